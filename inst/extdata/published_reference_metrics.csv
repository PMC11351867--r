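dataset,method,t,dsc_mean,dsc_sd,hd95_mean,hd95_sd,tpr,ppv,f1
Prostate158,nnU-Net,NA,49.5,32.4,10.4,8.5,70.8,71.0,70.9
Prostate158,UNETR,NA,51.0,26.1,14.3,10.7,75.0,42.1,55.1
Prostate158,MIDeepSeg,NA,80.5,10.6,8.2,3.5,83.3,86.3,84.8
Prostate158,SAM,NA,84.1,8.6,6.5,4.5,91.7,93.5,92.6
Prostate158,cascade,0.0,49.3,28.4,14.0,12.1,62.5,46.9,53.6
Prostate158,cascade,0.4,73.4,16.2,8.7,7.5,83.3,72.9,77.8
Prostate158,cascade,0.7,83.2,8.9,6.5,4.6,91.7,91.8,91.7
PROSTATEx2,nnU-Net,NA,43.7,34.3,12.6,12.7,64.5,63.6,64.0
PROSTATEx2,UNETR,NA,44.3,26.5,15.9,10.6,71.0,49.4,58.3
PROSTATEx2,MIDeepSeg,NA,79.2,11.9,3.0,2.2,93.5,89.7,91.6
PROSTATEx2,SAM,NA,81.9,10.7,10.8,6.7,93.5,90.9,92.2
PROSTATEx2,cascade,0.0,42.5,33.2,16.7,14.3,51.6,44.8,48.0
PROSTATEx2,cascade,0.4,69.3,21.4,14.0,7.9,90.3,70.1,78.9
PROSTATEx2,cascade,0.7,81.0,11.6,11.2,7.0,93.5,88.3,90.8
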