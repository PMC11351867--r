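# Encoder-decoder (U-Net style) composition over the layer primitives.
# The encoder has `levels` convolutional blocks with `levels - 1` max-pooling
# operations; skip connections join each encoder block to the mirrored
# decoder block; optional squeeze-and-excitation units sit at the end of
# every block and optional non-local attention units transform the two
# deepest skip connections. The layer before the final 1x1 classifier is
# exposed as the feature map consumed by the rejection network.

build_unet <- function(in_ch, base, levels = 5L, out_ch = 2L,
                       use_se = FALSE, use_nonlocal = FALSE,
                       se_reduction = 8, cap = 8L * base,
                       enc_group = "encoder", dec_group = "decoder") {
  ch <- pmin(base * 2^(seq_len(levels) - 1L), cap)
  enc <- vector("list", levels)
  prev <- in_ch
  for (k in seq_len(levels)) {
    blk <- list(new_conv3(prev, ch[k], enc_group), new_bnorm(ch[k], enc_group),
                new_relu(),
                new_conv3(ch[k], ch[k], enc_group), new_bnorm(ch[k], enc_group),
                new_relu())
    if (use_se) blk <- c(blk, list(new_se(ch[k], se_reduction, enc_group)))
    enc[[k]] <- blk
    prev <- ch[k]
  }
  pool <- lapply(seq_len(levels - 1L), function(k) new_pool())
  up <- lapply(seq_len(levels - 1L), function(k) new_up())
  nl <- vector("list", levels - 1L)
  if (use_nonlocal && levels >= 3L) {
    for (k in c(levels - 1L, levels - 2L)) nl[[k]] <- new_nonlocal(ch[k], enc_group)
  }
  dec <- vector("list", levels - 1L)
  for (k in seq_len(levels - 1L)) {
    cin <- ch[k + 1L] + ch[k]
    blk <- list(new_conv3(cin, ch[k], dec_group), new_bnorm(ch[k], dec_group),
                new_relu(),
                new_conv3(ch[k], ch[k], dec_group), new_bnorm(ch[k], dec_group),
                new_relu())
    if (use_se) blk <- c(blk, list(new_se(ch[k], se_reduction, dec_group)))
    dec[[k]] <- blk
  }
  final <- new_conv1(ch[1L], out_ch, dec_group)
  structure(list(enc = enc, pool = pool, up = up, nl = nl, dec = dec,
                 final = final, ch = ch, levels = levels, in_ch = in_ch,
                 out_ch = out_ch),
            class = "icseg_unet")
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  y[seq_len(da[1]), , , ] <- a
  y[da[1] + seq_len(db[1]), , , ] <- b
  y
}

# Forward pass on a (in_ch,H,W,B) batch. Returns the pre-softmax logits, the
# softmax probabilities and the final-stage feature map.
unet_fwd <- function(net, x, train = TRUE) {
  L <- net$levels
  skips <- vector("list", L - 1L)
  e <- x
  for (k in seq_len(L)) {
    e <- seq_fwd(net$enc[[k]], e, train)
    if (k < L) {
      skips[[k]] <- e
      e <- layer_fwd(net$pool[[k]], e, train)
    }
  }
  for (k in rev(seq_len(L - 1L))) {
    u <- layer_fwd(net$up[[k]], e, train)
    s <- skips[[k]]
    if (!is.null(net$nl[[k]])) s <- layer_fwd(net$nl[[k]], s, train)
    e <- seq_fwd(net$dec[[k]], concat_ch(u, s), train)
  }
  feats <- e
  logits <- layer_fwd(net$final, feats, train)
  list(logits = logits, probs = softmax2(logits), feats = feats)
}

# Backward pass from the gradient at the logits; returns the gradient at the
# input (rarely needed, but cheap).
unet_bwd <- function(net, dlogits) {
  L <- net$levels
  ch <- net$ch
  d <- layer_bwd(net$final, dlogits)
  dskip <- vector("list", L - 1L)
  for (k in seq_len(L - 1L)) {
    dcat <- seq_bwd(net$dec[[k]], d)
    cu <- ch[k + 1L]
    du <- dcat[seq_len(cu), , , , drop = FALSE]
    ds <- dcat[cu + seq_len(ch[k]), , , , drop = FALSE]
    if (!is.null(net$nl[[k]])) ds <- layer_bwd(net$nl[[k]], ds)
    dskip[[k]] <- ds
    d <- layer_bwd(net$up[[k]], du)
  }
  d <- seq_bwd(net$enc[[L]], d)
  for (k in rev(seq_len(L - 1L))) {
    d <- layer_bwd(net$pool[[k]], d)
    d <- d + dskip[[k]]
    d <- seq_bwd(net$enc[[k]], d)
  }
  d
}
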