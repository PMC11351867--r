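# NIfTI input/output, resampling to the working grid, and intensity
# normalization. The synthetic writer and the loader are mutual inverses on
# matched grids, so real volumes and phantom volumes share one code path.

#' Write one patient as per-modality NIfTI volumes plus a label volume
#'
#' Emits `t2w.nii.gz`, `adc.nii.gz`, `dwi.nii.gz` and `label.nii.gz` in
#' `dir`, each an H x W x S volume with in-plane pixel spacing taken from the
#' patient record.
#'
#' @param patient a patient record from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param slice_thickness_mm through-plane spacing written to the header.
#' @return Invisibly, the four file paths.
#' @export
write_patient_nifti <- function(patient, dir, slice_thickness_mm = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  S <- length(patient$slices)
  d <- dim(patient$slices[[1]]$pixels)
  pd <- c(patient$spacing_mm, slice_thickness_mm)
  paths <- character(4)
  mods <- c("t2w", "adc", "dwi")
  for (ch in 1:3) {
    vol <- array(0, c(d[1], d[2], S))
    for (z in seq_len(S)) vol[, , z] <- patient$slices[[z]]$pixels[, , ch]
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- pd
    paths[ch] <- file.path(dir, paste0(mods[ch], ".nii.gz"))
    RNifti::writeNifti(img, paths[ch])
  }
  lab <- array(0L, c(d[1], d[2], S))
  for (z in seq_len(S)) lab[, , z] <- patient$masks[[z]] + 0L
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- pd
  paths[4] <- file.path(dir, "label.nii.gz")
  RNifti::writeNifti(img, paths[4])
  invisible(stats::setNames(paths, c(mods, "label")))
}

#' Write a whole cohort as NIfTI volumes
#'
#' One subdirectory per patient, named by patient id.
#' @param cohort an `icseg_cohort`.
#' @param dir root output directory.
#' @return Invisibly, the patient directories.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dirs <- vapply(cohort$patients, function(p) {
    pd <- file.path(dir, p$patient_id)
    write_patient_nifti(p, pd)
    pd
  }, character(1))
  invisible(dirs)
}

read_vol <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot load volume: file '%s' does not exist", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  list(data = as.array(img), pixdim = RNifti::pixdim(img))
}

#' Load a patient from three modality volumes plus a label volume
#'
#' The T2W volume defines the reference grid; ADC and DWI slices whose
#' in-plane size differs are resampled to it (bilinear), the label with
#' nearest-neighbour. Slice counts must agree. Channels are optionally
#' min-max scaled and standardized per volume, and slices optionally
#' resampled to a square working size.
#'
#' @param t2w_path,adc_path,dwi_path,label_path NIfTI file paths.
#' @param target_size optional working size passed to [resample_slice()].
#' @param normalize apply [normalize_channels()] per volume (default TRUE).
#' @param patient_id identifier stored on the slices.
#' @return List of records with `slice` (an `icseg_slice`) and `mask`, in
#'   ascending slice order.
#' @export
load_patient <- function(t2w_path, adc_path, dwi_path, label_path,
                         target_size = NULL, normalize = TRUE,
                         patient_id = NA_character_) {
  ref <- read_vol(t2w_path)
  d <- dim(ref$data)
  spacing <- ref$pixdim[1:2]
  vols <- list(ref$data)
  for (path in c(adc_path, dwi_path)) {
    v <- read_vol(path)
    dv <- dim(v$data)
    if (dv[3] != d[3])
      stop(sprintf("volume '%s' has %d slices; reference has %d",
                   path, dv[3], d[3]), call. = FALSE)
    if (any(dv[1:2] != d[1:2])) {
      res <- array(0, d)
      for (z in seq_len(d[3]))
        res[, , z] <- as.matrix(EBImage::resize(v$data[, , z],
                                                w = d[1], h = d[2]))
      v$data <- res
    }
    vols[[length(vols) + 1L]] <- v$data
  }
  lab <- read_vol(label_path)
  dl <- dim(lab$data)
  if (dl[3] != d[3])
    stop(sprintf("volume '%s' has %d slices; reference has %d",
                 label_path, dl[3], d[3]), call. = FALSE)
  if (any(dl[1:2] != d[1:2])) {
    res <- array(0, d)
    for (z in seq_len(d[3]))
      res[, , z] <- as.matrix(EBImage::resize(lab$data[, , z],
                                              w = d[1], h = d[2],
                                              filter = "none"))
    lab$data <- res
  }
  out <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    px <- array(0, c(d[1], d[2], 3))
    for (ch in 1:3) px[, , ch] <- vols[[ch]][, , z]
    out[[z]] <- list(slice = new_slice(px, spacing, patient_id, z),
                     mask = lab$data[, , z] > 0.5)
  }
  if (normalize) {
    slices <- normalize_channels(lapply(out, `[[`, "slice"))
    for (z in seq_len(d[3])) out[[z]]$slice <- slices[[z]]
  }
  if (!is.null(target_size)) {
    for (z in seq_len(d[3])) {
      out[[z]]$slice <- resample_slice(out[[z]]$slice, target_size)
      out[[z]]$mask <- resample_mask(out[[z]]$mask, target_size)
    }
  }
  out
}

#' Resample a slice to a square working size
#'
#' Bilinear interpolation for image channels; the physical spacing is
#' rescaled by the size ratio so areas are preserved.
#'
#' @param slice an `icseg_slice`.
#' @param target_size working size in pixels (>= 32).
#' @return The resampled `icseg_slice`.
#' @export
resample_slice <- function(slice, target_size = 256L) {
  stopifnot(inherits(slice, "icseg_slice"))
  if (!is.numeric(target_size) || target_size < 32)
    stop_cfg("target_size", "must be at least 32")
  d <- dim(slice$pixels)
  if (d[1] == target_size && d[2] == target_size) return(slice)
  px <- array(0, c(target_size, target_size, d[3]))
  for (ch in seq_len(d[3]))
    px[, , ch] <- as.matrix(EBImage::resize(slice$pixels[, , ch],
                                            w = target_size, h = target_size))
  new_slice(px, slice$spacing_mm * d[1:2] / target_size,
            slice$patient_id, slice$slice_index)
}

#' Resample a binary mask with nearest-neighbour interpolation
#' @param mask logical matrix.
#' @param target_size working size in pixels.
#' @return Logical matrix of size `target_size` squared.
#' @export
resample_mask <- function(mask, target_size = 256L) {
  if (!is.numeric(target_size) || target_size < 32)
    stop_cfg("target_size", "must be at least 32")
  if (all(dim(mask) == target_size)) return(as_mask(mask))
  as.matrix(EBImage::resize(mask + 0, w = target_size, h = target_size,
                            filter = "none")) > 0.5
}

#' Min-max scale and standardize image channels per volume
#'
#' Each channel is independently scaled to \[0, 1\] over the volume's value
#' range and then standardized to zero mean and unit variance over the
#' volume. Degenerate (constant) channels become all zeros. Accepts a single
#' slice (treated as a one-slice volume) or a list of slices from one
#' patient.
#'
#' @param x an `icseg_slice` or a list of them.
#' @return Object of the same shape with normalized pixel channels.
#' @export
normalize_channels <- function(x) {
  single <- inherits(x, "icseg_slice")
  slices <- if (single) list(x) else x
  stopifnot(all(vapply(slices, inherits, logical(1), "icseg_slice")))
  n_ch <- dim(slices[[1]]$pixels)[3]
  for (ch in seq_len(n_ch)) {
    vals <- unlist(lapply(slices, function(s) s$pixels[, , ch]))
    rng <- range(vals)
    if (rng[2] - rng[1] < 1e-12) {
      for (z in seq_along(slices)) slices[[z]]$pixels[, , ch] <- 0
      next
    }
    scaled_mean <- (mean(vals) - rng[1]) / (rng[2] - rng[1])
    scaled_sd <- sd(vals) / (rng[2] - rng[1])
    for (z in seq_along(slices)) {
      v <- (slices[[z]]$pixels[, , ch] - rng[1]) / (rng[2] - rng[1])
      slices[[z]]$pixels[, , ch] <- (v - scaled_mean) / scaled_sd
    }
  }
  if (single) slices[[1]] else slices
}
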