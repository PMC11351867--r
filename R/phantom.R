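# Seeded multi-channel phantom generator.
#
# Each phantom slice emulates a co-registered three-channel MR slice
# (T2W-like, ADC-like, high-b-value-DWI-like) through a prostate-like gland:
# an elliptical gland region with smooth low-frequency texture, 0-3 blob
# lesions (ellipses warped by a low-frequency radial perturbation, giving the
# irregular shapes and ambiguous boundaries the cascade targets), channel
# specific lesion contrast (dark in the ADC-like channel, bright in the
# DWI-like channel) and additive Gaussian noise. A scalar `difficulty` in
# [0,1] scales lesion contrast by (1 - difficulty), so contrast-to-noise — and
# with it downstream coarse-segmentation quality — spans its full range.
# Geometry and noise draws do not depend on `difficulty`, so the same seed at
# two difficulty settings yields the same lesions at different contrasts.

#' Phantom generation settings
#'
#' @param image_size pixels per side (square slices; >= 32).
#' @param lesion_count_range integer interval for the number of lesions.
#' @param lesion_radius_range lesion base radius interval in pixels (default
#'   3.5%–7% of the image size; must stay below a quarter of the image).
#' @param contrast_per_channel signed lesion intensity offsets for the three
#'   channels; channel 2 (ADC-like) must be negative (dark lesion), channel 3
#'   (DWI-like) positive (bright lesion).
#' @param noise_sd additive Gaussian noise standard deviation (> 0).
#' @param difficulty scalar in \[0, 1\]; lesion contrast-to-noise decreases
#'   strictly as it rises.
#' @param contrast_floor fraction of the nominal lesion contrast retained at
#'   `difficulty = 1` (default 0.10). A hard lesion is faint and ambiguous —
#'   as in real multiparametric MR, where lesions that defeat an automatic
#'   segmenter are still visible to a reader — rather than physically absent;
#'   segmentation quality can therefore be *assessed* from the image even
#'   where segmentation itself fails.
#' @param noise_difficulty_gain factor by which the noise standard deviation
#'   grows over the difficulty range: the effective noise is
#'   `noise_sd * (1 + gain * difficulty)` (default gain 3). Difficult cases
#'   in real cohorts are noisy *globally*, not just at the lesion, so
#'   difficulty leaves evidence in every slice; contrast-to-noise still
#'   decreases strictly with difficulty.
#' @param spacing_mm physical pixel spacing (row, col).
#' @param seed integer seed; identical seeds yield bit-identical phantoms.
#' @return An object of class `icseg_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         lesion_count_range = c(0L, 3L),
                         lesion_radius_range = NULL,
                         contrast_per_channel = c(-0.25, -0.45, 0.55),
                         noise_sd = 0.12,
                         difficulty = 0.3,
                         contrast_floor = 0.10,
                         noise_difficulty_gain = 3,
                         spacing_mm = c(0.5, 0.5),
                         seed = 1L) {
  if (!is.numeric(image_size) || image_size < 32)
    stop_cfg("image_size", "must be at least 32")
  if (length(lesion_count_range) != 2 || any(lesion_count_range < 0) ||
      lesion_count_range[1] > lesion_count_range[2])
    stop_cfg("lesion_count_range", "must be a nondecreasing nonnegative pair")
  if (is.null(lesion_radius_range))
    lesion_radius_range <- c(0.035, 0.07) * image_size
  if (any(lesion_radius_range <= 0) || any(lesion_radius_range >= image_size / 4))
    stop_cfg("lesion_radius_range", "must be positive and below image_size/4")
  if (length(contrast_per_channel) != 3)
    stop_cfg("contrast_per_channel", "must have three entries")
  if (contrast_per_channel[2] >= 0)
    stop_cfg("contrast_per_channel", "channel 2 (ADC-like) must be negative")
  if (contrast_per_channel[3] <= 0)
    stop_cfg("contrast_per_channel", "channel 3 (DWI-like) must be positive")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_cfg("noise_sd", "must be positive")
  if (difficulty < 0 || difficulty > 1)
    stop_cfg("difficulty", "must lie in [0, 1]")
  if (contrast_floor < 0 || contrast_floor >= 1)
    stop_cfg("contrast_floor", "must lie in [0, 1)")
  if (noise_difficulty_gain < 0)
    stop_cfg("noise_difficulty_gain", "must be nonnegative")
  if (length(spacing_mm) != 2 || any(spacing_mm <= 0))
    stop_cfg("spacing_mm", "must be a positive (row, col) pair")
  structure(list(image_size = as.integer(image_size),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 contrast_per_channel = contrast_per_channel,
                 noise_sd = noise_sd, difficulty = difficulty,
                 contrast_floor = contrast_floor,
                 noise_difficulty_gain = noise_difficulty_gain,
                 spacing_mm = spacing_mm, seed = as.integer(seed)),
            class = "icseg_phantom_spec")
}

new_slice <- function(pixels, spacing_mm, patient_id = NA_character_,
                      slice_index = NA_integer_) {
  structure(list(pixels = pixels, spacing_mm = spacing_mm,
                 patient_id = patient_id, slice_index = slice_index),
            class = "icseg_slice")
}

# Gland geometry draw (consumes the current RNG stream).
draw_gland <- function(size) {
  list(cx = size / 2 + runif(1, -0.03, 0.03) * size,
       cy = size / 2 + runif(1, -0.03, 0.03) * size,
       rx = runif(1, 0.28, 0.38) * size,
       ry = runif(1, 0.24, 0.34) * size,
       theta = runif(1, 0, pi))
}

gland_mask <- function(g, size) {
  X <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  Y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  u <- (X - g$cx) * cos(g$theta) + (Y - g$cy) * sin(g$theta)
  v <- -(X - g$cx) * sin(g$theta) + (Y - g$cy) * cos(g$theta)
  (u / g$rx)^2 + (v / g$ry)^2 <= 1
}

# One lesion track: in-plane position, base radius, low-frequency radial
# shape coefficients, and the contiguous span of slices it occupies.
draw_lesion <- function(g, spec, n_slices) {
  u <- runif(1, -0.6, 0.6); v <- runif(1, -0.6, 0.6)
  cx <- g$cx + u * g$rx * cos(g$theta) - v * g$ry * sin(g$theta)
  cy <- g$cy + u * g$rx * sin(g$theta) + v * g$ry * cos(g$theta)
  r0 <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
  amp <- runif(3, 0, 0.25) / (2:4)
  phs <- runif(3, 0, 2 * pi)
  z0 <- sample.int(n_slices, 1)
  span <- min(sample.int(4L, 1), n_slices)
  z_lo <- max(1L, z0 - span %/% 2L)
  z_hi <- min(n_slices, z_lo + span - 1L)
  list(cx = cx, cy = cy, r0 = r0, amp = amp, phs = phs,
       z_lo = z_lo, z_hi = z_hi)
}

# Rasterize one lesion on slice z; the through-plane profile shrinks the
# radius toward the ends of the track (ellipsoid-like cross-sections).
lesion_mask_at <- function(les, z, size) {
  zc <- (les$z_lo + les$z_hi) / 2
  half <- (les$z_hi - les$z_lo) / 2 + 0.75
  fac <- 1 - ((z - zc) / half)^2
  if (fac <= 0) return(NULL)
  re <- les$r0 * sqrt(fac)
  X <- matrix(rep(seq_len(size), each = size), size, size)
  Y <- matrix(rep(seq_len(size), times = size), size, size)
  dx <- X - les$cx; dy <- Y - les$cy
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  rad <- re * (1 + les$amp[1] * cos(2 * ang + les$phs[1]) +
                   les$amp[2] * cos(3 * ang + les$phs[2]) +
                   les$amp[3] * cos(4 * ang + les$phs[3]))
  m <- dist <= rad
  if (!any(m)) NULL else m
}

# Channel base intensities inside/outside the gland.
.ch_levels <- list(inside = c(0.55, 0.60, 0.35), outside = c(0.15, 0.15, 0.12))

# Render one slice given geometry; consumes RNG for texture and noise only.
render_slice <- function(g, gmask, lesions, z, spec) {
  size <- spec$image_size
  lesion <- matrix(FALSE, size, size)
  for (les in lesions) {
    lm <- lesion_mask_at(les, z, size)
    if (!is.null(lm)) lesion <- lesion | lm
  }
  soft <- EBImage::gblur(lesion + 0, sigma = 0.8)
  px <- array(0, c(size, size, 3))
  fl <- spec$contrast_floor %||% 0.10
  scale <- (1 - spec$difficulty) * (1 - fl) + fl
  sd_eff <- spec$noise_sd * (1 + (spec$noise_difficulty_gain %||% 3) * spec$difficulty)
  for (ch in 1:3) {
    tex <- as.matrix(EBImage::resize(matrix(rnorm(36), 6, 6), w = size, h = size))
    img <- .ch_levels$outside[ch] +
      (.ch_levels$inside[ch] - .ch_levels$outside[ch]) * gmask +
      0.04 * tex +
      spec$contrast_per_channel[ch] * scale * soft +
      rnorm(size * size, sd = sd_eff)
    px[, , ch] <- img
  }
  list(pixels = px, mask = lesion)
}

#' Generate a single phantom slice with its ground-truth mask
#'
#' @param spec an [phantom_spec()] object.
#' @param rng_state optional integer seed overriding `spec$seed`.
#' @return A list with `slice` (an `icseg_slice`), `mask` (logical lesion
#'   mask) and `gland` (logical gland-region mask, useful as a reference
#'   region in quality checks).
#' @examples
#' p <- generate_phantom(phantom_spec(image_size = 64, seed = 7))
#' dim(p$slice$pixels)
#' @export
generate_phantom <- function(spec, rng_state = NULL) {
  stopifnot(inherits(spec, "icseg_phantom_spec"))
  seed <- rng_state %||% spec$seed
  with_seed(seed, {
    g <- draw_gland(spec$image_size)
    gmask <- gland_mask(g, spec$image_size)
    n <- spec$lesion_count_range[1] +
      (sample.int(diff(spec$lesion_count_range) + 1L, 1) - 1L)
    lesions <- if (n > 0) lapply(seq_len(n), function(i)
      draw_lesion(g, spec, 1L)) else list()
    r <- render_slice(g, gmask, lesions, 1L, spec)
    list(slice = new_slice(r$pixels, spec$spacing_mm), mask = r$mask,
         gland = gmask)
  })
}

#' Generate a seeded phantom cohort with patient-level splits
#'
#' Patients receive stratified difficulties covering the full \[0, 1\] range
#' (so downstream coarse-segmentation quality is heterogeneous — the regime
#' the rejection network must learn), lesions persist over 1–4 contiguous
#' slices (so 3D lesion-level metrics are meaningful), and train/val/test
#' splits are assigned on a patient basis.
#'
#' @param spec an [phantom_spec()] object (its `difficulty` is overridden per
#'   patient).
#' @param n_patients number of patients (>= 3).
#' @param slices_per_patient slices per patient volume.
#' @param split_fractions train/val/test fractions summing to 1.
#' @param difficulty_range interval the stratified per-patient difficulties
#'   cover (default the full \[0, 1\]; narrow it to generate uniformly easy
#'   or hard cohorts).
#' @return An object of class `icseg_cohort`.
#' @export
generate_cohort <- function(spec, n_patients, slices_per_patient = 8L,
                            split_fractions = c(0.6, 0.2, 0.2),
                            difficulty_range = c(0, 1)) {
  stopifnot(inherits(spec, "icseg_phantom_spec"))
  if (n_patients < 3)
    stop("n_patients must be at least 3 to form train/val/test splits", call. = FALSE)
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop_cfg("split_fractions", "must sum to 1")
  n <- as.integer(n_patients)
  n_train <- round(split_fractions[1] * n)
  n_val <- round(split_fractions[2] * n)
  n_test <- n - n_train - n_val
  counts <- c(train = n_train, val = n_val, test = n_test)
  while (any(counts < 1)) {  # every split needs at least one patient
    counts[which.min(counts)] <- counts[which.min(counts)] + 1L
    counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  }
  assign_split <- rep(c("train", "val", "test"), times = counts)
  master <- with_seed(derive_seed(spec$seed, 0L), {
    list(perm = sample.int(n), jit = runif(n), order = sample.int(n))
  })
  difficulty <- difficulty_range[1] +
    diff(difficulty_range) * (master$perm - 1 + master$jit) / n
  split_of <- character(n)
  split_of[master$order] <- assign_split
  patients <- vector("list", n)
  for (p in seq_len(n)) {
    patients[[p]] <- with_seed(derive_seed(spec$seed, p), {
      g <- draw_gland(spec$image_size)
      gmask <- gland_mask(g, spec$image_size)
      n_les <- spec$lesion_count_range[1] +
        (sample.int(diff(spec$lesion_count_range) + 1L, 1) - 1L)
      lesions <- if (n_les > 0) lapply(seq_len(n_les), function(i)
        draw_lesion(g, spec, slices_per_patient)) else list()
      pspec <- spec
      pspec$difficulty <- difficulty[p]
      slices <- vector("list", slices_per_patient)
      masks <- vector("list", slices_per_patient)
      pid <- sprintf("P%03d", p)
      for (z in seq_len(slices_per_patient)) {
        r <- render_slice(g, gmask, lesions, z, pspec)
        slices[[z]] <- new_slice(r$pixels, spec$spacing_mm, pid, z)
        masks[[z]] <- r$mask
      }
      list(patient_id = pid, split = split_of[p], difficulty = difficulty[p],
           spacing_mm = spec$spacing_mm, slices = slices, masks = masks)
    })
  }
  structure(list(patients = patients, spec = spec,
                 n_patients = n, slices_per_patient = as.integer(slices_per_patient),
                 split_counts = counts),
            class = "icseg_cohort")
}

#' @export
print.icseg_cohort <- function(x, ...) {
  cat(sprintf("<icseg_cohort: %d patients x %d slices (%dpx), splits %s>\n",
              x$n_patients, x$slices_per_patient, x$spec$image_size,
              paste(sprintf("%s=%d", names(x$split_counts), x$split_counts),
                    collapse = "/")))
  invisible(x)
}

#' Flatten a cohort split into a list of slice/mask records
#'
#' @param cohort an `icseg_cohort`.
#' @param split one of `"train"`, `"val"`, `"test"`, or `"all"`.
#' @return List of records with `slice`, `mask`, `patient_id`, `slice_index`,
#'   `difficulty`.
#' @export
cohort_slices <- function(cohort, split = "all") {
  out <- list()
  for (p in cohort$patients) {
    if (split != "all" && p$split != split) next
    for (z in seq_along(p$slices)) {
      out[[length(out) + 1L]] <- list(slice = p$slices[[z]], mask = p$masks[[z]],
                                      patient_id = p$patient_id,
                                      slice_index = z, difficulty = p$difficulty)
    }
  }
  out
}

#' Select the patients of one split
#' @param cohort an `icseg_cohort`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List of patient records.
#' @export
cohort_split <- function(cohort, split) {
  Filter(function(p) p$split == split, cohort$patients)
}
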