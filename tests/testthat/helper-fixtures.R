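# Shared fixtures. Trained models are expensive, so they are built lazily
# and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small easy cohort (low difficulty): the coarse task is clearly learnable,
# used for the training-behaviour invariants and pipeline contracts.
easy_cohort <- function() memo("easy_cohort", function() {
  spec <- phantom_spec(image_size = 48, lesion_radius_range = c(3, 6), seed = 5)
  generate_cohort(spec, 10, 4, difficulty_range = c(0, 0.2))
})

# Coarse model trained on the easy cohort.
easy_coarse <- function() memo("easy_coarse", function() {
  m <- build_coarse_net(coarse_net_config(seed = 1))
  tr <- train_coarse(m, easy_cohort(),
                     coarse_train_config(epochs = 22, batch_size = 2, seed = 1))
  freeze_model(m)
  list(model = m, history = tr$history, best_epoch = tr$best_epoch)
})

# Rejection model trained against the frozen easy coarse model on a
# mixed-difficulty cohort (quality must vary for the regression to be
# meaningful).
mixed_cohort <- function() memo("mixed_cohort", function() {
  spec <- phantom_spec(image_size = 48, lesion_radius_range = c(3, 6), seed = 6)
  generate_cohort(spec, 12, 4)
})

easy_prompt <- function() memo("easy_prompt", function() {
  p <- builtin_prompt_net(prompt_seg_config(seed = 3))
  tr <- train_prompt_seg(p, easy_cohort(),
                         prompt_train_config(epochs = 14, batch_size = 2, seed = 3))
  list(segmenter = p, history = tr$history)
})

easy_rejection <- function() memo("easy_rejection", function() {
  cm <- easy_coarse()$model
  rj <- build_rejection_net(reject_net_config(in_channels = cm$feat_channels + 2L,
                                              seed = 2))
  tr <- train_rejection(rj, cm, mixed_cohort(),
                        reject_train_config(epochs = 15, batch_size = 4, seed = 2))
  list(model = rj, history = tr$history)
})

# A deterministic mock prompt segmenter: fills the prompt box (interface
# tests that must not depend on training).
box_fill_segmenter <- function(counter = NULL) {
  f <- tempfile(fileext = ".bin")
  writeBin(raw(1), f)
  sam_adapter(f, runner = function(pixels, box) {
    if (!is.null(counter)) counter$n <- (counter$n %||% 0) + 1L
    H <- dim(pixels)[1]; W <- dim(pixels)[2]
    p <- array(0, c(H, W, 2))
    fg <- icseg:::render_box_channel(box, W, H)
    p[, , 2] <- 0.02 + 0.96 * fg
    p[, , 1] <- 1 - p[, , 2]
    p
  })
}

# Brute-force all-pairs 95% Hausdorff oracle (independent of the distance
# transform route used by hd95()).
hd95_oracle <- function(P, G, spacing = c(1, 1), percentile = 0.95) {
  bp <- which(icseg:::boundary_pixels(P), arr.ind = TRUE)
  bg <- which(icseg:::boundary_pixels(G), arr.ind = TRUE)
  if (nrow(bp) == 0 || nrow(bg) == 0) return(NA_real_)
  py <- bp[, 1] * spacing[1]; px <- bp[, 2] * spacing[2]
  gy <- bg[, 1] * spacing[1]; gx <- bg[, 2] * spacing[2]
  D <- sqrt(outer(py, gy, "-")^2 + outer(px, gx, "-")^2)
  d_pg <- apply(D, 1, min)
  d_gp <- apply(D, 2, min)
  unname(quantile(c(d_pg, d_gp), percentile, type = 7))
}

random_blob_mask <- function(H, W, p_empty = 0.1) {
  m <- matrix(FALSE, H, W)
  if (runif(1) < p_empty) return(m)
  k <- sample(1:3, 1)
  for (i in seq_len(k)) {
    cy <- runif(1, 2, H - 1); cx <- runif(1, 2, W - 1)
    r <- runif(1, 1, min(H, W) / 3)
    yy <- matrix(rep(seq_len(H), times = W), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  m
}
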