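# Coarse segmentation network: a U-Net-style encoder-decoder with five
# encoder blocks and four pooling operations (deepest stride 16),
# squeeze-and-excitation units after every convolutional block and non-local
# attention on the two deepest skip connections. Produces the initial
# foreground probability map and the final-stage feature map consumed by the
# rejection network.

#' Coarse network configuration
#'
#' @param base_channels channels of the first encoder block. The default (8)
#'   is the desk-scale CPU profile; 64 corresponds to a full-scale model.
#' @param encoder_blocks,pooling_ops architecture constants; the encoder must
#'   have five blocks and four pooling operations (deepest stride
#'   `2^pooling_ops = 16`).
#' @param use_se,use_nonlocal include squeeze-and-excitation / non-local
#'   attention units (both on by default; turn off for ablations).
#' @param se_reduction SE bottleneck reduction ratio.
#' @param seed initializer seed; identical seeds give identical parameters.
#' @return An object of class `icseg_coarse_config`.
#' @export
coarse_net_config <- function(base_channels = 8L, encoder_blocks = 5L,
                              pooling_ops = 4L, use_se = TRUE,
                              use_nonlocal = TRUE, se_reduction = 8,
                              seed = 1L) {
  if (encoder_blocks != 5L || pooling_ops != 4L)
    stop_cfg("encoder_blocks/pooling_ops",
             "must be 5 blocks with 4 pooling operations (output stride 16)")
  if (base_channels < 2) stop_cfg("base_channels", "must be at least 2")
  structure(list(base_channels = as.integer(base_channels),
                 encoder_blocks = 5L, pooling_ops = 4L,
                 use_se = isTRUE(use_se), use_nonlocal = isTRUE(use_nonlocal),
                 se_reduction = se_reduction, seed = as.integer(seed)),
            class = "icseg_coarse_config")
}

#' Build the coarse segmentation network
#'
#' @param config an [coarse_net_config()].
#' @return An `icseg_coarse_model`. Its forward pass maps an H x W x 3 slice
#'   to an H x W x 2 background/foreground probability map (pixelwise
#'   softmax) plus the final-stage feature map.
#' @export
build_coarse_net <- function(config = coarse_net_config()) {
  stopifnot(inherits(config, "icseg_coarse_config"))
  net <- with_seed(config$seed,
    build_unet(3L, config$base_channels, levels = 5L, out_ch = 2L,
               use_se = config$use_se, use_nonlocal = config$use_nonlocal,
               se_reduction = config$se_reduction))
  e <- new.env(parent = emptyenv())
  e$net <- net
  e$config <- config
  e$frozen <- FALSE
  e$feat_channels <- net$ch[1]
  class(e) <- "icseg_coarse_model"
  e
}

#' Freeze a model's parameters
#'
#' A frozen model takes no gradient updates; [train_rejection()] requires the
#' coarse model to be frozen.
#' @param model an icseg model object.
#' @return The model, invisibly.
#' @export
freeze_model <- function(model) {
  model$frozen <- TRUE
  invisible(model)
}

# Stack a list of H x W x C pixel arrays into a channel-first batch.
stack_batch <- function(pixel_list) {
  d <- dim(pixel_list[[1]])
  B <- length(pixel_list)
  x <- array(0, c(d[3], d[1], d[2], B))
  for (b in seq_len(B)) x[, , , b] <- aperm(pixel_list[[b]], c(3, 1, 2))
  x
}

#' Run the coarse network on slices
#'
#' @param model an `icseg_coarse_model`.
#' @param slices a list of `icseg_slice` objects (or records with a `$slice`).
#' @param batch_size forward batch size.
#' @return Per slice: `probs` (H x W x 2), `feats` (H x W x C) and `mask`
#'   (foreground probability > 0.5, i.e. the pixelwise argmax).
#' @export
predict_coarse <- function(model, slices, batch_size = 8L) {
  stopifnot(inherits(model, "icseg_coarse_model"))
  slices <- lapply(slices, function(s) if (inherits(s, "icseg_slice")) s else s$slice)
  out <- vector("list", length(slices))
  i <- 1L
  while (i <= length(slices)) {
    j <- min(i + batch_size - 1L, length(slices))
    x <- stack_batch(lapply(slices[i:j], `[[`, "pixels"))
    fw <- unet_fwd(model$net, x, train = FALSE)
    for (b in seq_len(j - i + 1L)) {
      probs <- aperm(array(fw$probs[, , , b], dim(fw$probs)[1:3]), c(2, 3, 1))
      feats <- aperm(array(fw$feats[, , , b], dim(fw$feats)[1:3]), c(2, 3, 1))
      out[[i + b - 1L]] <- list(probs = probs, feats = feats,
                                mask = probs[, , 2] > 0.5)
    }
    i <- j + 1L
  }
  out
}

#' Soft Dice loss
#'
#' `1 - mean_i [ (2 sum(p_i y_i) + eps) / (sum(p_i) + sum(y_i) + eps) ]` over
#' the images of a batch. The additive smoothing constant `eps` keeps the
#' loss defined on lesion-free slices (0/0 otherwise) and is small enough not
#' to bias nonempty cases.
#'
#' @param pred foreground probabilities, H x W or H x W x N.
#' @param target binary masks of matching shape.
#' @param eps smoothing constant (default 1e-5).
#' @return Loss value in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1e-5) {
  check_same_shape(pred, target, "prediction and target")
  d <- dim(pred) %||% length(pred)
  if (length(d) == 2) {
    pred <- array(pred, c(d, 1L))
    target <- array(target, c(d, 1L))
  }
  n <- dim(pred)[3]
  dices <- vapply(seq_len(n), function(i) {
    p <- pred[, , i]; y <- target[, , i] + 0
    (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
  }, numeric(1))
  1 - mean(dices)
}

# Batched Dice loss with gradient w.r.t. the (2,H,W,B) logits.
dice_loss_grad <- function(probs, y, eps = 1e-5) {
  d <- dim(probs)
  B <- d[4]
  pf <- array(probs[2, , , ], d[2:4])
  dlogit <- array(0, d)
  dices <- numeric(B)
  for (b in seq_len(B)) {
    p <- pf[, , b]; yb <- y[, , b]
    num <- 2 * sum(p * yb) + eps
    den <- sum(p) + sum(yb) + eps
    dices[b] <- num / den
    dp <- -(2 * yb * den - num) / den^2 / B
    dz <- dp * p * (1 - p)
    dlogit[2, , , b] <- dz
    dlogit[1, , , b] <- -dz
  }
  list(loss = 1 - mean(dices), dlogits = dlogit)
}

# ---- data augmentation -----------------------------------------------------

# Rotate a square matrix by k * 90 degrees (clockwise).
rot90_mat <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

shift_mat <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Random horizontal flip, multiple-of-90-degree rotation and small
# translation (the crop analogue), applied consistently to image and mask.
augment_pair <- function(px, mask, shift_max = 4L) {
  if (runif(1) < 0.5) {
    px <- px[, dim(px)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  k <- sample(0:3, 1)
  if (k > 0) {
    px2 <- array(0, dim(px))
    for (ch in seq_len(dim(px)[3])) px2[, , ch] <- rot90_mat(px[, , ch], k)
    px <- px2
    mask <- rot90_mat(mask + 0, k) > 0.5
  }
  sh <- sample(seq(-shift_max, shift_max), 2, replace = TRUE)
  if (any(sh != 0)) {
    px2 <- array(0, dim(px))
    for (ch in seq_len(dim(px)[3])) px2[, , ch] <- shift_mat(px[, , ch], sh[1], sh[2])
    px <- px2
    mask <- shift_mat(mask + 0, sh[1], sh[2]) > 0.5
  }
  list(px = px, mask = mask)
}

#' Training settings for the coarse network
#'
#' Defaults mirror the full-scale recipe (Adam, initial learning rate 1e-3,
#' polynomial decay with exponent 0.9, flip/rotation/translation
#' augmentation) at desk-scale epoch and batch counts.
#'
#' @param epochs training epochs.
#' @param batch_size slices per optimizer step.
#' @param lr initial learning rate.
#' @param dice_eps smoothing constant of the training-time Dice loss. The
#'   training default (1) is larger than the evaluation-loss default so that
#'   lesion-free slices can actually attain zero loss on an all-background
#'   prediction; with a tiny constant they never can, and their residual
#'   gradient fights the lesion slices.
#' @param poly_power polynomial decay exponent.
#' @param augment apply random flip/rotation/translation.
#' @param shift_max maximum translation in pixels.
#' @param seed RNG seed for shuffling and augmentation.
#' @return A config list.
#' @export
coarse_train_config <- function(epochs = 16L, batch_size = 8L, lr = 3e-3,
                                dice_eps = 1, poly_power = 0.9, augment = TRUE,
                                shift_max = 4L, seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, dice_eps = dice_eps, poly_power = poly_power,
       augment = isTRUE(augment),
       shift_max = as.integer(shift_max), seed = as.integer(seed))
}

#' Train the coarse segmentation network
#'
#' Minimizes the soft Dice loss with Adam under polynomial learning-rate
#' decay; the checkpoint with the highest validation mean Dice (computed on
#' binarized predictions) is restored at the end. Lesion-free slices stay in
#' the training set (the smoothed loss is well defined on them).
#'
#' @param model an `icseg_coarse_model` (modified in place).
#' @param cohort an `icseg_cohort` with train and val splits.
#' @param train_config an [coarse_train_config()].
#' @return List with `model`, `history` (per-epoch data frame) and
#'   `best_epoch`.
#' @export
train_coarse <- function(model, cohort, train_config = coarse_train_config()) {
  stopifnot(inherits(model, "icseg_coarse_model"))
  cfg <- train_config
  recs_tr <- cohort_slices(cohort, "train")
  recs_va <- cohort_slices(cohort, "val")
  if (length(recs_tr) == 0 || length(recs_va) == 0)
    stop("cohort must contain non-empty train and val splits", call. = FALSE)
  params <- nn_params(model$net)
  ckpt <- c(params, nn_states(model$net))
  opt <- adam_init(params)
  n <- length(recs_tr)
  spe <- ceiling(n / cfg$batch_size)
  total <- cfg$epochs * spe
  best <- -Inf; best_epoch <- NA_integer_; best_snap <- NULL
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_dsc = numeric(0))
  step <- 0L
  with_seed(derive_seed(cfg$seed, 101L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(spe)) {
        idx <- ord[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
        px <- vector("list", length(idx))
        H <- nrow(recs_tr[[1]]$mask); W <- ncol(recs_tr[[1]]$mask)
        y <- array(0, c(H, W, length(idx)))
        for (b in seq_along(idx)) {
          r <- recs_tr[[idx[b]]]
          if (cfg$augment) {
            a <- augment_pair(r$slice$pixels, r$mask, cfg$shift_max)
            px[[b]] <- a$px; y[, , b] <- a$mask
          } else {
            px[[b]] <- r$slice$pixels; y[, , b] <- r$mask
          }
        }
        x <- stack_batch(px)
        fw <- unet_fwd(model$net, x, train = TRUE)
        lg <- dice_loss_grad(fw$probs, y, cfg$dice_eps)
        ep_loss <- ep_loss + lg$loss
        zero_grads(params)
        unet_bwd(model$net, lg$dlogits)
        lr_now <- poly_lr(step, total, cfg$lr, cfg$poly_power)
        opt <- adam_step(opt, params, lr_now)
        step <- step + 1L
      }
      val_dsc <- validation_dice(model, recs_va)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     lr = poly_lr(step - 1L, total, cfg$lr, cfg$poly_power),
                                     train_loss = ep_loss / spe,
                                     val_dsc = val_dsc))
      if (val_dsc > best) {
        best <- val_dsc; best_epoch <- ep
        best_snap <- snapshot_params(ckpt)
      }
    }
  })
  restore_params(ckpt, best_snap)
  list(model = model, history = hist, best_epoch = best_epoch)
}

validation_dice <- function(model, recs) {
  preds <- predict_coarse(model, recs)
  mean(vapply(seq_along(recs), function(i)
    dice_coefficient(preds[[i]]$mask, recs[[i]]$mask), numeric(1)))
}
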