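# Rejection network: a regression model that predicts the Dice quality of
# the coarse segmentation from the channel-wise concatenation of the coarse
# network's final-stage feature map and its two-channel probability map.
# Slices with a predicted score strictly below the gate threshold t are
# flagged for manual interaction.

#' Rejection network configuration
#'
#' The regression head has exactly three fully connected stages with ReLU
#' between them, widths `(1024, 512, 1)`. The backbone ships as a desk-scale
#' four-stage convolutional encoder whose global pooling is *multiscale*:
#' after every stage the per-channel spatial mean and maximum are pooled, and
#' the head regresses on the concatenation of all four stages' statistics.
#' Segmentation quality expresses itself in exactly such global statistics —
#' peak confidence, activation roughness, fragmentation — while per-location
#' detail mostly identifies individual patients; pooling every stage keeps
#' the small-sample regression from memorizing the latter. A full-scale run
#' would swap in a large pretrained image classifier via the same config
#' surface.
#'
#' @param in_channels input channels; must equal the coarse feature channels
#'   plus 2 (the probability map).
#' @param backbone backbone identifier; `"desk"` is the built-in profile.
#' @param head_widths the three fully connected widths (last must be 1).
#' @param base_channels first-stage width of the desk backbone.
#' @param seed initializer seed.
#' @return An object of class `icseg_reject_config`.
#' @export
reject_net_config <- function(in_channels, backbone = "desk",
                              head_widths = c(1024L, 512L, 1L),
                              base_channels = 16L, seed = 1L) {
  if (length(head_widths) != 3L || head_widths[3] != 1L)
    stop_cfg("head_widths", "must be three fully connected widths ending in 1")
  if (!identical(backbone, "desk"))
    stop_cfg("backbone", "only the 'desk' convolutional profile ships with this package")
  if (in_channels < 3) stop_cfg("in_channels", "must be at least 3 (features + 2 probability channels)")
  structure(list(in_channels = as.integer(in_channels), backbone = backbone,
                 head_widths = as.integer(head_widths),
                 base_channels = as.integer(base_channels),
                 seed = as.integer(seed)),
            class = "icseg_reject_config")
}

#' Build the rejection network
#'
#' Maps a `(C+2)`-channel input (coarse features concatenated with the
#' background/foreground probability map) to a single scalar quality score
#' per slice. The output is linear during training (the mean-squared-error
#' loss acts on the raw output) and clamped to \[0, 1\] only at inference.
#'
#' @param config an [reject_net_config()].
#' @return An `icseg_reject_model`.
#' @export
build_rejection_net <- function(config) {
  stopifnot(inherits(config, "icseg_reject_config"))
  bc <- config$base_channels
  ch <- c(bc, 2L * bc, 4L * bc, 4L * bc)
  built <- with_seed(config$seed, {
    stages <- list()
    prev <- config$in_channels
    for (k in 1:4) {
      stages[[k]] <- list(conv = new_conv3(prev, ch[k], "backbone"),
                          relu = new_relu())
      prev <- ch[k]
    }
    pools <- lapply(1:3, function(k) new_pool())
    taps <- lapply(1:4, function(k) new_gpool())
    feat_dim <- 2L * sum(ch)
    head <- list(new_fc(feat_dim, config$head_widths[1], "head"), new_relu(),
                 new_fc(config$head_widths[1], config$head_widths[2], "head"),
                 new_relu(),
                 new_fc(config$head_widths[2], 1L, "head"))
    list(stages = stages, pools = pools, taps = taps, head = head, ch = ch)
  })
  e <- new.env(parent = emptyenv())
  e$stages <- built$stages
  e$pools <- built$pools
  e$taps <- built$taps
  e$head <- built$head
  e$ch <- built$ch
  # flat view of all layers, used for parameter collection and snapshots
  e$layers <- c(unlist(built$stages, recursive = FALSE), built$pools,
                built$taps, built$head)
  e$config <- config
  e$frozen <- FALSE
  class(e) <- "icseg_reject_model"
  e
}

# Assemble the rejection input for one coarse prediction: (C+2, H, W).
rejection_input <- function(coarse_pred) {
  feats <- aperm(coarse_pred$feats, c(3, 1, 2))
  probs <- aperm(coarse_pred$probs, c(3, 1, 2))
  d <- dim(feats)
  x <- array(0, c(d[1] + 2L, d[2], d[3]))
  x[seq_len(d[1]), , ] <- feats
  x[d[1] + 1:2, , ] <- probs
  x
}

rejection_forward <- function(model, x, train = TRUE) {
  if (dim(x)[1] != model$config$in_channels)
    stop(sprintf("rejection input has %d channels; model expects %d",
                 dim(x)[1], model$config$in_channels), call. = FALSE)
  B <- dim(x)[4]
  feats <- vector("list", 4L)
  h <- x
  for (k in 1:4) {
    a <- layer_fwd(model$stages[[k]]$relu,
                   layer_fwd(model$stages[[k]]$conv, h, train), train)
    feats[[k]] <- layer_fwd(model$taps[[k]], a, train)
    if (k < 4) h <- layer_fwd(model$pools[[k]], a, train)
  }
  z <- do.call(rbind, feats)
  as.numeric(seq_fwd(model$head, z, train))
}

rejection_backward <- function(model, dy) {
  dz <- seq_bwd(model$head, dy)
  rows <- c(0L, cumsum(2L * model$ch))
  dtap <- lapply(1:4, function(k)
    dz[(rows[k] + 1L):rows[k + 1L], , drop = FALSE])
  da <- layer_bwd(model$taps[[4]], dtap[[4]])
  for (k in 3:1) {
    dh <- layer_bwd(model$stages[[k + 1]]$conv,
                    layer_bwd(model$stages[[k + 1]]$relu, da))
    da <- layer_bwd(model$pools[[k]], dh) + layer_bwd(model$taps[[k]], dtap[[k]])
  }
  layer_bwd(model$stages[[1]]$conv, layer_bwd(model$stages[[1]]$relu, da))
}

#' Predict quality scores for coarse predictions
#'
#' @param model an `icseg_reject_model`.
#' @param coarse_preds list of coarse predictions from [predict_coarse()].
#' @param batch_size forward batch size.
#' @return Numeric vector of scores clamped to \[0, 1\].
#' @export
predict_quality <- function(model, coarse_preds, batch_size = 8L) {
  stopifnot(inherits(model, "icseg_reject_model"))
  xs <- lapply(coarse_preds, rejection_input)
  n <- length(xs)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    d <- dim(xs[[i]])
    x <- array(0, c(d, j - i + 1L))
    for (b in seq_len(j - i + 1L)) x[, , , b] <- xs[[i + b - 1L]]
    out[i:j] <- rejection_forward(model, x, train = FALSE)
    i <- j + 1L
  }
  pmin(1, pmax(0, out))
}

#' Dice quality target for a coarse prediction
#'
#' The Dice similarity between the binarized coarse mask and the ground
#' truth — the regression target of the rejection network.
#'
#' @param coarse_mask binarized (argmax) coarse prediction.
#' @param gt ground-truth mask of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
quality_target <- function(coarse_mask, gt) dice_coefficient(coarse_mask, gt)

#' Mean squared error between predicted and target quality scores
#'
#' @param predicted,target equal-length numeric vectors (nonempty).
#' @return Mean of squared differences.
#' @export
mse_loss <- function(predicted, target) {
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  if (length(predicted) != length(target))
    stop("predicted and target must have equal length", call. = FALSE)
  mean((predicted - target)^2)
}

#' Training settings for the rejection network
#'
#' Adam with separate initial learning rates for the backbone and the
#' regression head, polynomial decay with exponent 0.9, optional dihedral
#' (flip/rotation) augmentation of the input maps, and decoupled weight
#' decay against overfitting of the wide regression head; the checkpoint
#' with the lowest validation MSE is kept. The desk-scale backbone trains
#' from random weights, so its default rate equals the head's; fine-tuning a
#' large pretrained backbone would drop it to 1e-4.
#'
#' @param epochs,batch_size loop sizes.
#' @param lr_backbone,lr_head initial learning rates per parameter group.
#' @param poly_power decay exponent.
#' @param augment apply random flips/right-angle rotations to the input maps
#'   (the quality target is invariant under them).
#' @param weight_decay decoupled weight decay.
#' @param seed RNG seed for shuffling and augmentation.
#' @return A config list.
#' @export
reject_train_config <- function(epochs = 30L, batch_size = 4L,
                                lr_backbone = 3e-3, lr_head = 3e-3,
                                poly_power = 0.9, augment = TRUE,
                                weight_decay = 1e-3, seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_backbone = lr_backbone, lr_head = lr_head,
       poly_power = poly_power, augment = isTRUE(augment),
       weight_decay = weight_decay, seed = as.integer(seed))
}

# Random dihedral-group transform of a channel-first (C,H,W) array.
dihedral_chw <- function(x) {
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k))
    x <- aperm(x, c(1, 3, 2))[, , dim(x)[2]:1, drop = FALSE]
  if (runif(1) < 0.5) x <- x[, , dim(x)[3]:1, drop = FALSE]
  x
}

#' Train the rejection network against a frozen coarse model
#'
#' Quality targets are the Dice coefficients between the binarized coarse
#' predictions and ground truth, computed from the frozen coarse model
#' (which must be marked with [freeze_model()]; training never touches its
#' parameters). Because the coarse model is frozen and rejection inputs are
#' not augmented, its outputs are computed once per call — identical to
#' recomputing them every epoch.
#'
#' @param model an `icseg_reject_model` (modified in place).
#' @param coarse_model a frozen `icseg_coarse_model`.
#' @param cohort an `icseg_cohort`.
#' @param train_config an [reject_train_config()].
#' @return List with `model`, `history`, `best_epoch`, and the training/
#'   validation score tables (`val_scores`: patient, slice, target).
#' @export
train_rejection <- function(model, coarse_model, cohort,
                            train_config = reject_train_config()) {
  stopifnot(inherits(model, "icseg_reject_model"),
            inherits(coarse_model, "icseg_coarse_model"))
  if (!isTRUE(coarse_model$frozen))
    stop("coarse model must be frozen (freeze_model()) before training the rejection network",
         call. = FALSE)
  cfg <- train_config
  recs_tr <- cohort_slices(cohort, "train")
  recs_va <- cohort_slices(cohort, "val")
  if (length(recs_tr) == 0 || length(recs_va) == 0)
    stop("cohort must contain non-empty train and val splits", call. = FALSE)
  prep <- function(recs) {
    preds <- predict_coarse(coarse_model, recs)
    list(x = lapply(preds, rejection_input),
         d = vapply(seq_along(recs), function(i)
           quality_target(preds[[i]]$mask, recs[[i]]$mask), numeric(1)))
  }
  tr <- prep(recs_tr)
  va <- prep(recs_va)
  params <- nn_params(model$layers)
  opt <- adam_init(params)
  n <- length(tr$x)
  spe <- ceiling(n / cfg$batch_size)
  total <- cfg$epochs * spe
  lrs <- c(backbone = cfg$lr_backbone, head = cfg$lr_head)
  best <- Inf; best_epoch <- NA_integer_; best_snap <- NULL
  hist <- data.frame(epoch = integer(0), train_mse = numeric(0),
                     val_mse = numeric(0))
  step <- 0L
  with_seed(derive_seed(cfg$seed, 202L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(spe)) {
        idx <- ord[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
        d0 <- dim(tr$x[[1]])
        x <- array(0, c(d0, length(idx)))
        for (b in seq_along(idx)) {
          xb <- tr$x[[idx[b]]]
          if (cfg$augment) xb <- dihedral_chw(xb)
          x[, , , b] <- xb
        }
        sb <- rejection_forward(model, x, train = TRUE)
        db <- tr$d[idx]
        ep_loss <- ep_loss + mse_loss(sb, db)
        dy <- matrix(2 * (sb - db) / length(idx), nrow = 1)
        zero_grads(params)
        rejection_backward(model, dy)
        frac <- poly_lr(step, total, 1, cfg$poly_power)
        opt <- adam_step(opt, params, lrs * frac,
                         weight_decay = cfg$weight_decay %||% 0)
        step <- step + 1L
      }
      s_va <- numeric(length(va$x))
      i <- 1L
      while (i <= length(va$x)) {
        j <- min(i + cfg$batch_size - 1L, length(va$x))
        d0 <- dim(va$x[[1]])
        x <- array(0, c(d0, j - i + 1L))
        for (b in seq_len(j - i + 1L)) x[, , , b] <- va$x[[i + b - 1L]]
        s_va[i:j] <- rejection_forward(model, x, train = FALSE)
        i <- j + 1L
      }
      val_mse <- mse_loss(s_va, va$d)
      hist <- rbind(hist, data.frame(epoch = ep, train_mse = ep_loss / spe,
                                     val_mse = val_mse))
      if (val_mse < best) {
        best <- val_mse; best_epoch <- ep
        best_snap <- snapshot_params(params)
      }
    }
  })
  restore_params(params, best_snap)
  val_scores <- data.frame(
    patient_id = vapply(recs_va, `[[`, character(1), "patient_id"),
    slice_index = vapply(recs_va, `[[`, integer(1), "slice_index"),
    target = va$d)
  list(model = model, history = hist, best_epoch = best_epoch,
       val_scores = val_scores)
}

#' Gate configuration
#'
#' @param threshold the quality cutoff `t`. Scores strictly below `t` are
#'   routed to manual interaction. Values above 1 are permitted (they route
#'   everything to manual, the fully interactive limit).
#' @return An `icseg_gate_config`.
#' @export
gate_config <- function(threshold) {
  if (!is.numeric(threshold) || !is.finite(threshold) || threshold < 0)
    stop_cfg("threshold", "must be a finite nonnegative number")
  structure(list(threshold = threshold), class = "icseg_gate_config")
}

#' Route a quality score to manual or automatic box provisioning
#'
#' `"MANUAL"` iff the predicted score is strictly lower than the threshold;
#' a score exactly at the threshold stays `"AUTO"`.
#'
#' @param score predicted quality score (or vector of scores).
#' @param cfg an [gate_config()].
#' @return Character vector of `"MANUAL"` / `"AUTO"` decisions.
#' @export
gate <- function(score, cfg) {
  stopifnot(inherits(cfg, "icseg_gate_config"))
  ifelse(score < cfg$threshold, "MANUAL", "AUTO")
}
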