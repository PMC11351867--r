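# Fine segmentation stage: a box-prompt segmentation contract, a built-in
# desk-scale prompt-conditioned encoder-decoder, the combined
# cross-entropy + Dice training loss, and an adapter contract for external
# promptable models (SAM-style image encoder / prompt encoder / mask
# decoder stacks). The built-in net encodes the prompt as a rendered
# box-interior channel appended to the three image channels — the simplest
# conditioning that honours the contract (image + box -> mask) without an
# architecture-specific positional embedding.

#' Prompt segmenter configuration
#'
#' @param variant `"builtin"` (desk-scale prompt-conditioned network) or
#'   `"external_adapter"` (wraps external pretrained weights; excluded from
#'   the core test surface).
#' @param base_channels width of the built-in network's first block.
#' @param levels encoder depth of the built-in network.
#' @param freeze_policy `"none"` (default for the built-in net, which starts
#'   from random weights) or `"encoder"` (freeze the encoder and train the
#'   decoder only — the fine-tuning regime for pretrained backbones).
#' @param weights_path required when `variant = "external_adapter"`.
#' @param seed initializer seed.
#' @return An `icseg_prompt_config`.
#' @export
prompt_seg_config <- function(variant = c("builtin", "external_adapter"),
                              base_channels = 8L, levels = 4L,
                              freeze_policy = c("none", "encoder"),
                              weights_path = NULL, seed = 1L) {
  variant <- match.arg(variant)
  freeze_policy <- match.arg(freeze_policy)
  if (variant == "external_adapter" && is.null(weights_path))
    stop_cfg("weights_path", "is required for the external adapter variant")
  structure(list(variant = variant, base_channels = as.integer(base_channels),
                 levels = as.integer(levels), freeze_policy = freeze_policy,
                 weights_path = weights_path, seed = as.integer(seed)),
            class = "icseg_prompt_config")
}

#' Build the built-in prompt-conditioned segmentation network
#'
#' A small encoder-decoder taking four input channels — the three modality
#' channels plus a binary box-interior channel rendered from the prompt —
#' and emitting a two-channel pixelwise-softmax probability map of the same
#' spatial size as the input.
#'
#' @param config an [prompt_seg_config()] with `variant = "builtin"`.
#' @return An `icseg_prompt_segmenter`.
#' @export
builtin_prompt_net <- function(config = prompt_seg_config()) {
  stopifnot(inherits(config, "icseg_prompt_config"))
  if (config$variant != "builtin")
    stop("use sam_adapter() for the external adapter variant", call. = FALSE)
  net <- with_seed(config$seed,
    build_unet(4L, config$base_channels, levels = config$levels, out_ch = 2L))
  e <- new.env(parent = emptyenv())
  e$net <- net
  e$config <- config
  e$name <- "builtin-prompt-unet"
  e$trainable_part <- if (config$freeze_policy == "encoder") "decoder" else "all"
  e$kind <- "builtin"
  class(e) <- "icseg_prompt_segmenter"
  e
}

#' Segment a slice under a bounding-box prompt
#'
#' The generic entry point of the prompt-segmenter contract: any conforming
#' segmenter maps an H x W x 3 slice plus a box to an H x W x 2 probability
#' map, deterministically for fixed parameters and inputs.
#'
#' @param segmenter an `icseg_prompt_segmenter`.
#' @param pixels H x W x 3 pixel array (or an `icseg_slice`).
#' @param box an `icseg_bbox` prompt.
#' @return H x W x 2 array of background/foreground probabilities.
#' @export
prompt_segment <- function(segmenter, pixels, box) {
  stopifnot(inherits(segmenter, "icseg_prompt_segmenter"))
  if (inherits(pixels, "icseg_slice")) pixels <- pixels$pixels
  if (segmenter$kind == "external") return(segmenter$runner(pixels, box))
  x <- prompt_input(pixels, box)
  x <- array(x, c(dim(x), 1L))
  fw <- unet_fwd(segmenter$net, x, train = FALSE)
  aperm(array(fw$probs[, , , 1], dim(fw$probs)[1:3]), c(2, 3, 1))
}

# (4,H,W) channel-first input: modality channels plus rendered box channel.
prompt_input <- function(pixels, box) {
  d <- dim(pixels)
  x <- array(0, c(4L, d[1], d[2]))
  x[1:3, , ] <- aperm(pixels, c(3, 1, 2))
  x[4, , ] <- render_box_channel(box, W = d[2], H = d[1])
  x
}

#' Combined cross-entropy plus Dice loss for fine segmentation
#'
#' Mean binary cross-entropy of the foreground probabilities against the
#' target mask, plus the soft Dice loss. Predictions are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred foreground probabilities, H x W or H x W x N.
#' @param target binary masks of matching shape.
#' @param eps Dice smoothing constant.
#' @return Scalar loss (cross-entropy term plus Dice term).
#' @export
combined_loss <- function(pred, target, eps = 1e-5) {
  check_same_shape(pred, target, "prediction and target")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  y <- target + 0
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  bce + dice_loss(pred, target, eps)
}

# Batched loss with gradient w.r.t. the (2,H,W,B) logits: softmax
# cross-entropy gradient plus the Dice gradient.
combined_loss_grad <- function(probs, y, eps = 1e-5) {
  d <- dim(probs)
  npx <- prod(d[2:4])
  pf <- array(probs[2, , , ], d[2:4])
  dl <- dice_loss_grad(probs, y, eps)
  pc <- pmin(pmax(pf, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dz <- (pf - y) / npx
  dlog <- dl$dlogits
  # assign through as.vector: extraction drops the batch dimension when B = 1
  dlog[2, , , ] <- as.vector(dlog[2, , , ]) + as.vector(dz)
  dlog[1, , , ] <- as.vector(dlog[1, , , ]) - as.vector(dz)
  list(loss = bce + dl$loss, dlogits = dlog)
}

#' Training settings for the prompt segmentation network
#'
#' AdamW (beta1 = 0.9, beta2 = 0.999, decoupled weight decay 0.01). The
#' desk-scale default learning rate is 1e-3 because the built-in network
#' trains from random initialization; decoder-only fine-tuning of a
#' pretrained backbone would use 1e-4.
#'
#' @param epochs,batch_size loop sizes.
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay.
#' @param max_extend,max_shift box augmentation: expansion ratio drawn in
#'   `[0, max_extend]`, per-corner jitter in `[-max_shift, max_shift]` px.
#' @param val_ratio expansion ratio of the (unjittered) validation boxes.
#' @param seed RNG seed.
#' @return A config list.
#' @export
prompt_train_config <- function(epochs = 16L, batch_size = 8L, lr = 1e-3,
                                weight_decay = 0.01, max_extend = 0.6,
                                max_shift = 8L, val_ratio = 0.4, seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weight_decay = weight_decay, max_extend = max_extend,
       max_shift = as.integer(max_shift), val_ratio = val_ratio,
       seed = as.integer(seed))
}

# One training sample per 8-connected ground-truth component on slices with
# lesions; the target is the component that generated the box.
prompt_samples <- function(recs) {
  out <- list()
  for (r in recs) {
    lab <- label_components(r$mask)
    n <- attr(lab, "n")
    if (n == 0) next
    for (i in seq_len(n)) {
      comp <- lab == i
      out[[length(out) + 1L]] <- list(pixels = r$slice$pixels, target = comp,
                                      box = tight_bbox(comp))
    }
  }
  out
}

#' Train the prompt segmentation network
#'
#' Prompts are drawn from ground-truth tight boxes, randomly extended by
#' 0–60% and jittered ([augment_box_for_training()]); the target of each
#' sample is the lesion component that generated its box. Lesion-free slices
#' carry no ground-truth box and are excluded from this stage. Under
#' `freeze_policy = "encoder"` only decoder parameters are updated. The
#' checkpoint with the highest validation Dice (40%-expanded, unjittered
#' ground-truth prompts) is restored.
#'
#' @param segmenter a built-in `icseg_prompt_segmenter` (modified in place).
#' @param cohort an `icseg_cohort`.
#' @param train_config an [prompt_train_config()].
#' @return List with `segmenter`, `history` and `best_epoch`.
#' @export
train_prompt_seg <- function(segmenter, cohort,
                             train_config = prompt_train_config()) {
  stopifnot(inherits(segmenter, "icseg_prompt_segmenter"))
  if (segmenter$kind != "builtin")
    stop("only the built-in segmenter is trainable here", call. = FALSE)
  cfg <- train_config
  samp_tr <- prompt_samples(cohort_slices(cohort, "train"))
  samp_va <- prompt_samples(cohort_slices(cohort, "val"))
  if (length(samp_tr) == 0)
    stop("no training samples: every training slice is lesion-free", call. = FALSE)
  all_params <- nn_params(segmenter$net)
  params <- if (segmenter$config$freeze_policy == "encoder")
    Filter(function(p) p$group == "decoder", all_params) else all_params
  ckpt <- c(params, nn_states(segmenter$net))
  opt <- adam_init(params)
  n <- length(samp_tr)
  spe <- ceiling(n / cfg$batch_size)
  H <- nrow(samp_tr[[1]]$target); W <- ncol(samp_tr[[1]]$target)
  best <- -Inf; best_epoch <- NA_integer_; best_snap <- NULL
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_dsc = numeric(0))
  with_seed(derive_seed(cfg$seed, 303L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(spe)) {
        idx <- ord[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
        x <- array(0, c(4L, H, W, length(idx)))
        y <- array(0, c(H, W, length(idx)))
        for (b in seq_along(idx)) {
          sm <- samp_tr[[idx[b]]]
          bx <- augment_box_for_training(sm$box, W = W, H = H,
                                         max_extend = cfg$max_extend,
                                         max_shift = cfg$max_shift)
          x[, , , b] <- prompt_input(sm$pixels, bx)
          y[, , b] <- sm$target
        }
        fw <- unet_fwd(segmenter$net, x, train = TRUE)
        lg <- combined_loss_grad(fw$probs, y)
        ep_loss <- ep_loss + lg$loss
        zero_grads(all_params)
        unet_bwd(segmenter$net, lg$dlogits)
        opt <- adam_step(opt, params, cfg$lr, weight_decay = cfg$weight_decay)
      }
      val_dsc <- if (length(samp_va)) {
        mean(vapply(samp_va, function(sm) {
          bx <- expand_bbox(sm$box, cfg$val_ratio, W, H)
          pm <- prompt_segment(segmenter, sm$pixels, bx)
          dice_coefficient(pm[, , 2] > 0.5, sm$target)
        }, numeric(1)))
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / spe,
                                     val_dsc = val_dsc))
      score <- if (is.na(val_dsc)) -ep_loss else val_dsc
      if (score > best) {
        best <- score; best_epoch <- ep
        best_snap <- snapshot_params(ckpt)
      }
    }
  })
  restore_params(ckpt, best_snap)
  list(segmenter = segmenter, history = hist, best_epoch = best_epoch)
}

#' Wrap an external promptable segmentation model
#'
#' Adapts an externally trained promptable model (a SAM-style image encoder /
#' prompt encoder / mask decoder stack) to the prompt-segmenter contract so
#' the cascade can consume it interchangeably with the built-in network. The
#' weights are not shipped with this package; a missing weights file raises
#' an explicit external-dependency error.
#'
#' @param weights_path path to the external weights.
#' @param runner function `(pixels, box) -> H x W x 2 probability array`
#'   implementing the external model's inference; the default placeholder
#'   stops with an informative error, so supplying a runner is required for
#'   actual use.
#' @return An `icseg_prompt_segmenter` of kind `"external"`.
#' @export
sam_adapter <- function(weights_path, runner = NULL) {
  if (!file.exists(weights_path))
    stop(sprintf("external dependency missing: weights file '%s' not found",
                 weights_path), call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$name <- "external-adapter"
  e$kind <- "external"
  e$weights_path <- weights_path
  e$trainable_part <- "decoder"
  e$runner <- runner %||% function(pixels, box)
    stop("external adapter requires a runner function", call. = FALSE)
  class(e) <- "icseg_prompt_segmenter"
  e
}
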