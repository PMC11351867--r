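# Cascade orchestration: coarse prediction -> quality score -> gate ->
# box provisioning (manual-simulated or automatic) -> prompt-conditioned
# fine segmentation -> final mask, with full provenance, plus cohort
# evaluation and the threshold sweep of the workload/accuracy trade-off.

#' Run the full cascade on one slice
#'
#' The coarse network segments the slice; the rejection network scores the
#' result; the gate routes the slice: on the AUTO path one expanded box per
#' 8-connected component of the binarized coarse mask prompts the fine
#' segmenter (an empty coarse mask yields an empty final mask without
#' invoking the segmenter); on the MANUAL path boxes come from the manual
#' provider (by default, simulation from ground truth — the reproducible
#' stand-in for a human drawing a box around each lesion). Fine masks from
#' all boxes are unioned.
#'
#' @param record a list with `slice` (an `icseg_slice`) and optionally
#'   `mask` (ground truth, needed for the simulated manual provider and for
#'   the quality target).
#' @param coarse_model,reject_model,segmenter trained cascade components.
#' @param gate_cfg an [gate_config()].
#' @param manual_box_provider function `record -> list of icseg_bbox`; the
#'   default simulates manual boxes from `record$mask`.
#' @param expansion_ratio box expansion ratio (default 0.4).
#' @param coarse_pred,score optional precomputed coarse prediction and
#'   quality score (used by the cached sweep; `score` may also be forced for
#'   routing tests).
#' @return An `icseg_cascade_result`: slice id, coarse mask, score, decision,
#'   boxes used (with source), final mask, and the coarse Dice target when
#'   ground truth is available.
#' @export
run_cascade <- function(record, coarse_model, reject_model, segmenter,
                        gate_cfg, manual_box_provider = NULL,
                        expansion_ratio = 0.4,
                        coarse_pred = NULL, score = NULL) {
  slice <- record$slice
  H <- dim(slice$pixels)[1]; W <- dim(slice$pixels)[2]
  if (is.null(coarse_pred))
    coarse_pred <- predict_coarse(coarse_model, list(slice))[[1]]
  if (is.null(score))
    score <- predict_quality(reject_model, list(coarse_pred))
  decision <- gate(score, gate_cfg)
  if (decision == "MANUAL") {
    if (is.null(manual_box_provider)) {
      if (is.null(record$mask))
        stop("interaction required: MANUAL decision but no manual box provider",
             call. = FALSE)
      boxes <- simulate_manual_box(record$mask, expansion_ratio, W, H)
    } else {
      boxes <- manual_box_provider(record)
    }
    source <- "MANUAL"
  } else {
    boxes <- cascade_auto_boxes(coarse_pred$mask, expansion_ratio, W, H)
    source <- "AUTO"
  }
  final <- matrix(FALSE, H, W)
  if (length(boxes)) {
    for (bx in boxes) {
      pm <- prompt_segment(segmenter, slice$pixels, bx)
      final <- final | (pm[, , 2] > 0.5)
    }
  }
  structure(list(patient_id = slice$patient_id,
                 slice_index = slice$slice_index,
                 coarse_mask = coarse_pred$mask,
                 score = score, decision = decision,
                 boxes = boxes, box_source = source,
                 final_mask = final,
                 d = if (!is.null(record$mask))
                   quality_target(coarse_pred$mask, record$mask) else NA_real_),
            class = "icseg_cascade_result")
}

cascade_auto_boxes <- function(coarse_mask, expansion_ratio, W, H) {
  lab <- label_components(coarse_mask)
  n <- attr(lab, "n")
  if (n == 0) return(list())
  lapply(seq_len(n), function(i)
    expand_bbox(tight_bbox(lab == i), expansion_ratio, W, H))
}

# Precompute everything that does not depend on the gate threshold: coarse
# predictions, quality scores, and the final masks of both routing paths.
# A sweep over thresholds then only selects between cached masks, which is
# exactly equivalent to running the cascade per threshold.
build_cascade_cache <- function(records, coarse_model, reject_model,
                                segmenter, manual_box_provider = NULL,
                                expansion_ratio = 0.4) {
  preds <- predict_coarse(coarse_model, records)
  scores <- predict_quality(reject_model, preds)
  H <- dim(records[[1]]$slice$pixels)[1]
  W <- dim(records[[1]]$slice$pixels)[2]
  per <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    fine_union <- function(boxes) {
      m <- matrix(FALSE, H, W)
      for (bx in boxes)
        m <- m | (prompt_segment(segmenter, r$slice$pixels, bx)[, , 2] > 0.5)
      m
    }
    aboxes <- cascade_auto_boxes(preds[[i]]$mask, expansion_ratio, W, H)
    mboxes <- if (!is.null(manual_box_provider)) manual_box_provider(r)
      else if (!is.null(r$mask)) simulate_manual_box(r$mask, expansion_ratio, W, H)
      else stop("interaction required: no manual box provider and no ground truth",
                call. = FALSE)
    per[[i]] <- list(pred = preds[[i]], score = scores[i],
                     auto_boxes = aboxes, manual_boxes = mboxes,
                     auto_mask = fine_union(aboxes),
                     manual_mask = fine_union(mboxes),
                     d = if (!is.null(r$mask))
                       quality_target(preds[[i]]$mask, r$mask) else NA_real_)
  }
  structure(list(records = records, per = per, scores = scores,
                 expansion_ratio = expansion_ratio), class = "icseg_cache")
}

#' Evaluate the cascade on a cohort split
#'
#' Runs the full cascade on every test slice at gate threshold `t` and
#' assembles per-image metrics (Dice, 95% HD with undefined pairs excluded
#' and counted), the quality-regression R-squared over (score, target)
#' pairs, the rejection ratio, and lesion-level detection scores computed on
#' 3D per-patient volumes with counts pooled across patients.
#'
#' @param cohort an `icseg_cohort` (its test split is evaluated) or a list of
#'   slice records.
#' @param coarse_model,reject_model,segmenter trained cascade components.
#' @param gate_cfg an [gate_config()].
#' @param manual_box_provider optional manual box callback.
#' @param expansion_ratio box expansion ratio.
#' @param tau lesion-level overlap threshold.
#' @param cache optional precomputed cascade cache (from a sweep).
#' @return An `icseg_eval_report`.
#' @export
run_cohort <- function(cohort, coarse_model, reject_model, segmenter,
                       gate_cfg, manual_box_provider = NULL,
                       expansion_ratio = 0.4, tau = 0.1, cache = NULL) {
  records <- if (inherits(cohort, "icseg_cohort"))
    cohort_slices(cohort, "test") else cohort
  if (length(records) == 0) stop("test split is empty", call. = FALSE)
  if (is.null(cache))
    cache <- build_cascade_cache(records, coarse_model, reject_model,
                                 segmenter, manual_box_provider,
                                 expansion_ratio)
  t <- gate_cfg$threshold
  n <- length(cache$per)
  decision <- gate(cache$scores, gate_cfg)
  spacing <- records[[1]]$slice$spacing_mm
  dice <- numeric(n); hd <- numeric(n); dtar <- numeric(n)
  finals <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cache$per[[i]]
    finals[[i]] <- if (decision[i] == "MANUAL") p$manual_mask else p$auto_mask
    dice[i] <- dice_coefficient(finals[[i]], records[[i]]$mask)
    hd[i] <- hd95(finals[[i]], records[[i]]$mask, spacing)
    dtar[i] <- p$d
  }
  pid <- vapply(records, `[[`, character(1), "patient_id")
  lesion <- pool_lesion_scores(records, finals, pid, tau)
  r2 <- if (length(unique(dtar)) > 1) r_squared(cache$scores, dtar) else NA_real_
  per_image <- data.frame(patient_id = pid,
                          slice_index = vapply(records, `[[`, integer(1), "slice_index"),
                          score = cache$scores, target = dtar,
                          decision = decision, dice = dice, hd95 = hd)
  structure(list(
    threshold = t,
    per_image = per_image,
    mean_dsc = mean(dice), sd_dsc = sd(dice),
    mean_hd95 = mean(hd, na.rm = TRUE), sd_hd95 = sd(hd, na.rm = TRUE),
    hd95_excluded = sum(is.na(hd)),
    r2 = r2,
    rejection_ratio = rejection_ratio(cache$scores, t),
    lesion = lesion,
    cache = cache
  ), class = "icseg_eval_report")
}

pool_lesion_scores <- function(records, finals, pid, tau) {
  counts <- c(tp_gt = 0L, n_gt = 0L, tp_pred = 0L, n_pred = 0L)
  for (p in unique(pid)) {
    idx <- which(pid == p)
    idx <- idx[order(vapply(records[idx], `[[`, integer(1), "slice_index"))]
    H <- nrow(records[[idx[1]]]$mask); W <- ncol(records[[idx[1]]]$mask)
    gt <- array(FALSE, c(H, W, length(idx)))
    pr <- array(FALSE, c(H, W, length(idx)))
    for (k in seq_along(idx)) {
      gt[, , k] <- records[[idx[k]]]$mask
      pr[, , k] <- finals[[idx[k]]]
    }
    sc <- lesion_level_scores(gt, pr, tau)
    counts <- counts + c(sc$tp_gt, sc$n_gt, sc$tp_pred, sc$n_pred)
  }
  tpr <- if (counts["n_gt"] > 0) counts[["tp_gt"]] / counts[["n_gt"]] else NA_real_
  ppv <- if (counts["n_pred"] > 0) counts[["tp_pred"]] / counts[["n_pred"]] else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv)) f1_score(ppv, tpr) else NA_real_
  list(tpr = tpr, ppv = ppv, f1 = f1, counts = as.list(counts))
}

#' @export
print.icseg_eval_report <- function(x, ...) {
  cat(sprintf("<icseg_eval_report t=%.2f: %d images>\n", x$threshold,
              nrow(x$per_image)))
  cat(sprintf("  DSC  %.3f +/- %.3f\n", x$mean_dsc, x$sd_dsc))
  cat(sprintf("  95%%HD %.2f +/- %.2f mm (%d undefined pairs excluded)\n",
              x$mean_hd95, x$sd_hd95, x$hd95_excluded))
  cat(sprintf("  rejection ratio %.3f, quality R^2 %s\n", x$rejection_ratio,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  cat(sprintf("  lesion-level TPR %.3f PPV %.3f F1 %.3f\n",
              x$lesion$tpr, x$lesion$ppv, x$lesion$f1))
  invisible(x)
}

#' Sweep the gate threshold and trace the workload/accuracy trade-off
#'
#' Computes coarse predictions, quality scores and both routing paths' fine
#' masks once, then evaluates every threshold of the grid against the cache
#' — each row is identical to a direct [run_cohort()] at that threshold. The
#' rejection ratio is non-decreasing along the grid.
#'
#' @param cohort cohort or record list (as in [run_cohort()]).
#' @param coarse_model,reject_model,segmenter trained cascade components.
#' @param t_grid ascending threshold grid.
#' @param manual_box_provider,expansion_ratio,tau as in [run_cohort()].
#' @return A list with `curve` (data frame: t, rejection_ratio, mean_dsc,
#'   mean_hd95) and `reports` (one `icseg_eval_report` per threshold).
#' @export
sweep_thresholds <- function(cohort, coarse_model, reject_model, segmenter,
                             t_grid, manual_box_provider = NULL,
                             expansion_ratio = 0.4, tau = 0.1) {
  if (is.unsorted(t_grid)) stop("t_grid must be sorted ascending", call. = FALSE)
  records <- if (inherits(cohort, "icseg_cohort"))
    cohort_slices(cohort, "test") else cohort
  cache <- build_cascade_cache(records, coarse_model, reject_model,
                               segmenter, manual_box_provider,
                               expansion_ratio)
  reports <- lapply(t_grid, function(t)
    run_cohort(records, coarse_model, reject_model, segmenter,
               gate_config(t), manual_box_provider = manual_box_provider,
               expansion_ratio = expansion_ratio, tau = tau, cache = cache))
  curve <- data.frame(
    t = t_grid,
    rejection_ratio = vapply(reports, `[[`, numeric(1), "rejection_ratio"),
    mean_dsc = vapply(reports, `[[`, numeric(1), "mean_dsc"),
    mean_hd95 = vapply(reports, `[[`, numeric(1), "mean_hd95"))
  list(curve = curve, reports = reports)
}
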