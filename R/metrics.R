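# Evaluation metrics: Dice similarity, 95th-percentile Hausdorff distance,
# lesion-level detection scores over 3D connected components, R-squared for
# the quality regression, rejection ratio, and paired comparisons.

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  storage.mode(m) <- "logical"
  m
}

#' Dice similarity coefficient between two binary masks
#'
#' `DSC = 2|P ∩ G| / (|P| + |G|)`. The degenerate conventions are: both masks
#' empty gives 1 (a correct negative at image level), exactly one empty gives
#' 0.
#'
#' @param P,G binary masks (logical arrays of identical shape).
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
#' b <- matrix(FALSE, 8, 8); b[2:3, 3:4] <- TRUE
#' dice_coefficient(a, b)  # 0.5
#' @export
dice_coefficient <- function(P, G) {
  check_same_shape(P, G)
  P <- as_mask(P); G <- as_mask(G)
  sp <- sum(P); sg <- sum(G)
  if (sp + sg == 0) return(1)
  2 * sum(P & G) / (sp + sg)
}

# Boundary pixels: mask pixels with at least one 4-neighbour outside the mask
# (image border counts as outside).
boundary_pixels <- function(m) {
  m <- as_mask(m)
  H <- nrow(m); W <- ncol(m)
  interior <- matrix(FALSE, H, W)
  if (H > 2 && W > 2) {
    interior[2:(H - 1), 2:(W - 1)] <-
      m[1:(H - 2), 2:(W - 1)] & m[3:H, 2:(W - 1)] &
      m[2:(H - 1), 1:(W - 2)] & m[2:(H - 1), 3:W]
  }
  m & !interior
}

#' 95th-percentile Hausdorff distance between two masks (mm)
#'
#' Boundary pixels are mask pixels with at least one 4-neighbour outside the
#' mask. Directed nearest-boundary Euclidean distances are computed in
#' physical units in both directions (via an exact distance transform) and
#' the statistic is the 95th percentile, with linear interpolation, of the
#' union of the two directed distance sets — an outlier-robust variant of the
#' Hausdorff distance, and symmetric in its arguments.
#'
#' @param P,G binary masks (logical matrices of identical shape).
#' @param spacing_mm pixel spacing `(row, col)` in mm.
#' @param percentile percentile of the pooled distances (default 0.95).
#' @return Distance in mm, or `NA_real_` when either mask is empty (the
#'   statistic is undefined; callers exclude and count such pairs).
#' @export
hd95 <- function(P, G, spacing_mm = c(1, 1), percentile = 0.95) {
  check_same_shape(P, G)
  P <- as_mask(P); G <- as_mask(G)
  if (sum(P) == 0 || sum(G) == 0) return(NA_real_)
  bp <- boundary_pixels(P)
  bg <- boundary_pixels(G)
  dg <- sqrt(pmax(cpp_edt_sq(bg, spacing_mm[1], spacing_mm[2]), 0))
  dp <- sqrt(pmax(cpp_edt_sq(bp, spacing_mm[1], spacing_mm[2]), 0))
  d_pg <- dg[bp]   # from each boundary pixel of P to nearest boundary of G
  d_gp <- dp[bg]
  unname(quantile(c(d_pg, d_gp), percentile, type = 7))
}

# Connected-component labelling for 2D (8-connectivity) or 3D
# (26-connectivity) logical arrays. Returns an integer array of labels
# (0 = background) with attribute "n" giving the component count.
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array", call. = FALSE)
  if (length(d) == 2) d <- c(d, 1L)
  m <- array(as.logical(mask), d)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nlab <- 0L
  idx_all <- which(m)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, d)
      ny <- ai[1] + offs[, 1]; nx <- ai[2] + offs[, 2]; nz <- ai[3] + offs[, 3]
      ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
      ni <- ny[ok] + d[1] * (nx[ok] - 1) + d[1] * d[2] * (nz[ok] - 1)
      ni <- ni[m[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- nlab
        queue <- c(queue, ni)
      }
    }
  }
  if (length(dim(mask)) == 2) dim(lab) <- dim(mask)
  attr(lab, "n") <- nlab
  lab
}

#' Lesion-level detection scores over 3D connected components
#'
#' Each lesion is a 26-connected 3D component. A ground-truth component
#' counts as detected (TP for recall) when the summed overlap fraction with
#' all predicted components reaches `tau`; a predicted component counts as a
#' TP for precision symmetrically. `F1` combines the two rates. Volumes
#' without ground-truth lesions contribute no recall denominator and volumes
#' without predictions contribute no precision denominator; the returned
#' counts support pooling across volumes.
#'
#' @param gt_volume,pred_volume aligned 3D logical arrays (H x W x slices).
#' @param tau overlap threshold in \[0, 1\] (default 0.1, chosen low because
#'   lesion extent is subject to substantial inter-observer variability).
#' @return A list with `tpr`, `ppv`, `f1` (possibly `NA` when undefined) and
#'   the pooled counts `tp_gt`, `n_gt`, `tp_pred`, `n_pred`.
#' @export
lesion_level_scores <- function(gt_volume, pred_volume, tau = 0.1) {
  check_same_shape(gt_volume, pred_volume, "volumes")
  if (tau < 0 || tau > 1) stop_cfg("tau", "must lie in [0, 1]")
  gt <- as_mask(gt_volume); pr <- as_mask(pred_volume)
  lg <- label_components(gt)
  lp <- label_components(pr)
  ng <- attr(lg, "n"); np <- attr(lp, "n")
  tp_gt <- 0L
  for (i in seq_len(ng)) {
    comp <- lg == i
    if (sum(comp & pr) / sum(comp) >= tau) tp_gt <- tp_gt + 1L
  }
  tp_pred <- 0L
  for (j in seq_len(np)) {
    comp <- lp == j
    if (sum(comp & gt) / sum(comp) >= tau) tp_pred <- tp_pred + 1L
  }
  tpr <- if (ng > 0) tp_gt / ng else NA_real_
  ppv <- if (np > 0) tp_pred / np else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv)) f1_score(ppv, tpr) else NA_real_
  list(tpr = tpr, ppv = ppv, f1 = f1,
       tp_gt = tp_gt, n_gt = ng, tp_pred = tp_pred, n_pred = np)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; 0 by convention when both are 0.
#' @param precision,recall rates in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Coefficient of determination of the quality regression
#'
#' `R^2 = 1 - sum((d - s)^2) / sum((d - mean(d))^2)` where `s` are predicted
#' quality scores and `d` the observed Dice targets.
#'
#' @param s predicted scores.
#' @param d observed targets (must not be constant).
#' @return R-squared (at most 1; can be negative for poor predictors).
#' @export
r_squared <- function(s, d) {
  if (length(s) != length(d)) stop("s and d must have equal length", call. = FALSE)
  if (length(d) < 2) stop("need at least two observations", call. = FALSE)
  tss <- sum((d - mean(d))^2)
  if (tss == 0)
    stop("R-squared undefined: targets have zero variance", call. = FALSE)
  1 - sum((d - s)^2) / tss
}

#' Fraction of images routed to manual interaction at threshold t
#'
#' Counts scores strictly below `t` (a score exactly at the threshold is not
#' rejected, consistent with [gate()]).
#'
#' @param s predicted quality scores.
#' @param t gate threshold.
#' @return Fraction in \[0, 1\].
#' @export
rejection_ratio <- function(s, t) {
  if (length(s) == 0) stop("empty score vector", call. = FALSE)
  mean(s < t)
}

#' Two-sided paired t-test on per-image metrics
#'
#' Thin wrapper around [stats::t.test()] that handles the degenerate
#' zero-variance cases a metric comparison can produce: identical vectors
#' give statistic 0 and p = 1; a constant non-zero shift is flagged as
#' degenerate rather than reported with a spurious p-value.
#'
#' @param a,b paired metric vectors of equal length (>= 2).
#' @return List with `statistic`, `p.value` and `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least two pairs", call. = FALSE)
  dif <- a - b
  if (sd(dif) < 1e-12) {
    if (all(abs(dif) < 1e-12))
      return(list(statistic = 0, p.value = 1, degenerate = TRUE))
    return(list(statistic = NA_real_, p.value = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       degenerate = FALSE)
}
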