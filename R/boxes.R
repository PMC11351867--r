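# Bounding-box logic: tight extraction from masks, ratio expansion, manual
# prompt simulation from ground truth, and training-time box augmentation.
#
# Coordinate convention (used throughout the package): 0-based pixel indices,
# half-open intervals. x indexes columns, y indexes rows, so a box covers
# columns [x0, x1) and rows [y0, y1) of the image.

#' Construct an axis-aligned bounding box
#'
#' @param x0,y0 upper-left corner (0-based, inclusive).
#' @param x1,y1 lower-right corner (exclusive).
#' @param W,H optional image extent for validation.
#' @return An object of class `icseg_bbox`.
#' @export
bounding_box <- function(x0, y0, x1, y1, W = NULL, H = NULL) {
  b <- list(x0 = as.integer(x0), y0 = as.integer(y0),
            x1 = as.integer(x1), y1 = as.integer(y1))
  if (b$x0 < 0 || b$y0 < 0 || b$x0 >= b$x1 || b$y0 >= b$y1)
    stop("invalid bounding box: need 0 <= x0 < x1 and 0 <= y0 < y1", call. = FALSE)
  if (!is.null(W) && b$x1 > W) stop("bounding box exceeds image width", call. = FALSE)
  if (!is.null(H) && b$y1 > H) stop("bounding box exceeds image height", call. = FALSE)
  class(b) <- "icseg_bbox"
  b
}

#' @export
print.icseg_bbox <- function(x, ...) {
  cat(sprintf("<bbox [%d,%d) x [%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Minimal axis-aligned box containing all foreground pixels
#'
#' @param mask logical matrix.
#' @return An `icseg_bbox`, or `NULL` when the mask is empty.
#' @export
tight_bbox <- function(mask) {
  idx <- which(as_mask(mask), arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  bounding_box(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
               x1 = max(idx[, 2]), y1 = max(idx[, 1]))
}

#' Expand a bounding box by a width/height ratio
#'
#' Width and height each grow by `ratio` in total (`ratio/2` per side); the
#' expanded endpoints are rounded outward (floor on the low edge, ceiling on
#' the high edge) so lesion boundary pixels are never cropped, then clipped
#' to the image. The default framework setting is `ratio = 0.4` (a 40%
#' expansion), which gives the coarse mask a margin of error and reduces
#' sensitivity to the precision of a manual box.
#'
#' @param box an `icseg_bbox`.
#' @param ratio nonnegative expansion ratio.
#' @param W,H image extent.
#' @return The expanded, clipped `icseg_bbox`.
#' @export
expand_bbox <- function(box, ratio, W, H) {
  stopifnot(inherits(box, "icseg_bbox"))
  if (ratio < 0) stop_cfg("ratio", "must be nonnegative")
  px <- ratio * (box$x1 - box$x0) / 2
  py <- ratio * (box$y1 - box$y0) / 2
  bounding_box(x0 = max(0, floor(box$x0 - px)),
               y0 = max(0, floor(box$y0 - py)),
               x1 = min(W, ceiling(box$x1 + px)),
               y1 = min(H, ceiling(box$y1 + py)),
               W = W, H = H)
}

#' Simulate manual bounding-box prompts from a ground-truth mask
#'
#' Emulates a user drawing a box around each lesion: one tight box per
#' 8-connected component of the mask, expanded by `ratio` (default 40%).
#'
#' @param gt logical ground-truth mask.
#' @param ratio expansion ratio.
#' @param W,H image extent (defaults to the mask's own).
#' @return A list of `icseg_bbox` (empty list for an empty mask).
#' @export
simulate_manual_box <- function(gt, ratio = 0.4, W = ncol(gt), H = nrow(gt)) {
  lab <- label_components(as_mask(gt))
  n <- attr(lab, "n")
  if (n == 0) return(list())
  lapply(seq_len(n), function(i)
    expand_bbox(tight_bbox(lab == i), ratio, W, H))
}

#' Randomly extend and perturb a box for prompt-network training
#'
#' Draws an expansion ratio uniformly in `[0, max_extend]` (default 0–60%),
#' applies [expand_bbox()], then shifts each corner coordinate independently
#' by an integer drawn uniformly in `[-max_shift, max_shift]` (default 0–20
#' pixels of perturbation), re-clips to the image, and repairs degenerate
#' boxes to a minimum size of 2 x 2. Uses the current RNG stream; seed the
#' caller for reproducibility.
#'
#' @param box an `icseg_bbox`.
#' @param W,H image extent.
#' @param max_extend maximum expansion ratio.
#' @param max_shift maximum absolute corner shift in pixels.
#' @return A valid `icseg_bbox`.
#' @export
augment_box_for_training <- function(box, W, H, max_extend = 0.6,
                                     max_shift = 20L) {
  ratio <- runif(1, 0, max_extend)
  b <- expand_bbox(box, ratio, W, H)
  sh <- sample.int(2L * max_shift + 1L, 4L, replace = TRUE) - max_shift - 1L
  x0 <- max(0L, min(b$x0 + sh[1], W - 2L))
  y0 <- max(0L, min(b$y0 + sh[2], H - 2L))
  x1 <- max(x0 + 2L, min(b$x1 + sh[3], W))
  y1 <- max(y0 + 2L, min(b$y1 + sh[4], H))
  x0 <- min(x0, x1 - 2L)
  y0 <- min(y0, y1 - 2L)
  bounding_box(x0, y0, x1, y1, W = W, H = H)
}

# Render the interior of a box as a binary H x W matrix (the prompt channel
# consumed by the built-in fine segmentation network).
render_box_channel <- function(box, W, H) {
  m <- matrix(0, H, W)
  m[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1] <- 1
  m
}
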