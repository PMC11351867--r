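test_that("tight_bbox extracts minimal half-open boxes", {
  m <- matrix(FALSE, 10, 12)
  expect_null(tight_bbox(m))
  m[6, 8] <- TRUE  # row 5, col 7 in 0-based coordinates
  b <- tight_bbox(m)
  expect_equal(c(b$x0, b$y0, b$x1, b$y1), c(7, 5, 8, 6))
  all_true <- matrix(TRUE, 10, 12)
  b2 <- tight_bbox(all_true)
  expect_equal(c(b2$x0, b2$y0, b2$x1, b2$y1), c(0, 0, 12, 10))
})

test_that("expand_bbox grows by ratio with outward rounding and clipping", {
  b <- bounding_box(10, 10, 20, 20)
  expect_equal(unclass(expand_bbox(b, 0, 64, 64))[1:4],
               unclass(b)[1:4])
  e <- expand_bbox(b, 0.4, 64, 64)
  expect_equal(c(e$x0, e$y0, e$x1, e$y1), c(8, 8, 22, 22))
  corner <- bounding_box(0, 0, 10, 10)
  ec <- expand_bbox(corner, 0.4, 64, 64)
  expect_equal(c(ec$x0, ec$y0, ec$x1, ec$y1), c(0, 0, 12, 12))
})

test_that("expansion is monotone and containing", {
  set.seed(2)
  for (i in 1:50) {
    x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
    b <- bounding_box(x0, y0, x0 + sample(1:20, 1), y0 + sample(1:20, 1))
    r1 <- runif(1, 0, 0.5); r2 <- r1 + runif(1, 0, 0.5)
    e1 <- expand_bbox(b, r1, 64, 64)
    e2 <- expand_bbox(b, r2, 64, 64)
    expect_true(e1$x0 <= b$x0 && e1$y0 <= b$y0 &&
                e1$x1 >= min(b$x1, 64) && e1$y1 >= min(b$y1, 64))
    expect_true(e2$x0 <= e1$x0 && e2$y0 <= e1$y0 &&
                e2$x1 >= e1$x1 && e2$y1 >= e1$y1)
  }
})

test_that("simulate_manual_box yields one expanded box per component, covering gt", {
  gt <- matrix(FALSE, 32, 32)
  gt[4:8, 4:8] <- TRUE
  gt[20:26, 18:25] <- TRUE
  boxes <- simulate_manual_box(gt)
  expect_length(boxes, 2)
  single <- matrix(FALSE, 32, 32); single[10:14, 9:15] <- TRUE
  b <- simulate_manual_box(single)[[1]]
  ref <- expand_bbox(tight_bbox(single), 0.4, 32, 32)
  expect_equal(unclass(b)[1:4], unclass(ref)[1:4])
  expect_length(simulate_manual_box(matrix(FALSE, 8, 8)), 0)
  # joint coverage of every true pixel
  covered <- matrix(FALSE, 32, 32)
  for (bx in boxes)
    covered[(bx$y0 + 1):bx$y1, (bx$x0 + 1):bx$x1] <- TRUE
  expect_true(all(covered[gt]))
})

test_that("box augmentation always produces valid boxes", {
  set.seed(4)
  W <- 48L; H <- 48L
  for (i in 1:1000) {
    x0 <- sample(0:(W - 3), 1); y0 <- sample(0:(H - 3), 1)
    b <- bounding_box(x0, y0, min(W, x0 + sample(2:20, 1)),
                      min(H, y0 + sample(2:20, 1)))
    a <- augment_box_for_training(b, W, H)
    expect_true(a$x0 >= 0 && a$y0 >= 0 && a$x1 <= W && a$y1 <= H)
    expect_true(a$x1 - a$x0 >= 2 && a$y1 - a$y0 >= 2)
  }
  # corner box with extreme shifts stays valid
  corner <- bounding_box(0, 0, 3, 3)
  for (i in 1:200) {
    a <- augment_box_for_training(corner, 24, 24, max_shift = 30)
    expect_true(a$x0 >= 0 && a$x1 <= 24 && a$x1 - a$x0 >= 2)
  }
})

test_that("box constructor validates the coordinate convention", {
  expect_error(bounding_box(5, 0, 5, 4), "invalid")
  expect_error(bounding_box(-1, 0, 4, 4), "invalid")
  expect_error(bounding_box(0, 0, 9, 4, W = 8), "width")
})
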