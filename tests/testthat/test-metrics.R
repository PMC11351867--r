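test_that("dice coefficient matches hand-computed overlaps and conventions", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 8, 8); b[6:7, 6:7] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  shifted <- matrix(FALSE, 8, 8); shifted[2:3, 3:4] <- TRUE  # one column over
  expect_equal(dice_coefficient(a, shifted), 0.5)            # 2*2/(4+4)
  empty <- matrix(FALSE, 8, 8)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  expect_equal(dice_coefficient(a, shifted), dice_coefficient(shifted, a))
  expect_error(dice_coefficient(a, matrix(FALSE, 4, 4)), "shape")
})

test_that("hd95 matches the brute-force all-pairs oracle on constructed cases", {
  m <- matrix(FALSE, 16, 16); m[5:9, 5:9] <- TRUE
  expect_equal(hd95(m, m, c(1, 1)), 0)
  # two single pixels three columns apart: every distance is 3
  p <- matrix(FALSE, 9, 9); p[5, 3] <- TRUE
  g <- matrix(FALSE, 9, 9); g[5, 6] <- TRUE
  expect_equal(hd95(p, g, c(1, 1)), 3)
  expect_equal(hd95(p, g, c(2, 2)), 6)  # linear in physical spacing
  # undefined when either mask is empty
  expect_true(is.na(hd95(p, matrix(FALSE, 9, 9), c(1, 1))))
  set.seed(7)
  for (i in 1:40) {
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    sp <- runif(2, 0.3, 2)
    P <- random_blob_mask(H, W); G <- random_blob_mask(H, W)
    if (sum(P) == 0 || sum(G) == 0) next
    expect_equal(hd95(P, G, sp), hd95_oracle(P, G, sp), tolerance = 1e-10)
    expect_equal(hd95(P, G, sp), hd95(G, P, sp))  # symmetric by construction
  }
})

test_that("hd95 is bounded by the exact Hausdorff distance", {
  set.seed(11)
  for (i in 1:20) {
    P <- random_blob_mask(20, 20, 0); G <- random_blob_mask(20, 20, 0)
    h95 <- hd95(P, G, c(1, 1))
    hmax <- hd95_oracle(P, G, c(1, 1), percentile = 1)
    expect_lte(h95, hmax + 1e-12)
  }
})

test_that("lesion-level scores follow the overlap-threshold rules", {
  v <- array(FALSE, c(10, 10, 4)); v[3:5, 3:5, 2:3] <- TRUE
  sc <- lesion_level_scores(v, v)
  expect_equal(c(sc$tpr, sc$ppv, sc$f1), c(1, 1, 1))
  # gt lesion of 10 voxels vs a 20-voxel prediction overlapping 1 voxel at
  # tau = 0.1: coverage 1/10 >= 0.1 so recall 1; 1/20 < 0.1 so precision 0
  gt <- array(FALSE, c(6, 6, 2)); gt[2:6, 2, 1] <- TRUE; gt[2:6, 2, 2] <- TRUE
  pr <- array(FALSE, c(6, 6, 2)); pr[2, 2:6, 1] <- TRUE; pr[c(3, 4), 3:5, 1] <- TRUE
  pr[2, 3:6, 2] <- TRUE; pr[5, 3:5, 2] <- TRUE; pr[6, 4:5, 2] <- TRUE
  stopifnot(sum(gt) == 10, sum(pr) == 20, sum(gt & pr) == 1)
  sc <- lesion_level_scores(gt, pr, tau = 0.1)
  expect_equal(sc$tpr, 1)
  expect_equal(sc$ppv, 0)
  expect_equal(sc$f1, 0)
  # rates are non-increasing in tau
  set.seed(3)
  g3 <- array(random_blob_mask(12, 12, 0), c(12, 12, 3))
  p3 <- array(random_blob_mask(12, 12, 0), c(12, 12, 3))
  taus <- c(0.01, 0.1, 0.3, 0.6, 0.9)
  scs <- lapply(taus, function(tt) lesion_level_scores(g3, p3, tt))
  tprs <- vapply(scs, `[[`, numeric(1), "tpr")
  ppvs <- vapply(scs, `[[`, numeric(1), "ppv")
  expect_true(all(diff(tprs) <= 1e-12))
  expect_true(all(diff(ppvs) <= 1e-12))
  # every emitted triple satisfies the F1 formula
  for (s in scs) {
    if (s$tpr + s$ppv > 0)
      expect_equal(s$f1, 2 * s$tpr * s$ppv / (s$tpr + s$ppv), tolerance = 1e-12)
  }
})

test_that("zero-lesion volumes contribute no denominators", {
  empty <- array(FALSE, c(8, 8, 2))
  one <- array(FALSE, c(8, 8, 2)); one[3:4, 3:4, 1] <- TRUE
  sc <- lesion_level_scores(empty, one)
  expect_true(is.na(sc$tpr))
  expect_equal(sc$n_gt, 0L)
  expect_equal(sc$ppv, 0)
  sc2 <- lesion_level_scores(one, empty)
  expect_true(is.na(sc2$ppv))
  expect_equal(sc2$tpr, 0)
})

test_that("f1 score is the harmonic mean with the 0/0 convention", {
  expect_equal(f1_score(0.4, 0.4), 0.4)
  expect_equal(f1_score(0, 1), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_error(f1_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("r_squared follows its defining identity", {
  d <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(r_squared(d, d), 1)
  expect_equal(r_squared(rep(mean(d), 4), d), 0)
  expect_equal(r_squared(c(0.2, 0.4), c(0.3, 0.5)), 0)  # 1 - 0.02/0.02
  expect_error(r_squared(c(0.1, 0.2), c(0.5, 0.5)), "variance")
  expect_error(r_squared(0.1, 0.5), "two")
})

test_that("rejection ratio counts strictly-below scores", {
  expect_equal(rejection_ratio(c(0.5, 0.6), 0.4), 0)
  expect_equal(rejection_ratio(c(0.3, 0.5, 0.9), 0.4), 1 / 3)
  expect_equal(rejection_ratio(c(0.4, 0.5), 0.4), 0)  # boundary not rejected
  expect_error(rejection_ratio(numeric(0), 0.4), "empty")
  # non-decreasing step function with steps only at observed scores
  s <- c(0.2, 0.5, 0.7)
  grid <- seq(0, 1.1, by = 0.01)
  rr <- vapply(grid, function(t) rejection_ratio(s, t), numeric(1))
  expect_true(all(diff(rr) >= 0))
  expect_setequal(unique(rr), c(0, 1 / 3, 2 / 3, 1))
})

test_that("paired t-test handles degenerate and regular cases", {
  a <- c(0.2, 0.5, 0.8, 0.4)
  r <- paired_t_test(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r2 <- paired_t_test(a + 1, a)   # zero-variance nonzero shift
  expect_true(r2$degenerate)
  set.seed(1)
  x <- rnorm(1000); y <- x + 0.2 + rnorm(1000, sd = 0.5)
  r3 <- paired_t_test(y, x)
  expect_lt(r3$p.value, 0.01)
  expect_false(r3$degenerate)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("connected-component labelling honours 8- and 26-connectivity", {
  m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[5, 5] <- TRUE
  lab <- icseg:::label_components(m)
  expect_equal(attr(lab, "n"), 2L)          # diagonal touch joins in 2D-8
  expect_equal(lab[1, 1], lab[2, 2])
  v <- array(FALSE, c(3, 3, 2)); v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_equal(attr(icseg:::label_components(v), "n"), 1L)  # 26-conn diagonal
})
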