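test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(image_size = 48, seed = 9)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$slice$pixels, b$slice$pixels)
  expect_identical(a$mask, b$mask)
  c2 <- generate_cohort(spec, 4, 3)
  c3 <- generate_cohort(spec, 4, 3)
  expect_identical(c2$patients[[3]]$slices[[2]]$pixels,
                   c3$patients[[3]]$slices[[2]]$pixels)
})

test_that("lesion-free specs yield all-background masks", {
  spec <- phantom_spec(image_size = 48, lesion_count_range = c(0, 0), seed = 2)
  p <- generate_phantom(spec)
  expect_false(any(p$mask))
})

test_that("lesion contrast decreases strictly with difficulty, geometry fixed", {
  # large lesions so the empirical lesion/background mean difference (a noisy
  # estimator at high difficulty, where the generator also raises the noise
  # floor) averages over enough pixels to expose the true contrast ordering
  # background reference = lesion-free gland tissue, not the whole image:
  # the gland/exterior intensity offset would otherwise confound the
  # per-channel lesion contrast
  mean_contrast <- function(difficulty) {
    spec <- phantom_spec(image_size = 96, lesion_count_range = c(2, 3),
                         lesion_radius_range = c(9, 14),
                         difficulty = difficulty, seed = 31)
    p <- generate_phantom(spec)
    stopifnot(sum(p$mask) > 300)
    bg <- p$gland & !p$mask
    vapply(1:3, function(ch) {
      img <- p$slice$pixels[, , ch]
      abs(mean(img[p$mask]) - mean(img[bg]))
    }, numeric(1))
  }
  c0 <- mean_contrast(0)
  c9 <- mean_contrast(0.9)
  expect_true(all(c0 > c9))
  # monotone over a grid on the strongest (DWI-like) channel
  cs <- vapply(c(0, 0.3, 0.6, 0.9), function(d) mean_contrast(d)[3], numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("cohort splits are disjoint by patient and sized by fractions", {
  spec <- phantom_spec(image_size = 48, seed = 7)
  coh <- generate_cohort(spec, 10, 3, split_fractions = c(0.6, 0.1, 0.3))
  splits <- vapply(coh$patients, `[[`, character(1), "split")
  expect_equal(unname(table(splits)[c("train", "val", "test")]),
               c(6L, 1L, 3L), ignore_attr = TRUE)
  ids_by_split <- split(vapply(coh$patients, `[[`, character(1), "patient_id"),
                        splits)
  expect_length(Reduce(intersect, ids_by_split), 0)
  expect_error(generate_cohort(spec, 2, 3), "at least 3")
  expect_error(generate_cohort(spec, 10, 3, split_fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("different seeds give different lesion geometries", {
  a <- generate_cohort(phantom_spec(image_size = 48, seed = 1), 3, 2)
  b <- generate_cohort(phantom_spec(image_size = 48, seed = 2), 3, 2)
  diffs <- mapply(function(pa, pb)
    !identical(pa$slices[[1]]$pixels, pb$slices[[1]]$pixels),
    a$patients, b$patients)
  expect_true(any(diffs))
})

test_that("lesion load stays below a quarter of the gland area", {
  spec <- phantom_spec(image_size = 64, seed = 13)
  coh <- generate_cohort(spec, 6, 4)
  for (p in coh$patients) {
    for (m in p$masks) {
      # gland occupies at least ~pi*0.28*0.24 of the image
      gland_area <- pi * 0.28 * 0.24 * 64^2
      expect_lt(sum(m), 0.25 * gland_area)
    }
  }
})

test_that("spec validation names the offending field", {
  expect_error(phantom_spec(image_size = 16), "image_size")
  expect_error(phantom_spec(noise_sd = 0), "noise_sd")
  expect_error(phantom_spec(image_size = 64, lesion_radius_range = c(5, 40)),
               "lesion_radius_range")
  expect_error(phantom_spec(contrast_per_channel = c(0.1, 0.2, 0.3)),
               "channel 2")
  expect_error(phantom_spec(difficulty = 1.4), "difficulty")
})

test_that("per-patient difficulties cover the requested range stratified", {
  coh <- generate_cohort(phantom_spec(image_size = 48, seed = 3), 10, 2)
  d <- sort(vapply(coh$patients, `[[`, numeric(1), "difficulty"))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(findInterval(d, seq(0, 1, by = 0.1))) >= 0))
  expect_gt(max(d) - min(d), 0.7)  # spans most of [0,1]
  easy <- generate_cohort(phantom_spec(image_size = 48, seed = 3), 5, 2,
                          difficulty_range = c(0, 0.2))
  expect_true(all(vapply(easy$patients, `[[`, numeric(1), "difficulty") <= 0.2))
})
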