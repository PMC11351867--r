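test_that("builtin prompt net honours the segmenter contract", {
  pn <- builtin_prompt_net(prompt_seg_config(seed = 7))
  px <- array(rnorm(48 * 48 * 3), c(48, 48, 3))
  full <- bounding_box(0, 0, 48, 48)
  p <- prompt_segment(pn, px, full)
  expect_equal(dim(p), c(48, 48, 2))
  expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-5)
  # determinism for fixed parameters and inputs
  expect_identical(p, prompt_segment(pn, px, full))
  # identical seeds give identical parameters
  pn2 <- builtin_prompt_net(prompt_seg_config(seed = 7))
  expect_identical(prompt_segment(pn2, px, full), p)
})

test_that("combined loss has the right limits and closed forms", {
  y <- matrix(0, 8, 8); y[3:5, 3:5] <- 1
  p_perfect <- pmin(pmax(y, 1e-7), 1 - 1e-7)
  expect_lt(combined_loss(p_perfect, y), 1e-5 + 1e-4)
  # uniform 0.5: the cross-entropy term is exactly ln 2
  p_half <- matrix(0.5, 8, 8)
  expect_equal(combined_loss(p_half, y) - dice_loss(p_half, y), log(2),
               tolerance = 1e-12)
  # loss decreases monotonically as the prediction approaches the target
  lambdas <- seq(0, 1, length.out = 5)
  losses <- vapply(lambdas, function(l)
    combined_loss(0.5 + l * (y - 0.5), y), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("combined loss gradient handles singleton batches", {
  set.seed(8)
  for (B in c(1L, 3L)) {
    z <- array(rnorm(2 * 8 * 8 * B), c(2, 8, 8, B))
    probs <- icseg:::softmax2(z)
    y <- array((runif(8 * 8 * B) < 0.4) + 0, c(8, 8, B))
    lg <- icseg:::combined_loss_grad(probs, y)
    expect_equal(dim(lg$dlogits), dim(z))
    expect_true(all(is.finite(lg$dlogits)))
  }
})

test_that("encoder freeze policy keeps frozen parameters bitwise unchanged", {
  coh <- easy_cohort()
  pn <- builtin_prompt_net(prompt_seg_config(freeze_policy = "encoder", seed = 5))
  all_p <- icseg:::nn_params(pn$net)
  enc_p <- Filter(function(p) p$group == "encoder", all_p)
  dec_p <- Filter(function(p) p$group == "decoder", all_p)
  enc_before <- icseg:::snapshot_params(enc_p)
  dec_before <- icseg:::snapshot_params(dec_p)
  train_prompt_seg(pn, coh, prompt_train_config(epochs = 1, seed = 5))
  expect_identical(icseg:::snapshot_params(enc_p), enc_before)
  expect_false(identical(icseg:::snapshot_params(dec_p), dec_before))
  expect_equal(pn$trainable_part, "decoder")
})

test_that("desk-scale training segments well under ground-truth prompts", {
  fx <- easy_prompt()
  expect_gte(max(fx$history$val_dsc), 0.75)
})

test_that("a trained net responds to the prompt location", {
  seg <- easy_prompt()$segmenter
  recs <- cohort_slices(easy_cohort(), "val")
  r <- NULL
  for (cand in recs) if (sum(cand$mask) > 8) { r <- cand; break }
  skip_if(is.null(r), "no lesion slice in validation split")
  correct <- expand_bbox(tight_bbox(r$mask), 0.4, 48, 48)
  far_x0 <- if (correct$x0 > 24) 0L else 36L
  far_y0 <- if (correct$y0 > 24) 0L else 36L
  far <- bounding_box(far_x0, far_y0, far_x0 + 10L, far_y0 + 10L)
  p_ok <- prompt_segment(seg, r$slice$pixels, correct)
  p_far <- prompt_segment(seg, r$slice$pixels, far)
  inbox <- icseg:::render_box_channel(correct, 48, 48) > 0
  expect_gt(mean(p_ok[, , 2][inbox]), mean(p_far[, , 2][inbox]))
  # the predicted mask respects the prompt: averaged over validation
  # components, under a fifth of its pixels fall outside the prompt box
  samp <- icseg:::prompt_samples(recs)
  outside <- vapply(samp, function(sm) {
    bx <- expand_bbox(sm$box, 0.4, 48, 48)
    m <- prompt_segment(seg, sm$pixels, bx)[, , 2] > 0.5
    ib <- icseg:::render_box_channel(bx, 48, 48) > 0
    sum(m & !ib) / max(sum(m), 1L)
  }, numeric(1))
  expect_lt(mean(outside), 0.2)
})

test_that("training excludes lesion-free cohorts with a clear error", {
  coh <- generate_cohort(phantom_spec(image_size = 48, lesion_count_range = c(0, 0),
                                      seed = 3), 4, 2)
  pn <- builtin_prompt_net(prompt_seg_config(seed = 1))
  expect_error(train_prompt_seg(pn, coh), "lesion-free")
})

test_that("the external adapter enforces and honours the contract", {
  expect_error(sam_adapter(tempfile("missing_weights_")),
               "external dependency missing")
  counter <- new.env()
  mock <- box_fill_segmenter(counter)
  px <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  bx <- bounding_box(4, 6, 12, 14)
  p <- prompt_segment(mock, px, bx)
  expect_equal(dim(p), c(32, 32, 2))
  # adapter output flows through the same pipeline path as the builtin net
  rec <- list(slice = icseg:::new_slice(px, c(1, 1), "X", 1L),
              mask = icseg:::render_box_channel(bx, 32, 32) > 0)
  cm <- build_coarse_net(coarse_net_config(base_channels = 4, seed = 1))
  rj <- build_rejection_net(reject_net_config(in_channels = cm$feat_channels + 2L,
                                              seed = 1))
  res <- run_cascade(rec, cm, rj, mock, gate_config(2), score = 0)
  expect_s3_class(res, "icseg_cascade_result")
  expect_true(counter$n >= 1)
})
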