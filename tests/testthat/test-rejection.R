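test_that("rejection forward maps batches to one finite scalar per slice", {
  rj <- build_rejection_net(reject_net_config(in_channels = 10, seed = 4))
  x1 <- array(rnorm(10 * 64 * 64 * 1), c(10, 64, 64, 1))
  s1 <- icseg:::rejection_forward(rj, x1, train = FALSE)
  expect_length(s1, 1)
  expect_true(is.finite(s1))
  xb <- array(rnorm(10 * 64 * 64 * 5), c(10, 64, 64, 5))
  expect_length(icseg:::rejection_forward(rj, xb, train = FALSE), 5)
  bad <- array(rnorm(7 * 64 * 64), c(7, 64, 64, 1))
  expect_error(icseg:::rejection_forward(rj, bad), "channels")
})

test_that("rejection builds are deterministic and the head has three FC stages", {
  a <- build_rejection_net(reject_net_config(in_channels = 6, seed = 9))
  b <- build_rejection_net(reject_net_config(in_channels = 6, seed = 9))
  expect_identical(icseg:::snapshot_params(icseg:::nn_params(a$layers)),
                   icseg:::snapshot_params(icseg:::nn_params(b$layers)))
  fcs <- Filter(function(l) l$type == "fc", a$layers)
  expect_length(fcs, 3)
  expect_equal(nrow(fcs[[3]]$W), 1L)
  expect_error(reject_net_config(in_channels = 6, head_widths = c(512, 1)),
               "head_widths")
})

test_that("quality target equals the Dice of the coarse mask", {
  g <- matrix(FALSE, 10, 10); g[3:6, 3:6] <- TRUE
  expect_equal(quality_target(g, g), 1)
  disj <- matrix(FALSE, 10, 10); disj[8:9, 8:9] <- TRUE
  expect_equal(quality_target(disj, g), 0)
  shifted <- matrix(FALSE, 10, 10); shifted[3:6, 4:7] <- TRUE
  expect_equal(quality_target(shifted, g), 0.75)  # 2*12/(16+16)
})

test_that("mse loss matches hand arithmetic and rejects bad input", {
  expect_equal(mse_loss(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(mse_loss(0.5, 0), 0.25)
  expect_equal(mse_loss(c(0.2, 0.4), c(0.4, 0.2)), 0.04)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("gate uses a strict lower-than rule", {
  cfg <- gate_config(0.4)
  expect_equal(gate(0.35, cfg), "MANUAL")
  expect_equal(gate(0.45, cfg), "AUTO")
  expect_equal(gate(0.40, cfg), "AUTO")  # boundary score is not rejected
  s <- runif(20)
  expect_true(all(gate(s, gate_config(0)) == "AUTO"))
  expect_true(all(gate(s, gate_config(1.01)) == "MANUAL"))
  expect_error(gate_config(-0.2), "threshold")
})

test_that("training requires a frozen coarse model and never updates it", {
  coh <- generate_cohort(phantom_spec(image_size = 48, lesion_count_range = c(0, 0),
                                      seed = 14), 6, 2)
  cm <- build_coarse_net(coarse_net_config(seed = 2))
  rj <- build_rejection_net(reject_net_config(in_channels = cm$feat_channels + 2L,
                                              seed = 3))
  expect_error(train_rejection(rj, cm, coh), "frozen")
  freeze_model(cm)
  before <- icseg:::snapshot_params(icseg:::nn_params(cm$net))
  tr <- train_rejection(rj, cm, coh, reject_train_config(epochs = 1, seed = 3))
  after <- icseg:::snapshot_params(icseg:::nn_params(cm$net))
  expect_identical(before, after)
})

test_that("regression converges to the constant on a degenerate cohort", {
  # all-lesion-free cohort: with an untrained coarse net every slice has the
  # same quality target, so the regressor should drive validation MSE ~ 0
  coh <- generate_cohort(phantom_spec(image_size = 48, lesion_count_range = c(0, 0),
                                      seed = 15), 8, 2)
  cm <- build_coarse_net(coarse_net_config(seed = 5))
  freeze_model(cm)
  rj <- build_rejection_net(reject_net_config(in_channels = cm$feat_channels + 2L,
                                              seed = 6))
  tr <- train_rejection(rj, cm, coh,
                        reject_train_config(epochs = 12, batch_size = 4, seed = 6))
  expect_equal(length(unique(tr$val_scores$target)), 1)
  expect_lte(min(tr$history$val_mse), 0.01)
  expect_equal(tr$best_epoch, which.min(tr$history$val_mse))
})

test_that("predicted scores are clamped to the unit interval", {
  rj <- build_rejection_net(reject_net_config(in_channels = 10, seed = 4))
  fake_preds <- lapply(1:3, function(i)
    list(feats = array(rnorm(16 * 16 * 8, sd = 5), c(16, 16, 8)),
         probs = array(runif(16 * 16 * 2), c(16, 16, 2))))
  s <- predict_quality(rj, fake_preds)
  expect_true(all(s >= 0 & s <= 1))
})
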