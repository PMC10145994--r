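test_that("backpropagation matches central-difference gradients", {
  cfg <- tiny_config()
  d <- tiny_xy(cfg)
  params <- mieegnet:::with_seed(1, mieegnet:::eegnet_init_params(cfg))
  st <- mieegnet:::eegnet_step(params, cfg, d$x, d$Y)
  loss_at <- function(p) mieegnet:::eegnet_step(p, cfg, d$x, d$Y)$loss
  h <- 1e-6
  set.seed(99)
  for (nm in mieegnet:::.trainable) {
    idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      ana <- as.numeric(st$grads[[nm]])[i]
      expect_lt(abs(num - ana) / max(1, abs(num) + abs(ana)), 1e-6,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("pooling floor-divides the temporal axis and rejects exhaustion", {
  cfg <- eegnet_config(chans = 8)
  expect_identical(cfg$T1, 42L)   # 170 %/% 4
  expect_identical(cfg$T2, 5L)    # 42 %/% 8
  expect_identical(cfg$flat, 80L)
  expect_error(eegnet_config(chans = 2, samples = 10, pool1 = 4, pool2 = 8),
               "configuration error")
})

test_that("a zeroed dense layer predicts the uniform distribution", {
  cfg <- eegnet_config(chans = 4, samples = 40)
  model <- eegnet_build(cfg, seed = 3)
  model$params$W6[] <- 0
  model$params$b6[] <- 0
  x <- array(rnorm(5 * 4 * 40), c(5, 4, 40, 1))
  p <- predict(model, x)
  expect_equal(unname(p$probs), matrix(1 / 6, 5, 6), tolerance = 1e-12)
  expect_identical(p$labels, rep(1L, 5))   # tie -> lowest class code
})

test_that("probability rows sum to one and labels track the maximum", {
  tr <- mini_trials()
  cfg <- eegnet_config(chans = 5)
  fit <- eegnet(tr, cfg, processing_train_config(epochs = 2,
                                                 batch_size = 40, seed = 2))
  p <- predict(fit, tr)
  expect_equal(rowSums(p$probs), rep(1, n_trials(tr)), tolerance = 1e-6)
  expect_identical(p$labels, max.col(p$probs, ties.method = "first"))
  expect_true(all(p$labels %in% 1:6))
})

test_that("training records history, declines in loss, and is reproducible", {
  tr <- select_channels(default_trials(), planted_clique)
  cfg <- eegnet_config(chans = 6)
  tc <- processing_train_config(epochs = 12, batch_size = 40, seed = 7)
  fit1 <- eegnet(tr, cfg, tc)
  expect_identical(nrow(fit1$history), 12L)
  expect_true(all(is.finite(fit1$history$loss)))
  expect_lt(fit1$history$loss[12], fit1$history$loss[1])
  # bit-identical re-run under the same seed
  fit2 <- eegnet(tr, cfg, tc)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history, fit2$history)
  # learning-rate column follows the cyclical schedule bounds
  expect_true(all(fit1$history$lr >= 1e-6 & fit1$history$lr <= 5e-2))
})

test_that("training rejects empty data, bad labels and shape mismatches", {
  cfg <- eegnet_config(chans = 2, samples = 40)
  m <- eegnet_build(cfg)
  empty <- trial_set(array(0, c(0, 2, 40, 1)), integer(0), c("A", "B"),
                     window_len = 40)
  expect_error(eegnet_train(m, empty, train_config(epochs = 1)),
               "empty")
  tr <- mini_trials()
  expect_error(eegnet_train(m, tr, train_config(epochs = 1)),
               "shape error")
})

test_that("model JSON container round-trips weights and config", {
  cfg <- tiny_config()
  m <- eegnet_build(cfg, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  eegnet_save(m, f)
  m2 <- eegnet_load(f)
  expect_equal(m2$params[mieegnet:::.trainable],
               m$params[mieegnet:::.trainable], tolerance = 1e-15)
  expect_identical(m2$config$flat, cfg$flat)
  # loaded model predicts identically
  x <- array(rnorm(3 * cfg$chans * cfg$samples),
             c(3, cfg$chans, cfg$samples, 1))
  expect_equal(predict(m2, x)$probs, predict(m, x)$probs, tolerance = 1e-12)
})

test_that("high-capacity fit reaches high training accuracy on planted data", {
  tr <- select_channels(default_trials(), planted_clique)
  fit <- eegnet(tr, train_cfg = processing_train_config(
    epochs = 30, batch_size = 40, seed = 5))
  p <- predict(fit, tr)
  expect_gt(mean(p$labels == tr$y), 0.9)
})
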