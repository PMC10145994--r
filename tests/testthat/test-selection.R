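test_that("mutual-information grouping recovers a planted clique", {
  tr <- default_trials(seed = 31)
  d <- cmiba_select(tr, n = 6)
  expect_s3_class(d, "dcs")
  expect_identical(d$method, "cmiba")
  expect_identical(sort(d$channels), sort(planted_clique))
  expect_identical(nrow(d$scores), 6L)
  # deterministic
  d2 <- cmiba_select(tr, n = 6)
  expect_identical(d$channels, d2$channels)
})

test_that("grouping edge cases: full montage, oversize, degenerate MI", {
  tr <- default_trials(seed = 31, trials_per_class = 2)
  d <- cmiba_select(tr, n = 19)
  expect_identical(sort(d$channels), sort(tr$channel_names))
  expect_error(cmiba_select(tr, n = 25), "argument error")
  pm0 <- pairwise_mi(tr, n_bins = 16)
  pm0$mi[] <- 0
  expect_error(cmiba_select(tr, n = 4, pm = pm0),
               "no discriminative structure")
})

test_that("least-redundancy objective picks channels outside the clique", {
  tr <- default_trials(seed = 31)
  dmin <- cmiba_select(tr, n = 6, objective = "min")
  # minimising shared information should not reconstruct the coherent clique
  expect_false(identical(sort(dmin$channels), sort(planted_clique)))
})

test_that("accuracy ranking puts planted channels above background ones", {
  tr <- mini_trials(seed = 11)     # C3, Cz, P3 informative; Fp1, T4 noise
  prof <- arbc_desk_profile()
  rk <- arbc_rank(tr, prof$model_cfg, prof$train_cfg, folds = prof$folds,
                  seed = 5)
  expect_s3_class(rk, "channel_ranking")
  expect_identical(sort(rk$channel[1:3]), c("C3", "Cz", "P3"))
  expect_gt(min(rk$accuracy[1:3]), max(rk$accuracy[4:5]) + 10)
})

test_that("label-shuffled data ranks every channel near chance", {
  tr <- select_channels(default_trials(seed = 11), c("C3", "Fp1"))
  tr$y <- mieegnet:::with_seed(77, sample(tr$y))
  prof <- arbc_desk_profile()
  rk <- arbc_rank(tr, prof$model_cfg, prof$train_cfg, folds = prof$folds,
                  seed = 5)
  # binomial sampling band around 1/6 over 120 held-out trials
  expect_true(all(abs(rk$accuracy - 100 / 6) < 15))
})

test_that("top-n selection resolves boundary ties by subset evaluation", {
  rk <- structure(
    data.frame(channel = c("C3", "Cz", "P3", "P4", "O2", "Fp1"),
               accuracy = c(80, 70, 60, 36.7, 36.7, 20)),
    class = c("channel_ranking", "data.frame"))
  tr <- select_channels(default_trials(seed = 11),
                        c("C3", "Cz", "P3", "P4", "O2", "Fp1"))
  prof <- arbc_desk_profile()
  d <- arbc_select(rk, tr, n = 4, train_cfg = prof$train_cfg,
                   folds = 2, seed = 5)
  expect_identical(d$n, 4L)
  expect_identical(d$channels[1:3], c("C3", "Cz", "P3"))
  # the boundary slot goes to the tied candidate that is informative
  expect_identical(d$channels[4], "P4")
  # no tie at the cut -> simple top-n, no training needed
  rk2 <- rk; rk2$accuracy <- c(80, 70, 60, 50, 40, 20)
  d2 <- arbc_select(rk2, tr, n = 4)
  expect_identical(d2$channels, c("C3", "Cz", "P3", "P4"))
  # all tied and n covers them all -> membership only, no training needed
  rk3 <- rk; rk3$accuracy <- rep(50, 6)
  d3 <- arbc_select(rk3, tr, n = 6)
  expect_identical(sort(d3$channels), sort(rk3$channel))
  expect_error(arbc_select(rk, tr, n = 25), "argument error")
})

test_that("reference selection results carry the published structure", {
  ref <- halt_reference()
  expect_length(ref$arbc_accuracy, 19L)
  expect_identical(names(which.max(ref$arbc_accuracy)), "Fp1")
  # the eight boldface accuracies descend Fp1 > F8 > Fp2 > F7 > P3 > Cz/O1 > P4
  top8 <- sort(ref$arbc_accuracy, decreasing = TRUE)[1:8]
  expect_identical(unname(top8), c(39.5, 39.2, 39.1, 38.4, 37.4, 37.0,
                                   37.0, 36.7))
  expect_identical(ref$arbc_subset_8[1:6], ref$arbc_subset_6)
  expect_identical(ref$cmiba_subset_8[1:6], ref$cmiba_subset_6)
  expect_identical(ref$headline[["per_subject"]], 83.7)
  expect_identical(ref$headline[["per_task"]], 81.3)
})
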