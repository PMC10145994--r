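test_that("stratified folds partition trials with balanced sizes and classes", {
  tr <- default_trials()                       # 120 trials, 20 per class
  plan <- make_folds(tr, k = 10, seed = 1)
  all_ix <- sort(unlist(plan$folds))
  expect_identical(all_ix, seq_len(n_trials(tr)))
  sizes <- lengths(plan$folds)
  expect_lte(diff(range(sizes)), 1L)
  # class proportions preserved within one trial
  for (f in plan$folds) {
    tab <- table(factor(tr$y[f], levels = 1:6))
    expect_lte(diff(range(tab)), 1L)
  }
  # deterministic under the seed
  plan2 <- make_folds(tr, k = 10, seed = 1)
  expect_identical(plan, plan2)
  plan3 <- make_folds(tr, k = 10, seed = 2)
  expect_false(identical(plan, plan3))
  expect_error(make_folds(tr, k = 10000), "argument error")
})

test_that("binary accuracy matches the count ratio and is scale-invariant", {
  expect_equal(accuracy_from_counts(5, 5, 0, 0), 100)
  expect_equal(accuracy_from_counts(1, 1, 1, 1), 50)
  expect_equal(accuracy_from_counts(3, 90, 4, 3), 93)
  expect_equal(accuracy_from_counts(30, 900, 40, 30),
               accuracy_from_counts(3, 90, 4, 3))
  expect_error(accuracy_from_counts(0, 0, 0, 0), "undefined")
  expect_error(accuracy_from_counts(-1, 1, 1, 1), "nonnegative")
})

test_that("confusion matrix matches a hand tally", {
  true <- c(1, 1, 2, 2, 3, 4, 5, 6, 6, 2, 3, 1)
  pred <- c(1, 2, 2, 2, 3, 4, 5, 6, 5, 1, 3, 1)
  cm <- confusion(true, pred)
  expect_identical(sum(cm), 12L)
  expect_identical(cm["left hand", "left hand"], 2L)
  expect_identical(cm["left hand", "right hand"], 1L)
  expect_identical(cm["right hand", "left hand"], 1L)
  expect_identical(cm["right leg", "tongue"], 1L)
  expect_identical(unname(diag(unclass(cm))), c(2L, 2L, 2L, 1L, 1L, 1L))
  # perfect prediction is diagonal
  cmp <- confusion(1:6, 1:6)
  expect_identical(sum(cmp) - sum(diag(unclass(cmp))), 0L)
  cm1 <- confusion(2, 5)
  expect_identical(cm1["right hand", "tongue"], 1L)
  expect_error(confusion(c(1, 7), c(1, 1)), "label error")
  expect_error(confusion(1:3, 1:2), "equal length")
})

test_that("cross-validation aggregates folds without losing trials", {
  tr <- mini_trials()
  cfg <- eegnet_config(chans = 5)
  r <- cross_validate(tr, cfg,
                      processing_train_config(epochs = 3, batch_size = 60,
                                              seed = 3),
                      k = 5, seed = 9)
  expect_length(r$per_fold, 5L)
  expect_identical(r$n, n_trials(tr))
  expect_identical(sum(r$confusion), n_trials(tr))
  expect_equal(r$overall, 100 * sum(diag(unclass(r$confusion))) / r$n)
  expect_identical(nrow(r$per_class), 6L)
  expect_true(all(r$per_class$ovr_accuracy >= 0 &
                    r$per_class$ovr_accuracy <= 100))
  # reproducible end to end
  r2 <- cross_validate(tr, cfg,
                       processing_train_config(epochs = 3, batch_size = 60,
                                               seed = 3),
                       k = 5, seed = 9)
  expect_identical(r$confusion, r2$confusion)
  expect_identical(r$per_fold, r2$per_fold)
})

test_that("per-subject mode returns one report per subject tag", {
  spec <- synthetic_spec(n_subjects = 2, trials_per_class = 8, seed = 17)
  tr <- generate_synthetic_trials(spec)
  tr <- select_channels(tr, c("C3", "Cz", "Pz"))
  cfg <- eegnet_config(chans = 3)
  rep <- cross_validate(tr, cfg,
                        processing_train_config(epochs = 2, batch_size = 40,
                                                seed = 1),
                        k = 4, seed = 2, per_subject = TRUE)
  expect_identical(names(rep), c("SYN01", "SYN02"))
  expect_identical(rep$SYN01$subject, "SYN01")
  expect_identical(rep$SYN01$n + rep$SYN02$n, n_trials(tr))
})

test_that("latency report carries sane order statistics", {
  cfg <- eegnet_config(chans = 3, samples = 40)
  m <- eegnet_build(cfg)
  tr <- trial_set(array(rnorm(20 * 3 * 40), c(20, 3, 40, 1)),
                  rep(1:4, 5), c("C3", "Cz", "C4"), window_len = 40)
  lat <- measure_latency(m, tr, warmup = 3)
  expect_identical(lat$n, 20L)
  expect_true(is.finite(lat$mean_ms) && lat$mean_ms > 0)
  expect_lte(lat$min_ms, lat$mean_ms)
  expect_lte(lat$mean_ms, lat$max_ms)
  expect_match(lat$hardware, "R version")
})
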