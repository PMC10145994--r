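test_that("generator is deterministic per (spec, subject) and varies by seed", {
  spec <- synthetic_spec(trials_per_class = 3, seed = 21)
  a <- generate_synthetic_session(spec, 1)
  b <- generate_synthetic_session(spec, 1)
  expect_identical(a$session$data, b$session$data)
  expect_identical(a$session$marker, b$session$marker)
  c <- generate_synthetic_session(spec, 2)
  expect_false(identical(a$session$data, c$session$data))
  spec2 <- synthetic_spec(trials_per_class = 3, seed = 22)
  d <- generate_synthetic_session(spec2, 1)
  expect_false(identical(a$session$data, d$session$data))
})

test_that("marker stream encodes the requested trial counts and gaps", {
  spec <- synthetic_spec(trials_per_class = 4, seed = 3)
  s <- generate_synthetic_session(spec, 1)$session
  runs <- mieegnet:::marker_runs(s$marker)
  task <- runs[runs$code != 0, ]
  expect_identical(nrow(task), 24L)
  expect_identical(as.integer(table(task$code)), rep(4L, 6))
  expect_true(all(task$length >= 200))
  gaps <- runs[runs$code == 0, ]
  expect_true(all(gaps$length >= 50))
})

test_that("snr = 0 removes the planted class effect", {
  band_ratio <- function(snr) {
    spec <- synthetic_spec(trials_per_class = 30, snr = snr, seed = 4)
    tr <- generate_synthetic_trials(spec)
    # class-1 band (8-12 Hz) power, planted vs background channels
    bp <- function(x) {
      sp <- stats::spec.pgram(stats::ts(x, frequency = 200), taper = 0,
                              plot = FALSE, detrend = TRUE)
      sum(sp$spec[sp$freq >= 8 & sp$freq <= 12])
    }
    pow <- vapply(seq_along(tr$channel_names), function(ch)
      mean(apply(tr$x[tr$y == 1, ch, , 1], 1, bp)), numeric(1))
    names(pow) <- tr$channel_names
    mean(pow[planted_clique]) /
      mean(pow[setdiff(tr$channel_names, planted_clique)])
  }
  # the statistic detects the planted effect when present ...
  expect_gt(band_ratio(4), 2)
  # ... and finds none in the snr = 0 limit
  r0 <- band_ratio(0)
  expect_gt(r0, 0.7)
  expect_lt(r0, 1.4)
})

test_that("per-channel band power peaks on each class's informative channel", {
  # one distinct channel per class, distinct bands, high snr
  per_class <- c("Fp1", "F3", "T3", "P3", "O1", "C4")
  bands <- list(c(8, 12), c(12, 16), c(16, 20), c(20, 24), c(24, 28),
                c(28, 32))
  spec <- synthetic_spec(trials_per_class = 12, snr = 8,
                         informative_map = stats::setNames(
                           as.list(per_class), names(mi_classes())),
                         osc_band_hz = bands, seed = 13)
  tr <- generate_synthetic_trials(spec)
  band_power <- function(x, lo, hi, fs = 200) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                            plot = FALSE, detrend = TRUE)
    sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
  }
  for (cls in 1:6) {
    b <- bands[[cls]]
    pow <- vapply(seq_along(tr$channel_names), function(ch) {
      mean(apply(tr$x[tr$y == cls, ch, , 1], 1, band_power, lo = b[1],
                 hi = b[2]))
    }, numeric(1))
    expect_identical(tr$channel_names[which.max(pow)], per_class[cls])
  }
})

test_that("spec validation rejects out-of-passband bands and bad sizes", {
  expect_error(synthetic_spec(osc_band_hz = list(c(0.1, 5), NULL, NULL,
                                                 NULL, NULL, NULL)),
               "passband|0.5")
  expect_error(synthetic_spec(snr = -1), "snr")
  expect_error(synthetic_spec(run_len = 100), "run_len")
  expect_error(synthetic_spec(gap_len = 10), "gap_len")
  expect_error(synthetic_spec(informative_map = stats::setNames(
    rep(list("Zz"), 6), names(mi_classes()))), "Zz")
})

test_that("pink-noise background has a decaying spectrum", {
  set.seed(2)
  x <- mieegnet:::pink_noise(20000, 1)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 200), taper = 0,
                          plot = FALSE, spans = 31)
  low <- mean(sp$spec[sp$freq > 1 & sp$freq < 5])
  high <- mean(sp$spec[sp$freq > 60 & sp$freq < 90])
  expect_gt(low / high, 5)
})
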