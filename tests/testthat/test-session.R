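make_session <- function(marker, n_ch = 19L) {
  m <- halt_montage()
  eeg_session(matrix(seq_len(length(marker) * n_ch), length(marker), n_ch),
              marker, 200, m$names[seq_len(n_ch)], subject_id = "T")
}

test_that("session invariants are enforced", {
  expect_error(make_session(c(0, 7, 0)), "1\\.\\.6")
  m <- halt_montage()
  expect_error(eeg_session(matrix(0, 5, 19), rep(0, 4), 200, m$names),
               "marker length")
  expect_error(eeg_session(matrix(0, 5, 19), rep(0, 5), -1, m$names),
               "samp_freq")
})

test_that("epoching cuts one window per run with the stated offsets", {
  # a 200-sample run of code 3 starting at sample 101 (1-based)
  marker <- c(rep(0, 100), rep(3, 200), rep(0, 50))
  s <- make_session(marker)
  tr <- extract_trials(s, window_len = 170, trim = 15)
  expect_identical(n_trials(tr), 1L)
  expect_identical(tr$y, 3L)
  # window = run samples 16..185 -> absolute rows 116..285; column 1 holds
  # the row index by construction
  expect_equal(tr$x[1, 1, , 1], 116:285)
})

test_that("short runs are skipped and counted; trial count is conserved", {
  marker <- c(rep(0, 10), rep(1, 200), rep(0, 10), rep(2, 150),
              rep(0, 10), rep(5, 220), rep(0, 10))
  s <- make_session(marker)
  tr <- extract_trials(s)
  expect_identical(tr$y, c(1L, 5L))
  expect_identical(attr(tr, "n_runs"), 3L)
  expect_identical(attr(tr, "n_skipped"), 1L)
  # conservation: emitted + skipped == all task runs
  expect_identical(n_trials(tr) + attr(tr, "n_skipped"), attr(tr, "n_runs"))
})

test_that("windows never bleed across run boundaries", {
  set.seed(7)
  spec <- synthetic_spec(trials_per_class = 4, seed = 7)
  s <- generate_synthetic_session(spec, 1)$session
  runs <- mieegnet:::marker_runs(s$marker)
  runs <- runs[runs$code != 0, ]
  tr <- extract_trials(s, window_len = 170, trim = 15)
  # re-derive each trial from the raw session and compare
  for (i in seq_len(n_trials(tr))) {
    from <- runs$start[i] + 15L
    expect_lte(from + 170L - 1L, runs$start[i] + runs$length[i] - 1L)
    expect_equal(tr$x[i, , , 1], unname(t(s$data[from:(from + 169L), ])))
  }
})

test_that("all-zero markers give an empty trial set with a warning", {
  s <- make_session(rep(0, 300))
  expect_warning(tr <- extract_trials(s), "no task runs")
  expect_identical(n_trials(tr), 0L)
})

test_that("negative trim is rejected", {
  expect_error(extract_trials(make_session(rep(0, 10)), trim = -1), "trim")
})

test_that("0.85 s at 200 Hz is a 170-sample window", {
  expect_identical(0.85 * 200, 170)
})

test_that("channel subsetting reorders and restricts the channel axis", {
  tr <- default_trials()
  arbc8 <- halt_reference()$arbc_subset_8
  sub <- select_channels(tr, arbc8)
  expect_identical(dim(sub$x)[2], 8L)
  expect_identical(sub$channel_names, arbc8)
  expect_identical(sub$y, tr$y)
  # data columns follow the requested order
  i <- match("P3", tr$channel_names)
  expect_equal(sub$x[, match("P3", arbc8), , ], tr$x[, i, , ])
  # full montage subset is the identity
  idm <- select_channels(tr, tr$channel_names)
  expect_equal(idm$x, tr$x)
  # six-channel reference subset
  expect_identical(dim(select_channels(tr, halt_reference()$cmiba_subset_6)$x)[2],
                   6L)
  expect_error(select_channels(tr, c("Cz", "Nope")), "Nope")
})
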