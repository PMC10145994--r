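test_that("histogram estimate matches direct counting on a hand-built signal", {
  x <- c(0.1, 0.9, 1.1, 1.9, 2.1, 2.9, 3.1, 3.9)  # range [0.1, 3.9], 4 bins
  d <- estimate_distribution(x, n_bins = 4, eps = 0)
  # widths 0.95: edges 0.1, 1.05, 2.0, 2.95, 3.9 -> counts 2,2,2,2
  expect_identical(d$counts, rep(2L, 4))
  expect_equal(sum(d$probs), 1)
  expect_equal(d$probs, rep(0.25, 4))
})

test_that("uniform data fills bins evenly and constants have zero entropy", {
  set.seed(5)
  d <- estimate_distribution(runif(200000), n_bins = 4)
  expect_equal(d$probs, rep(0.25, 4), tolerance = 0.01)
  dc <- estimate_distribution(rep(3.2, 100), n_bins = 8)
  expect_identical(sum(dc$counts > 0), 1L)
  expect_lt(shannon_entropy(dc), 1e-6)
  expect_error(estimate_distribution(1:3, n_bins = 8), "n_bins samples")
})

test_that("entropy matches closed forms and its bounds", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  set.seed(1)
  p <- prop.table(runif(16))
  expect_gte(shannon_entropy(p), 0)
  expect_lte(shannon_entropy(p), log2(16))
})

test_that("kld matches direct evaluation, is asymmetric, zero iff equal", {
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), 1)
  p <- c(0.7, 0.2, 0.1); q <- c(0.3, 0.3, 0.4)
  expect_equal(kld(p, q), sum(p * log2(p / q)))
  expect_equal(kld(p, p), 0)
  expect_gt(kld(p, q), 0)
  expect_false(isTRUE(all.equal(kld(p, q), kld(q, p))))
  expect_error(kld(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "binning")
  expect_error(kld(c(0.5, 0.5), c(1, 0)), "positive")
  # distribution objects must share bin edges
  a <- estimate_distribution(1:100, 8)
  b <- estimate_distribution(201:300, 8)
  expect_error(kld(a, b), "bin edges")
})

test_that("mutual information agrees with exhaustive summation on toy joints", {
  # independent oracle: brute-force loop over all cells
  mi_brute <- function(J) {
    pi_ <- rowSums(J); pj <- colSums(J)
    s <- 0
    for (i in seq_len(nrow(J))) for (j in seq_len(ncol(J))) {
      if (J[i, j] > 0) s <- s + J[i, j] * log2(J[i, j] / (pi_[i] * pj[j]))
    }
    s
  }
  J1 <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  expect_equal(mi_from_joint(J1), mi_brute(J1), tolerance = 1e-12)
  J2 <- matrix(c(0.25, 0.25, 0.25, 0.25), 2)   # independent
  expect_equal(mi_from_joint(J2), 0, tolerance = 1e-12)
  set.seed(8)
  J3 <- matrix(runif(16), 4); J3 <- J3 / sum(J3)
  expect_equal(mi_from_joint(J3), mi_brute(J3), tolerance = 1e-12)
  expect_error(mi_from_joint(J3 * 2), "sum to 1")
})

test_that("sampled MI satisfies I(X,X) = H(X) and vanishes for independence", {
  set.seed(3)
  x <- rnorm(20000)
  h <- shannon_entropy(estimate_distribution(x, 32, eps = 0))
  expect_equal(mutual_information(x, x, 32), h, tolerance = 1e-12)
  y <- rnorm(20000)
  expect_lt(mutual_information(x, y, 32), 0.05)
  expect_gte(mutual_information(x, y, 32), 0)
  # symmetric in its arguments
  expect_equal(mutual_information(x, y, 16), mutual_information(y, x, 16),
               tolerance = 1e-12)
  # strong dependence shows up
  expect_gt(mutual_information(x, x + rnorm(20000, sd = 0.1), 32), 1)
  expect_error(mutual_information(1:10, 1:9), "equal length")
})

test_that("pairwise MI evaluates every unordered pair once", {
  tr4 <- select_channels(default_trials(seed = 11, trials_per_class = 2),
                         c("C3", "Cz", "Fp1", "O2"))
  pm <- pairwise_mi(tr4, n_bins = 16)
  expect_identical(pm$n_pairs, 6L)          # C(4,2)
  expect_equal(pm$mi, t(pm$mi))
  expect_true(all(pm$mi[upper.tri(pm$mi)] >= -1e-9))
  expect_equal(unname(diag(pm$mi)), unname(pm$entropy))
  # diagonal is each channel's self-entropy
  x1 <- as.numeric(tr4$x[, 1, , 1])
  expect_equal(unname(pm$entropy[1]),
               shannon_entropy(estimate_distribution(x1, 16, eps = 0)))
})
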