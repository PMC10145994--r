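#' Histogram estimate of a channel's amplitude distribution
#'
#' Equal-width bins spanning the pooled data range, with additive smoothing
#' `eps` applied to the counts before normalisation.  A constant signal
#' occupies a single bin (a unit-width range is substituted) and has zero
#' entropy.
#'
#' @param signal numeric samples (microvolts), e.g. one channel pooled over
#'   all trials.
#' @param n_bins number of amplitude bins.
#' @param eps additive smoothing added to each bin count.
#' @param edges optional explicit bin edges (length `n_bins + 1`),
#'   overriding the data range.
#' @return An object of class `"amp_distribution"`: list with `bin_edges`,
#'   `probs`, `counts`, `n_bins`.
#' @export
estimate_distribution <- function(signal, n_bins = 32L, eps = 1e-10,
                                  edges = NULL) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < n_bins) stop("need at least n_bins samples (got ", n, ")")
  if (is.null(edges)) {
    lo <- min(signal); hi <- max(signal)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  stopifnot(length(edges) == n_bins + 1L)
  counts <- tabulate(bin_index(signal, edges), nbins = n_bins)
  probs <- (counts + eps) / (n + n_bins * eps)
  structure(list(bin_edges = edges, probs = probs, counts = counts,
                 n_bins = as.integer(n_bins)),
            class = "amp_distribution")
}

# map samples to 1..n_bins for given equal-width edges (clamped)
bin_index <- function(x, edges) {
  nb <- length(edges) - 1L
  w <- (edges[nb + 1L] - edges[1L]) / nb
  pmin(pmax(floor((x - edges[1L]) / w) + 1L, 1L), nb)
}

.as_probs <- function(p) {
  if (inherits(p, "amp_distribution")) p$probs else as.numeric(p)
}

#' Shannon entropy of a distribution, in bits
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention; bounded by
#' `log2(n_bins)`.
#'
#' @param p an [estimate_distribution()] object or probability vector.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))   # 1.5 bits
#' @export
shannon_entropy <- function(p) {
  p <- .as_probs(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Kullback-Leibler divergence, in bits
#'
#' `sum(p * log2(p / q))` over the shared binning; nonnegative and zero
#' iff the distributions coincide.  `q` must be positive wherever `p` is
#' (guaranteed when `q` comes from [estimate_distribution()] with its
#' default smoothing).
#'
#' @param p,q [estimate_distribution()] objects on the same bin edges, or
#'   probability vectors of equal length.
#' @return divergence in bits.
#' @export
kld <- function(p, q) {
  if (inherits(p, "amp_distribution") && inherits(q, "amp_distribution")) {
    if (!isTRUE(all.equal(p$bin_edges, q$bin_edges)))
      stop("mismatched binning: p and q must share bin edges")
  }
  pp <- .as_probs(p); qq <- .as_probs(q)
  if (length(pp) != length(qq))
    stop("mismatched binning: p and q must have the same number of bins")
  on <- pp > 0
  if (any(qq[on] <= 0))
    stop("q must be positive wherever p is; smooth q first")
  sum(pp[on] * log2(pp[on] / qq[on]))
}

#' Mutual information from a joint probability table, in bits
#'
#' The Kullback-Leibler divergence between the joint distribution and the
#' product of its own marginals.
#'
#' @param joint numeric matrix of joint probabilities (sums to 1).
#' @return mutual information in bits.
#' @export
mi_from_joint <- function(joint) {
  joint <- as.matrix(joint)
  tot <- sum(joint)
  if (abs(tot - 1) > 1e-8) stop("joint table must sum to 1")
  pi_ <- rowSums(joint)
  pj <- colSums(joint)
  prod_ <- outer(pi_, pj)
  on <- joint > 0
  sum(joint[on] * log2(joint[on] / prod_[on]))
}

#' Histogram mutual information between two sampled signals
#'
#' Both signals are binned with `n_bins` equal-width bins over their own
#' ranges; the joint occupancy table is formed and the mutual information
#' is the divergence of the joint from the product of its marginals.
#' `mutual_information(x, x)` equals the plug-in entropy of `x`;
#' independent streams give values near zero (the plug-in positive bias
#' shrinks as `(n_bins - 1)^2 / (2 n ln 2)`).
#'
#' @param si,sj numeric sample vectors of equal length.
#' @param n_bins bins per axis.
#' @return mutual information in bits.
#' @export
mutual_information <- function(si, sj, n_bins = 32L) {
  if (length(si) != length(sj))
    stop("argument error: si and sj must have equal lengths (",
         length(si), " vs ", length(sj), ")")
  di <- estimate_distribution(si, n_bins, eps = 0)
  dj <- estimate_distribution(sj, n_bins, eps = 0)
  bi <- bin_index(si, di$bin_edges)
  bj <- bin_index(sj, dj$bin_edges)
  counts <- tabulate(bi + n_bins * (bj - 1L), nbins = n_bins * n_bins)
  joint <- matrix(counts / length(si), n_bins, n_bins)
  mi_from_joint(joint)
}

#' Pairwise mutual information over all channels of a trial set
#'
#' Pools every trial's samples per channel (all subjects mixed) and
#' evaluates [mutual_information()] for each unordered channel pair —
#' 171 evaluations for the 19-channel montage.  The diagonal holds each
#' channel's plug-in self-entropy, which equals `I(S, S)`.
#'
#' @param trials a [trial_set()].
#' @param n_bins amplitude bins per channel.
#' @return An object of class `"pairwise_mi"`: list with `mi` (symmetric
#'   matrix, channel-named, bits), `entropy` (named diagonal), `n_bins`,
#'   `n_pairs` (number of pair evaluations performed).
#' @export
pairwise_mi <- function(trials, n_bins = 32L) {
  stopifnot(inherits(trials, "trial_set"))
  n_ch <- dim(trials$x)[2]
  chn <- trials$channel_names
  pooled <- lapply(seq_len(n_ch), function(c) as.numeric(trials$x[, c, , 1]))
  dists <- lapply(pooled, estimate_distribution, n_bins = n_bins, eps = 0)
  bins <- lapply(seq_len(n_ch), function(c)
    bin_index(pooled[[c]], dists[[c]]$bin_edges))
  n <- length(pooled[[1]])
  mi <- matrix(0, n_ch, n_ch, dimnames = list(chn, chn))
  diag(mi) <- vapply(dists, shannon_entropy, numeric(1))
  n_pairs <- 0L
  for (i in seq_len(n_ch - 1L)) {
    for (j in (i + 1L):n_ch) {
      counts <- tabulate(bins[[i]] + n_bins * (bins[[j]] - 1L),
                         nbins = n_bins * n_bins)
      v <- mi_from_joint(matrix(counts / n, n_bins, n_bins))
      mi[i, j] <- v; mi[j, i] <- v
      n_pairs <- n_pairs + 1L
    }
  }
  structure(list(mi = mi, entropy = diag(mi), n_bins = as.integer(n_bins),
                 n_pairs = n_pairs),
            class = "pairwise_mi")
}

#' @export
print.pairwise_mi <- function(x, ...) {
  cat("Pairwise channel mutual information:", nrow(x$mi), "channels,",
      x$n_pairs, "pair evaluations,", x$n_bins, "bins\n")
  off <- x$mi[upper.tri(x$mi)]
  cat(sprintf("  off-diagonal MI range: %.4f .. %.4f bits\n",
              min(off), max(off)))
  invisible(x)
}

#' Export a pairwise-MI matrix as CSV
#'
#' @param pm a [pairwise_mi()] object.
#' @param path output CSV path (channel-name headers).
#' @return `path`, invisibly.
#' @export
write_pairwise_mi_csv <- function(pm, path) {
  stopifnot(inherits(pm, "pairwise_mi"))
  utils::write.csv(as.data.frame(pm$mi), path, row.names = TRUE)
  invisible(path)
}
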