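#' Exponential linear unit
#'
#' `elu(x) = x` for `x >= 0` and `exp(x) - 1` otherwise; continuous and
#' monotone, used after the depthwise and separable convolution stages.
#'
#' @param x numeric vector/array.
#' @return elementwise ELU, same shape as `x`.
#' @examples
#' elu(c(-1, 0, 2.5))
#' @export
elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

# derivative of ELU given pre-activation x
elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[!neg] <- 1
  g[neg] <- exp(x[neg])
  g
}

#' Softmax activation
#'
#' Shift-invariant normalized exponential: subtracting the maximum before
#' exponentiating keeps the computation stable, and the output rows are
#' positive and sum to one.
#'
#' @param x numeric vector, or matrix with one score vector per row.
#' @return probabilities with the same shape as `x`.
#' @examples
#' softmax(c(0, log(2)))     # (1/3, 2/3)
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1L, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

#' Triangular cyclical learning-rate schedule
#'
#' The learning rate sweeps linearly from `base_lr` up to `max_lr` over
#' `step_size` iterations and back down over the next `step_size`,
#' repeating with period `2 * step_size`.  Iteration 0 sits at `base_lr`,
#' iteration `step_size` at `max_lr`.
#'
#' @param iteration 0-based iteration counter (vectorized).
#' @param base_lr,max_lr cycle bounds, `base_lr < max_lr`.
#' @param step_size half-period in iterations (>= 1).
#' @return learning rate(s) in `[base_lr, max_lr]`.
#' @examples
#' clr_schedule(0:8, 1e-6, 5e-2, 4)
#' @export
clr_schedule <- function(iteration, base_lr, max_lr, step_size) {
  if (base_lr >= max_lr) stop("base_lr must be smaller than max_lr")
  if (step_size < 1) stop("step_size must be at least 1")
  cycle <- floor(1 + iteration / (2 * step_size))
  x <- abs(iteration / step_size - 2 * cycle + 1)
  base_lr + (max_lr - base_lr) * pmax(0, 1 - x)
}
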