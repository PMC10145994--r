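# R-side numerical core of the compact convolutional network: parameter
# initialisation, dropout-mask generation and the Nadam update.  The fused
# forward/backward training step and the inference forward pass live in
# compiled code (src/eegnet_core.cpp); everything stochastic (weight init,
# shuffling, dropout) is drawn from R's RNG here, so a fixed seed fully
# determines training.

.bn_eps <- 1e-3
.bn_momentum <- 0.99

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# initialise all weights; uses the current RNG stream
eegnet_init_params <- function(cfg) {
  k <- cfg$chans
  list(
    W1 = glorot(cfg$kern_length, cfg$kern_length * cfg$F1,
                c(cfg$F1, cfg$kern_length)),
    g1 = rep(1, cfg$F1), be1 = rep(0, cfg$F1),
    rm1 = rep(0, cfg$F1), rv1 = rep(1, cfg$F1),
    W2 = glorot(k, k * cfg$D, c(cfg$F1, cfg$D, k)),
    g2 = rep(1, cfg$M), be2 = rep(0, cfg$M),
    rm2 = rep(0, cfg$M), rv2 = rep(1, cfg$M),
    Wd = glorot(cfg$sep_kern_length, cfg$sep_kern_length,
                c(cfg$M, cfg$sep_kern_length)),
    Wp = glorot(cfg$M, cfg$F2, c(cfg$F2, cfg$M)),
    g3 = rep(1, cfg$F2), be3 = rep(0, cfg$F2),
    rm3 = rep(0, cfg$F2), rv3 = rep(1, cfg$F2),
    W6 = glorot(cfg$flat, cfg$nb_classes, c(cfg$nb_classes, cfg$flat)),
    b6 = rep(0, cfg$nb_classes)
  )
}

.trainable <- c("W1", "g1", "be1", "W2", "g2", "be2",
                "Wd", "Wp", "g3", "be3", "W6", "b6")

# inverted-dropout masks in the flattened (N * time, maps) layout used by
# the compiled core; NULL when no dropout applies
draw_dropout_masks <- function(cfg, N) {
  if (cfg$dropout_rate <= 0) return(list(mask1 = NULL, mask2 = NULL))
  keep <- 1 - cfg$dropout_rate
  expand <- function(mk, Tn) mk[rep(seq_len(N), Tn), , drop = FALSE]
  if (cfg$dropout_type == "spatial") {
    m1 <- matrix(stats::rbinom(N * cfg$M, 1L, keep) / keep, N, cfg$M)
    m2 <- matrix(stats::rbinom(N * cfg$F2, 1L, keep) / keep, N, cfg$F2)
    list(mask1 = expand(m1, cfg$T1), mask2 = expand(m2, cfg$T2))
  } else {
    list(mask1 = matrix(stats::rbinom(N * cfg$T1 * cfg$M, 1L, keep) / keep,
                        N * cfg$T1, cfg$M),
         mask2 = matrix(stats::rbinom(N * cfg$T2 * cfg$F2, 1L, keep) / keep,
                        N * cfg$T2, cfg$F2))
  }
}

# one fused training step: forward + backward on a batch.
# X: (N, C, T) array, Y: one-hot matrix.  Returns grads, loss, hit count
# and the batch BN statistics.
eegnet_step <- function(params, cfg, X, Y, mask1 = NULL, mask2 = NULL) {
  storage.mode(X) <- "double"
  .eegnet_step_cpp(params, cfg, X, Y,
                   if (is.null(mask1)) NULL else mask1,
                   if (is.null(mask2)) NULL else mask2)
}

# inference-mode forward pass (running BN statistics, no dropout)
eegnet_infer <- function(params, cfg, X) {
  storage.mode(X) <- "double"
  .eegnet_infer_cpp(params, cfg, X)
}

nadam_init <- function(params) {
  zero <- function(p) { p[] <- 0; p }
  list(m = lapply(params[.trainable], zero),
       v = lapply(params[.trainable], zero),
       t = 0L)
}

# one Nadam step (Dozat's bias-corrected Nesterov-Adam)
nadam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in .trainable) {
    gr <- grads[[nm]]
    if (is.null(dim(params[[nm]]))) gr <- as.numeric(gr)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / (1 - beta1^(t + 1))
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- (beta1 * mhat + (1 - beta1) * gr / (1 - beta1^t)) /
      (sqrt(vhat) + eps)
    p <- params[[nm]]
    params[[nm]] <- p - lr * upd
  }
  list(params = params, state = state)
}
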