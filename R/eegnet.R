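#' Build a compact convolutional EEG classifier
#'
#' Constructs the network of [eegnet_config()] with freshly initialised
#' weights (Glorot-uniform convolutions and dense layer, unit-gain batch
#' normalisation).  The model is untrained until passed to
#' [eegnet_train()].
#'
#' @param config an [eegnet_config()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `"eegnet"`.
#' @export
eegnet_build <- function(config, seed = 1L) {
  stopifnot(inherits(config, "eegnet_config"))
  params <- with_seed(seed, eegnet_init_params(config))
  structure(list(config = config, params = params, fitted = FALSE,
                 history = NULL, train_config = NULL),
            class = "eegnet")
}

#' Train the classifier on an epoched trial set
#'
#' Minimises categorical cross-entropy with the Nadam optimiser, optionally
#' under a triangular cyclical learning-rate schedule
#' ([clr_schedule()]).  Weights are re-initialised from `train_cfg$seed`,
#' and the same seed drives epoch shuffling and dropout, so a fixed
#' `(trials, config, train_cfg)` triple reproduces the fitted weights
#' bit-for-bit.
#'
#' @param model an [eegnet_build()] model.
#' @param trials a [trial_set()] whose channel and sample axes match the
#'   model configuration.
#' @param train_cfg a [train_config()].
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return The fitted `"eegnet"` model, with a `history` data.frame
#'   (`epoch`, `lr`, `loss`, `accuracy`).
#' @export
eegnet_train <- function(model, trials, train_cfg = processing_train_config(),
                         verbose = 0L) {
  stopifnot(inherits(model, "eegnet"), inherits(train_cfg, "train_config"))
  cfg <- model$config
  X <- trials_to_input(trials, cfg)
  y <- trials$y
  if (length(y) == 0L) stop("data error: empty trial set")
  if (!all(y %in% seq_len(cfg$nb_classes)))
    stop("label error: labels must lie in 1..", cfg$nb_classes)
  N <- dim(X)[1]
  Y <- matrix(0, N, cfg$nb_classes)
  Y[cbind(seq_len(N), y)] <- 1

  bs <- min(train_cfg$batch_size, N)
  n_batches <- ceiling(N / bs)
  clr <- train_cfg$clr
  if (!is.null(clr) && is.null(clr$step_size))
    clr$step_size <- max(1L, (clr$step_size_epochs %||% 8) * n_batches)

  with_seed(train_cfg$seed, {
    params <- eegnet_init_params(cfg)
    state <- nadam_init(params)
    hist <- data.frame(epoch = seq_len(train_cfg$epochs), lr = NA_real_,
                       loss = NA_real_, accuracy = NA_real_)
    it <- 0L
    for (ep in seq_len(train_cfg$epochs)) {
      idx <- sample.int(N)
      ep_loss <- 0; ep_hits <- 0
      for (b in seq_len(n_batches)) {
        rows <- idx[(((b - 1L) * bs) + 1L):min(b * bs, N)]
        Xb <- X[rows, , , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        lr <- if (is.null(clr)) train_cfg$lr
              else clr_schedule(it, clr$base_lr, clr$max_lr, clr$step_size)
        masks <- draw_dropout_masks(cfg, length(rows))
        st0 <- eegnet_step(params, cfg, Xb, Yb, masks$mask1, masks$mask2)
        st <- nadam_step(params, st0$grads, state, lr)
        params <- st$params; state <- st$state
        # running batch-norm statistics (momentum update)
        bnb <- lapply(st0$bn_batch, as.numeric)
        params$rm1 <- .bn_momentum * params$rm1 + (1 - .bn_momentum) * bnb$m1
        params$rv1 <- .bn_momentum * params$rv1 + (1 - .bn_momentum) * bnb$v1
        params$rm2 <- .bn_momentum * params$rm2 + (1 - .bn_momentum) * bnb$m2
        params$rv2 <- .bn_momentum * params$rv2 + (1 - .bn_momentum) * bnb$v2
        params$rm3 <- .bn_momentum * params$rm3 + (1 - .bn_momentum) * bnb$m3
        params$rv3 <- .bn_momentum * params$rv3 + (1 - .bn_momentum) * bnb$v3
        ep_loss <- ep_loss + st0$loss * length(rows)
        ep_hits <- ep_hits + st0$hits
        it <- it + 1L
      }
      hist$lr[ep] <- if (is.null(clr)) train_cfg$lr
                     else clr_schedule(it - 1L, clr$base_lr, clr$max_lr,
                                       clr$step_size)
      hist$loss[ep] <- ep_loss / N
      hist$accuracy[ep] <- ep_hits / N
      if (verbose > 0L && ep %% verbose == 0L)
        message(sprintf("epoch %d/%d loss %.4f acc %.3f",
                        ep, train_cfg$epochs, hist$loss[ep],
                        hist$accuracy[ep]))
    }
    model$params <- params
    model$fitted <- TRUE
    model$history <- hist
    model$train_config <- train_cfg
    model
  })
}

#' Fit a compact convolutional classifier in one call
#'
#' Convenience wrapper around [eegnet_build()] + [eegnet_train()], the
#' package's main fitting function.
#'
#' @param trials a [trial_set()].
#' @param config an [eegnet_config()]; defaults to the processing-stage
#'   configuration sized to the trial set.
#' @param train_cfg a [train_config()].
#' @param ... passed to [eegnet_train()].
#' @return A fitted `"eegnet"` model.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(trials_per_class = 5, seed = 7)
#' tr <- generate_synthetic_trials(spec)
#' tr6 <- select_channels(tr, c("C3", "Cz", "C4", "P3", "Pz", "P4"))
#' fit <- eegnet(tr6, train_cfg = processing_train_config(epochs = 3,
#'                                                        batch_size = 30))
#' predict(fit, tr6)$labels[1:5]
#' }
#' @export
eegnet <- function(trials, config = NULL,
                   train_cfg = processing_train_config(), ...) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(config))
    config <- eegnet_config(chans = dim(trials$x)[2],
                            samples = trials$window_len)
  model <- eegnet_build(config, seed = train_cfg$seed)
  eegnet_train(model, trials, train_cfg, ...)
}

# coerce a trial_set (or rank-3/4 array) to the (N, C, T) input array,
# checking dimensions against the configuration
trials_to_input <- function(trials, cfg) {
  x <- if (inherits(trials, "trial_set")) trials$x else trials
  if (length(dim(x)) == 4L) dim(x) <- dim(x)[1:3]
  if (length(dim(x)) != 3L)
    stop("shape error: expected trials x channels x samples input")
  if (dim(x)[2] != cfg$chans || dim(x)[3] != cfg$samples)
    stop("shape error: expected (channels, samples) = (", cfg$chans, ", ",
         cfg$samples, "), got (", dim(x)[2], ", ", dim(x)[3], ")")
  x
}

#' Predict class probabilities and labels
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout).  Each probability row sums to one; the hard label is the
#' maximum-probability class, ties broken toward the lowest class code.
#'
#' @param object a (fitted or built) `"eegnet"` model.
#' @param newdata a [trial_set()] or rank-3/4 array.
#' @param batch inference chunk size.
#' @param ... unused.
#' @return list with `probs` (matrix, one row per trial, class-named
#'   columns) and `labels` (integer codes 1..nb_classes).
#' @export
predict.eegnet <- function(object, newdata, batch = 512L, ...) {
  cfg <- object$config
  X <- trials_to_input(newdata, cfg)
  N <- dim(X)[1]
  probs <- matrix(0, N, cfg$nb_classes)
  at <- 1L
  while (at <= N) {
    to <- min(at + batch - 1L, N)
    probs[at:to, ] <- eegnet_infer(object$params, cfg,
                                   X[at:to, , , drop = FALSE])
    at <- to + 1L
  }
  if (cfg$nb_classes == 6L) colnames(probs) <- names(mi_classes())
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}

#' @export
print.eegnet <- function(x, ...) {
  cfg <- x$config
  cat("Compact convolutional EEG classifier (EEGNet family)\n")
  cat(sprintf("  input %d channels x %d samples -> %d classes\n",
              cfg$chans, cfg$samples, cfg$nb_classes))
  cat(sprintf("  F1=%d D=%d F2=%d kern=%d sep_kern=%d pools=%d/%d  (%d parameters)\n",
              cfg$F1, cfg$D, cfg$F2, cfg$kern_length, cfg$sep_kern_length,
              cfg$pool1, cfg$pool2, sum(audit_parameters(cfg)$params)))
  if (x$fitted) {
    h <- x$history
    cat(sprintf("  fitted: %d epochs, final loss %.4f, training accuracy %.1f%%\n",
                nrow(h), h$loss[nrow(h)], 100 * h$accuracy[nrow(h)]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.eegnet <- function(object, ...) {
  print(object)
  cat("\n")
  print(audit_parameters(object$config))
  invisible(audit_parameters(object$config))
}

#' @export
coef.eegnet <- function(object, ...) object$params[.trainable]

#' @export
plot.eegnet <- function(x, ...) {
  if (!x$fitted) stop("nothing to plot: model is untrained")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "Training loss", ...)
  graphics::plot(h$epoch, 100 * h$accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy (%)", main = "Training accuracy", ...)
  invisible(h)
}

#' Save / load a model as a JSON container
#'
#' Weights and configuration are serialised to a single JSON text file,
#' portable across platforms.
#'
#' @param model a `"eegnet"` model.
#' @param path file path.
#' @return `path` invisibly; `eegnet_load()` returns the model.
#' @export
eegnet_save <- function(model, path) {
  stopifnot(inherits(model, "eegnet"))
  payload <- list(
    config = unclass(model$config),
    fitted = model$fitted,
    history = model$history,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname eegnet_save
#' @export
eegnet_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- eegnet_config(chans = cfg$chans, nb_classes = cfg$nb_classes,
                          samples = cfg$samples,
                          dropout_rate = cfg$dropout_rate,
                          dropout_type = cfg$dropout_type,
                          kern_length = cfg$kern_length, F1 = cfg$F1,
                          D = cfg$D, F2 = cfg$F2,
                          sep_kern_length = cfg$sep_kern_length,
                          pool1 = cfg$pool1, pool2 = cfg$pool2)
  params <- lapply(payload$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(v) <- p$dim
    v
  })
  structure(list(config = config, params = params,
                 fitted = isTRUE(payload$fitted),
                 history = payload$history, train_config = NULL),
            class = "eegnet")
}
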