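#' Compact convolutional network configuration
#'
#' Hyperparameters of the EEGNet-family architecture used throughout the
#' pipeline: a temporal convolution of `F1` filters (length `kern_length`,
#' unpadded bias-free, "same" time padding), batch normalisation, a
#' depthwise spatial convolution across all `chans` electrodes with depth
#' multiplier `D`, batch normalisation and ELU, average pooling by `pool1`,
#' dropout, a separable convolution (depthwise temporal length
#' `sep_kern_length`, then `F2` pointwise filters), batch normalisation and
#' ELU, average pooling by `pool2`, dropout, and a dense softmax output
#' over `nb_classes`.
#'
#' Defaults reproduce the processing-stage configuration: with
#' `chans = 8, samples = 170` the layer parameter counts are 16 (temporal
#' conv), 16 (BN), 128 (depthwise), 64 (BN), 512 (separable), 64 (BN) and
#' 486 (dense), with temporal lengths 170 -> 42 -> 5 and a flatten width
#' of 80.
#'
#' @param chans number of input channels k.
#' @param nb_classes number of output classes.
#' @param samples trial length in samples.
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param dropout_type `"spatial"` (drop whole feature maps) or `"plain"`.
#' @param kern_length temporal-convolution kernel length.
#' @param F1 number of temporal filters.
#' @param D depth multiplier (spatial filters per temporal filter).
#' @param F2 number of pointwise filters.
#' @param sep_kern_length separable depthwise kernel length.
#' @param pool1,pool2 average-pooling widths (floor division of the
#'   temporal axis).
#' @return An object of class `"eegnet_config"`.
#' @seealso [arbc_config()] for the single-channel ranking configuration.
#' @export
eegnet_config <- function(chans,
                          nb_classes = 6L,
                          samples = 170L,
                          dropout_rate = 0.25,
                          dropout_type = c("spatial", "plain"),
                          kern_length = 4L,
                          F1 = 4L, D = 4L, F2 = 16L,
                          sep_kern_length = 16L,
                          pool1 = 4L, pool2 = 8L) {
  dropout_type <- match.arg(dropout_type)
  cfg <- list(chans = as.integer(chans), nb_classes = as.integer(nb_classes),
              samples = as.integer(samples), dropout_rate = dropout_rate,
              dropout_type = dropout_type,
              kern_length = as.integer(kern_length),
              F1 = as.integer(F1), D = as.integer(D), F2 = as.integer(F2),
              sep_kern_length = as.integer(sep_kern_length),
              pool1 = as.integer(pool1), pool2 = as.integer(pool2))
  cfg$M <- cfg$F1 * cfg$D
  cfg$T1 <- cfg$samples %/% cfg$pool1
  cfg$T2 <- cfg$T1 %/% cfg$pool2
  cfg$flat <- cfg$F2 * cfg$T2
  if (cfg$T1 < 1L || cfg$T2 < 1L)
    stop("configuration error: pooling exhausts the temporal axis (",
         cfg$samples, " -> ", cfg$T1, " -> ", cfg$T2, ")")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(cfg, class = "eegnet_config")
}

#' Single-channel configuration for accuracy-based channel ranking
#'
#' The channel-ranking stage classifies each electrode alone, with temporal,
#' pointwise and spatial filter counts all set to four
#' (`F1 = F2 = D = 4`, `chans = 1`).
#'
#' @param ... overrides passed to [eegnet_config()].
#' @return An `"eegnet_config"`.
#' @export
arbc_config <- function(...) {
  args <- list(...)
  defaults <- list(chans = 1L, F1 = 4L, D = 4L, F2 = 4L)
  do.call(eegnet_config, utils::modifyList(defaults, args))
}

#' Training configuration
#'
#' The two stages of the pipeline use categorical cross-entropy and the
#' Nadam optimiser throughout.  The channel-ranking stage trains 2000
#' epochs at rate 0.001 with no learning-rate cycling; the processing
#' stage trains 1500 epochs at rate 0.0001 with a triangular cyclical
#' learning rate between 1e-6 and 5e-2.  Both use batch size 330.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size (capped at the data size at run time).
#' @param lr Nadam base learning rate (used when `clr` is `NULL`).
#' @param clr `NULL` for a constant rate, or a list with `base_lr`,
#'   `max_lr` and either `step_size` (iterations) or `step_size_epochs`
#'   (converted at run time).
#' @param seed RNG seed controlling weight init, shuffling and dropout.
#' @param n_repeats repeated-training count used by callers that average
#'   over repetitions.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 1500L, batch_size = 330L, lr = 1e-4,
                         clr = list(base_lr = 1e-6, max_lr = 5e-2,
                                    step_size_epochs = 8),
                         seed = 1L, n_repeats = 1L) {
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (!is.null(clr)) {
    stopifnot(is.list(clr), !is.null(clr$base_lr), !is.null(clr$max_lr))
    if (clr$base_lr >= clr$max_lr)
      stop("clr: base_lr must be smaller than max_lr")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, clr = clr, seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats)),
            class = "train_config")
}

#' @rdname train_config
#' @details `arbc_train_config()` is the channel-ranking recipe (2000
#'   epochs, Nadam 0.001, no cycling); `processing_train_config()` is the
#'   classification recipe (1500 epochs, Nadam 0.0001, CLR on).
#' @param ... overrides passed to [train_config()].
#' @export
arbc_train_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 2000L, batch_size = 330L, lr = 1e-3, clr = NULL),
    list(...))
  do.call(train_config, args)
}

#' @rdname train_config
#' @export
processing_train_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 1500L, batch_size = 330L, lr = 1e-4,
         clr = list(base_lr = 1e-6, max_lr = 5e-2, step_size_epochs = 8)),
    list(...))
  do.call(train_config, args)
}

#' Per-layer shape and parameter audit
#'
#' Walks the layer stack of a configuration (or a built model) and reports
#' each layer's output shape and parameter count.  Batch-normalisation
#' counts include the two trainable affine terms and the two running
#' statistics (4 per feature map), the convention under which the
#' processing-stage stack audits to 16 / 16 / 16k / 64 / 512 / 64 / 486.
#'
#' @param x an `"eegnet_config"` or `"eegnet"` model.
#' @return A data.frame of class `"layer_audit"` with columns `layer`,
#'   `output_shape` and `params`.
#' @examples
#' audit_parameters(eegnet_config(chans = 8))
#' @export
audit_parameters <- function(x) {
  cfg <- if (inherits(x, "eegnet")) x$config else x
  stopifnot(inherits(cfg, "eegnet_config"))
  shp <- function(...) paste0("(None, ", paste(c(...), collapse = ", "), ")")
  rows <- list(
    c("input",                 shp(cfg$chans, cfg$samples, 1), 0),
    c("conv2d_temporal",       shp(cfg$chans, cfg$samples, cfg$F1),
      cfg$F1 * cfg$kern_length),
    c("batch_normalization_1", shp(cfg$chans, cfg$samples, cfg$F1),
      4 * cfg$F1),
    c("depthwise_conv2d",      shp(1, cfg$samples, cfg$M),
      cfg$M * cfg$chans),
    c("batch_normalization_2", shp(1, cfg$samples, cfg$M), 4 * cfg$M),
    c("activation_1",          shp(1, cfg$samples, cfg$M), 0),
    c("average_pooling2d_1",   shp(1, cfg$T1, cfg$M), 0),
    c("dropout_1",             shp(1, cfg$T1, cfg$M), 0),
    c("separable_conv2d",      shp(1, cfg$T1, cfg$F2),
      cfg$M * cfg$sep_kern_length + cfg$F2 * cfg$M),
    c("batch_normalization_3", shp(1, cfg$T1, cfg$F2), 4 * cfg$F2),
    c("activation_2",          shp(1, cfg$T1, cfg$F2), 0),
    c("average_pooling2d_2",   shp(1, cfg$T2, cfg$F2), 0),
    c("dropout_2",             shp(1, cfg$T2, cfg$F2), 0),
    c("flatten",               shp(cfg$flat), 0),
    c("dense",                 shp(cfg$nb_classes),
      cfg$flat * cfg$nb_classes + cfg$nb_classes),
    c("softmax",               shp(cfg$nb_classes), 0))
  out <- data.frame(layer = vapply(rows, `[`, "", 1),
                    output_shape = vapply(rows, `[`, "", 2),
                    params = as.integer(vapply(rows, `[`, "", 3)))
  class(out) <- c("layer_audit", "data.frame")
  out
}

#' @export
print.layer_audit <- function(x, ...) {
  cat("Layer audit (", sum(x$params), " parameters incl. BN statistics)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
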