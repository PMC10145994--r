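#' Stratified k-fold partition of a trial set
#'
#' Deterministic under `seed`.  In stratified mode each class's shuffled
#' trials are dealt to the currently least-loaded fold, so fold sizes
#' differ by at most one and class proportions are preserved within one
#' trial per fold.
#'
#' @param trials a [trial_set()].
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified preserve class proportions per fold.
#' @return An object of class `"fold_plan"`: list with `k`, `folds`
#'   (list of trial-index vectors), `seed`, `stratified`.
#' @export
make_folds <- function(trials, k = 10L, seed = 1L, stratified = TRUE) {
  n <- n_trials(trials)
  if (k > n) stop("argument error: k (", k, ") exceeds trial count (", n, ")")
  if (k < 2L) stop("argument error: k must be at least 2")
  folds <- vector("list", k)
  with_seed(derive_seed(seed, 101L), {
    load <- integer(k)
    groups <- if (stratified) split(seq_len(n), trials$y)
              else list(seq_len(n))
    for (gr in groups) {
      gr <- if (length(gr) > 1L) sample(gr) else gr
      for (ix in gr) {
        f <- which.min(load)      # lowest fold index wins ties
        folds[[f]] <- c(folds[[f]], ix)
        load[f] <- load[f] + 1L
      }
    }
  })
  structure(list(k = as.integer(k), folds = folds, seed = as.integer(seed),
                 stratified = stratified),
            class = "fold_plan")
}

#' Binary accuracy from confusion counts, in percent
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn nonnegative counts, not all zero.
#' @return accuracy percentage.
#' @examples
#' accuracy_from_counts(3, 90, 4, 3)   # 93
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("undefined metric: all counts are zero")
  100 * (tp + tn) / tot
}

#' Six-class confusion matrix
#'
#' @param true_labels,predicted_labels integer codes in 1..6, equal length.
#' @return A 6 x 6 integer matrix of class `"confusion_matrix"`; rows are
#'   true classes, columns predicted, in paradigm order.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (!all(true_labels %in% 1:6) || !all(predicted_labels %in% 1:6))
    stop("label error: labels must lie in 1..6")
  lv <- names(mi_classes())
  m <- table(factor(true_labels, 1:6, lv), factor(predicted_labels, 1:6, lv))
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("true", "predicted")
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (", sum(x), " trials, rows = true class)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Write a confusion matrix as CSV with class-name headers
#' @param cm a [confusion()] matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

# internal: train on all folds but `fold`, evaluate on `fold`
.cv_fold <- function(trials, model_cfg, train_cfg, plan, fold) {
  test_ix <- plan$folds[[fold]]
  train_ix <- setdiff(seq_len(n_trials(trials)), test_ix)
  sub <- function(ix) trial_set(trials$x[ix, , , , drop = FALSE],
                                trials$y[ix], trials$channel_names,
                                trials$subject_ids[ix], trials$window_len)
  cfg_fold <- train_cfg
  cfg_fold$seed <- derive_seed(train_cfg$seed, fold)
  fit <- eegnet_train(eegnet_build(model_cfg, seed = cfg_fold$seed),
                      sub(train_ix), cfg_fold)
  pred <- predict(fit, sub(test_ix))
  list(true = trials$y[test_ix], pred = pred$labels)
}

#' k-fold cross-validation of the classifier
#'
#' Trains a fresh model per fold on the remaining folds and evaluates on
#' the held-out fold.  Overall accuracy is the trace of the summed
#' confusion matrix over the total (the multi-class generalisation of the
#' binary TP/TN accuracy ratio); per-class one-vs-rest accuracies and
#' diagonal (recall) percentages are also reported.
#'
#' @param trials a [trial_set()].
#' @param model_cfg an [eegnet_config()]; defaults to the processing-stage
#'   configuration sized to the data.
#' @param train_cfg a [train_config()].
#' @param plan a [make_folds()] plan; built from `k` and `seed` if omitted.
#' @param k,seed,stratified fold-plan parameters when `plan` is `NULL`.
#' @param per_subject evaluate each subject tag separately (a named list of
#'   reports is returned) instead of pooling.
#' @param verbose print one line per fold.
#' @return An object of class `"mi_cv"` (or a named list of them): list
#'   with `overall` (%), `per_fold` (%), `mean`, `sd`, `confusion`,
#'   `per_class` (data.frame: class, diagonal_pct, ovr_accuracy), `n`,
#'   `subject`.
#' @export
cross_validate <- function(trials, model_cfg = NULL,
                           train_cfg = processing_train_config(),
                           plan = NULL, k = 10L, seed = 1L,
                           stratified = TRUE, per_subject = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  if (per_subject) {
    tags <- unique(trials$subject_ids)
    out <- lapply(tags, function(tag) {
      ix <- which(trials$subject_ids == tag)
      sub <- trial_set(trials$x[ix, , , , drop = FALSE], trials$y[ix],
                       trials$channel_names, trials$subject_ids[ix],
                       trials$window_len)
      r <- cross_validate(sub, model_cfg, train_cfg, plan = NULL, k = k,
                          seed = seed, stratified = stratified,
                          verbose = verbose)
      r$subject <- tag
      r
    })
    names(out) <- tags
    return(out)
  }
  if (is.null(model_cfg))
    model_cfg <- eegnet_config(chans = dim(trials$x)[2],
                               samples = trials$window_len)
  if (is.null(plan)) plan <- make_folds(trials, k = k, seed = seed,
                                        stratified = stratified)
  res <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    res[[f]] <- .cv_fold(trials, model_cfg, train_cfg, plan, f)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.1f%%", f, plan$k,
                      100 * mean(res[[f]]$true == res[[f]]$pred)))
  }
  true <- unlist(lapply(res, `[[`, "true"))
  pred <- unlist(lapply(res, `[[`, "pred"))
  cm <- confusion(true, pred)
  per_fold <- vapply(res, function(r) 100 * mean(r$true == r$pred),
                     numeric(1))
  per_class <- data.frame(
    class = names(mi_classes()),
    diagonal_pct = vapply(1:6, function(c) {
      tot <- sum(cm[c, ])
      if (tot == 0) NA_real_ else 100 * cm[c, c] / tot
    }, numeric(1)),
    ovr_accuracy = vapply(1:6, function(c) {
      tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp
      fp <- sum(cm[, c]) - tp; tn <- sum(cm) - tp - fn - fp
      accuracy_from_counts(tp, tn, fp, fn)
    }, numeric(1)))
  structure(list(overall = 100 * sum(diag(cm)) / sum(cm),
                 per_fold = per_fold,
                 mean = mean(per_fold), sd = stats::sd(per_fold),
                 confusion = cm, per_class = per_class,
                 n = sum(cm), subject = "pooled",
                 k = plan$k, seed = plan$seed),
            class = "mi_cv")
}

#' @export
print.mi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %d trials)\n",
              x$k, x$subject, x$n))
  cat(sprintf("  overall accuracy: %.1f%%  (per-fold mean %.1f%% +/- %.1f)\n",
              x$overall, x$mean, x$sd))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' @param report an `"mi_cv"` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "mi_cv"))
  payload <- list(subject = report$subject, k = report$k,
                  seed = report$seed, n_trials = report$n,
                  overall_accuracy = report$overall,
                  per_fold_accuracy = report$per_fold,
                  mean_accuracy = report$mean, sd_accuracy = report$sd,
                  per_class = report$per_class,
                  confusion = unclass(report$confusion))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Per-trial inference latency
#'
#' Wall-clock timing of single-trial inference after warm-up discards.
#' Timings are hardware- and load-dependent: only sanity properties
#' (positive, finite, min <= mean <= max) are stable.
#'
#' @param model a built or fitted `"eegnet"`.
#' @param trials a [trial_set()].
#' @param warmup untimed warm-up inferences.
#' @return An object of class `"latency_report"`: list with `mean_ms`,
#'   `sd_ms`, `min_ms`, `max_ms`, `n`, `hardware`.
#' @export
measure_latency <- function(model, trials, warmup = 5L) {
  stopifnot(inherits(model, "eegnet"))
  n <- n_trials(trials)
  one <- function(i) {
    x <- trials$x[i, , , , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    predict(model, x)
    (proc.time()[["elapsed"]] - t0) * 1000
  }
  for (i in seq_len(min(warmup, n))) one(((i - 1L) %% n) + 1L)
  times <- vapply(seq_len(n), one, numeric(1))
  si <- Sys.info()
  structure(list(mean_ms = mean(times), sd_ms = stats::sd(times),
                 min_ms = min(times), max_ms = max(times), n = n,
                 hardware = paste0(si[["sysname"]], " ", si[["machine"]],
                                   ", ", R.version.string)),
            class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf(
    "Per-trial inference latency over %d trials: %.2f ms (sd %.2f, range %.2f-%.2f)\n",
    x$n, x$mean_ms, x$sd_ms, x$min_ms, x$max_ms))
  cat("  hardware:", x$hardware, "\n")
  invisible(x)
}
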