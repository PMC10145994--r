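#' Construct an EEG recording session
#'
#' A session is a continuous multichannel recording with a per-sample task
#' marker stream: 0 where no task is cued, 1..6 while one of the six
#' motor-imagery tasks is active.
#'
#' @param data numeric matrix, samples x channels, amplitudes in microvolts.
#' @param marker integer vector, one code per sample row (0 or 1..6).
#' @param samp_freq sampling frequency in Hz.
#' @param channel_names ordered channel labels aligned to `data` columns.
#' @param subject_id subject tag.
#' @return An object of class `"eeg_session"`.
#' @export
eeg_session <- function(data, marker, samp_freq, channel_names,
                        subject_id = "S1") {
  data <- as.matrix(data)
  marker <- as.integer(marker)
  if (length(marker) != nrow(data))
    stop("marker length (", length(marker),
         ") must equal the number of sample rows (", nrow(data), ")")
  if (!is.numeric(samp_freq) || samp_freq <= 0)
    stop("samp_freq must be a positive number")
  if (length(channel_names) != ncol(data))
    stop("channel_names length must equal the number of data columns")
  bad <- marker[marker != 0L & !(marker %in% 1:6)]
  if (length(bad))
    stop("nonzero marker codes must lie in 1..6; found: ",
         paste(unique(bad), collapse = ", "))
  colnames(data) <- channel_names
  structure(
    list(data = data, marker = marker, samp_freq = samp_freq,
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id)),
    class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat("EEG session:", x$subject_id, "-", nrow(x$data), "samples x",
      ncol(x$data), "channels @", x$samp_freq, "Hz\n")
  runs <- marker_runs(x$marker)
  cat("  task runs:", sum(runs$code != 0L), "\n")
  invisible(x)
}

#' Load a HaLT-layout MAT-file as a session
#'
#' The file is expected to contain one top-level record (a MATLAB struct,
#' any variable name) with fields `data` (samples x channels), `marker`
#' (per-sample code), `sampFreq` and `chnames` (ordered channel labels).
#' Columns are matched to the montage by name, case-insensitively; columns
#' not in the montage (auxiliary electrodes, reference leads) are dropped
#' and the result follows montage order.  Marker codes outside 1..6 (the
#' benchmark's service codes, e.g. 91/92/99) are remapped to 0 (no task);
#' the number of remapped samples is kept in attribute `"n_service_samples"`.
#'
#' @param path MAT v5 file path.
#' @param montage a [halt_montage()] object.
#' @param subject_id optional subject tag; defaults to an `id` field when
#'   present, else the file name.
#' @return An [eeg_session()] restricted to the 19 montage channels.
#' @export
load_session <- function(path, montage = halt_montage(), subject_id = NULL) {
  vars <- mat5_read(path)
  rec <- NULL
  for (v in vars) if (is.list(v) && !is.null(names(v))) { rec <- v; break }
  if (is.null(rec))
    stop("MAT file format error: no top-level record struct found in ", path)
  for (f in c("data", "marker", "sampFreq", "chnames")) {
    if (is.null(rec[[f]]))
      stop("MAT file format error: missing required field '", f, "'")
  }
  data <- as.matrix(rec$data)
  chnames <- unlist(rec$chnames)
  if (length(chnames) != ncol(data))
    stop("MAT file format error: chnames length (", length(chnames),
         ") does not match data columns (", ncol(data), ")")
  hit <- match(tolower(montage$names), tolower(chnames))
  if (anyNA(hit))
    stop("montage error: channel(s) not present in file: ",
         paste(montage$names[is.na(hit)], collapse = ", "))
  marker <- as.integer(round(rec$marker))
  service <- marker != 0L & !(marker %in% 1:6)
  marker[service] <- 0L
  sess <- eeg_session(
    data = data[, hit, drop = FALSE],
    marker = marker,
    samp_freq = as.numeric(rec$sampFreq)[1],
    channel_names = montage$names,
    subject_id = subject_id %||% as.character(rec$id %||%
      sub("\\.mat$", "", basename(path))))
  attr(sess, "n_service_samples") <- sum(service)
  sess
}

#' Write a session as a HaLT-layout MAT-file
#'
#' Inverse of [load_session()]: `load_session(write_session(s, p))` equals
#' `s` on the montage channels, markers and sampling frequency.
#'
#' @param session an [eeg_session()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  rec <- list(
    id = session$subject_id,
    sampFreq = session$samp_freq,
    marker = as.numeric(session$marker),
    data = unname(session$data),
    chnames = as.list(session$channel_names))
  mat5_write(list(o = rec), path)
  invisible(path)
}

# maximal runs of constant marker code: data.frame(code, start, length)
marker_runs <- function(marker) {
  r <- rle(as.integer(marker))
  ends <- cumsum(r$lengths)
  data.frame(code = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths)
}

#' Construct a set of epoched, labelled trials
#'
#' @param x rank-4 numeric array, trials x channels x samples x 1
#'   (microvolts); a rank-3 array is promoted.
#' @param y integer class codes in 1..6, one per trial.
#' @param channel_names ordered labels for the channel axis.
#' @param subject_ids per-trial subject tags (recycled if scalar).
#' @param window_len samples per trial.
#' @return An object of class `"trial_set"`.
#' @export
trial_set <- function(x, y, channel_names,
                      subject_ids = "S1", window_len = dim(x)[3]) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == 1L)
  y <- as.integer(y)
  if (dim(x)[1] != length(y))
    stop("number of trials (", dim(x)[1], ") must equal length of y (",
         length(y), ")")
  if (length(y) && !all(y %in% 1:6))
    stop("class labels must lie in 1..6")
  if (dim(x)[3] != window_len)
    stop("samples axis (", dim(x)[3], ") must equal window_len (",
         window_len, ")")
  if (dim(x)[2] != length(channel_names))
    stop("channel axis must match channel_names")
  subject_ids <- rep_len(as.character(subject_ids), length(y))
  structure(
    list(x = x, y = y, channel_names = as.character(channel_names),
         subject_ids = subject_ids, window_len = as.integer(window_len)),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("Trial set:", dim(x$x)[1], "trials x", dim(x$x)[2], "channels x",
      x$window_len, "samples\n")
  if (length(x$y)) {
    tab <- table(factor(x$y, levels = 1:6, labels = names(mi_classes())))
    print(tab)
  }
  invisible(x)
}

#' Number of trials in a trial set
#' @param trials a [trial_set()].
#' @return integer trial count.
#' @export
n_trials <- function(trials) dim(trials$x)[1]

#' Epoch a session into fixed-length labelled trials
#'
#' One trial is cut per maximal run of a constant nonzero marker code.  The
#' window starts `trim` samples after run onset and spans `window_len`
#' samples, so artifacts at the beginning and end of each ~1 s task are
#' discarded (the default 170-sample window is 0.85 s at 200 Hz, trimmed
#' symmetrically from a 200-sample task).  Runs too short for
#' `window_len + 2 * trim` are skipped and counted in attribute
#' `"n_skipped"`; `"n_runs"` records the number of task runs seen.
#'
#' @param session an [eeg_session()].
#' @param window_len trial length in samples.
#' @param trim samples discarded at the start of each run (and implicitly at
#'   its end, by the run-length requirement).
#' @return A [trial_set()].
#' @export
extract_trials <- function(session, window_len = 170L, trim = 15L) {
  stopifnot(inherits(session, "eeg_session"))
  if (trim < 0) stop("trim must be nonnegative")
  if (window_len < 1) stop("window_len must be positive")
  runs <- marker_runs(session$marker)
  runs <- runs[runs$code != 0L, , drop = FALSE]
  keep <- runs$length >= window_len + 2L * trim
  kept <- runs[keep, , drop = FALSE]
  n_ch <- ncol(session$data)
  if (nrow(runs) == 0L) warning("no task runs found in marker stream")
  x <- array(0, dim = c(nrow(kept), n_ch, window_len, 1L))
  for (i in seq_len(nrow(kept))) {
    from <- kept$start[i] + trim
    x[i, , , 1L] <- t(session$data[from:(from + window_len - 1L), ,
                                   drop = FALSE])
  }
  ts <- trial_set(x, kept$code, session$channel_names,
                  subject_ids = session$subject_id, window_len = window_len)
  attr(ts, "n_runs") <- nrow(runs)
  attr(ts, "n_skipped") <- sum(!keep)
  ts
}

#' Restrict a trial set to an ordered channel subset
#'
#' @param trials a [trial_set()].
#' @param subset ordered channel names (e.g. a discriminant channel subset).
#' @param montage montage used for name validation.
#' @return A [trial_set()] whose channel axis follows `subset` order.
#' @export
select_channels <- function(trials, subset, montage = halt_montage()) {
  stopifnot(inherits(trials, "trial_set"))
  montage_match(subset, montage)  # validates names against the montage
  idx <- match(tolower(subset), tolower(trials$channel_names))
  if (anyNA(idx))
    stop("channel(s) not present in trial set: ",
         paste(subset[is.na(idx)], collapse = ", "))
  trial_set(trials$x[, idx, , , drop = FALSE], trials$y,
            channel_names = trials$channel_names[idx],
            subject_ids = trials$subject_ids,
            window_len = trials$window_len)
}

#' Concatenate trial sets (e.g. across subjects)
#'
#' @param ... trial sets sharing channel layout and window length.
#' @return A pooled [trial_set()].
#' @export
bind_trials <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "trial_set")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1]]
  for (p in parts) {
    stopifnot(inherits(p, "trial_set"),
              identical(p$channel_names, ref$channel_names),
              identical(p$window_len, ref$window_len))
  }
  ns <- vapply(parts, n_trials, integer(1))
  x <- array(0, dim = c(sum(ns), dim(ref$x)[2], ref$window_len, 1L))
  at <- 0L
  for (p in parts) {
    if (n_trials(p) > 0L) x[(at + 1L):(at + n_trials(p)), , , ] <- p$x
    at <- at + n_trials(p)
  }
  trial_set(x, unlist(lapply(parts, `[[`, "y")),
            channel_names = ref$channel_names,
            subject_ids = unlist(lapply(parts, `[[`, "subject_ids")),
            window_len = ref$window_len)
}
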