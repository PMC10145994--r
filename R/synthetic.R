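#' Specification for synthetic HaLT-like sessions
#'
#' The generator emulates the recording characteristics of the source
#' paradigm — 19 channels in 10-20 layout at 200 Hz, six cued tasks of
#' about 1 s separated by rest gaps, microvolt-scale amplitudes inside a
#' 0.53-70 Hz passband — and plants a known discriminative structure:
#' during a task run, a band-limited oscillation (class-specific frequency
#' band, coherent across channels) is added to that class's informative
#' channels on top of independent pink-noise background.  The planted map
#' is returned as ground truth so selection and classification can be
#' validated against it.
#'
#' @param n_subjects number of subjects to simulate.
#' @param trials_per_class task runs per class per subject session.
#' @param informative_map named list, class name or code -> character vector
#'   of informative channel names.  Default: one shared sensorimotor clique
#'   `C3, Cz, C4, P3, Pz, P4` for every class, giving both selectors a
#'   recoverable 6-channel target.
#' @param osc_band_hz list of 6 frequency bands `c(lo, hi)` (Hz), one per
#'   class code; `NULL` for a class means no oscillation is injected (the
#'   "passive" near-flat class).  Bands must respect the 0.53-70 Hz
#'   recording passband.
#' @param snr ratio of in-run class-oscillation power to background-noise
#'   power on an informative channel; 0 removes the planted effect.
#' @param noise_exponent spectral slope of the 1/f^a background.
#' @param noise_rms_uv background noise RMS amplitude (microvolts).
#' @param common_mode_amp amplitude (microvolts) of a slow drift shared by
#'   all channels.
#' @param run_len task-run length in samples (>= 200).
#' @param gap_len zero-marker gap between runs in samples (>= 50).
#' @param samp_freq sampling frequency (Hz).
#' @param seed base seed; each subject derives its own stream from it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 1L,
                           trials_per_class = 20L,
                           informative_map = NULL,
                           osc_band_hz = list(c(8, 12), c(12, 16), NULL,
                                              c(16, 20), c(20, 24), c(24, 28)),
                           snr = 4,
                           noise_exponent = 1,
                           noise_rms_uv = 10,
                           common_mode_amp = 2,
                           run_len = 200L,
                           gap_len = 60L,
                           samp_freq = 200,
                           seed = 1L) {
  montage <- halt_montage()
  if (is.null(informative_map)) {
    clique <- c("C3", "Cz", "C4", "P3", "Pz", "P4")
    informative_map <- stats::setNames(rep(list(clique), 6), names(mi_classes()))
  }
  if (length(informative_map) != 6L)
    stop("informative_map must give a channel subset for each of 6 classes")
  # accept names or codes as list names; normalize to class-name keys
  key <- names(informative_map)
  if (!is.null(key) && all(key %in% as.character(1:6)))
    names(informative_map) <- names(mi_classes())[as.integer(key)]
  for (chs in informative_map) montage_match(chs, montage)
  stopifnot(length(osc_band_hz) == 6L)
  for (b in osc_band_hz) {
    if (!is.null(b)) {
      stopifnot(length(b) == 2L, b[1] < b[2])
      if (b[1] <= 0.5 || b[2] >= 70)
        stop("oscillation bands must lie within (0.5, 70) Hz")
    }
  }
  if (snr < 0) stop("snr must be nonnegative")
  if (run_len < 200L) stop("run_len must be at least 200 samples")
  if (gap_len < 50L) stop("gap_len must be at least 50 samples")
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_class = as.integer(trials_per_class),
         informative_map = informative_map,
         osc_band_hz = osc_band_hz,
         snr = snr, noise_exponent = noise_exponent,
         noise_rms_uv = noise_rms_uv, common_mode_amp = common_mode_amp,
         run_len = as.integer(run_len), gap_len = as.integer(gap_len),
         samp_freq = samp_freq, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# 1/f^a noise with unit RMS, via spectral shaping of white Gaussian noise
pink_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # two-sided frequency index
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic session with ground truth
#'
#' Deterministic in `(spec, subject_index)`: the subject's RNG stream is
#' derived from `spec$seed` and `subject_index`, so repeated calls give
#' byte-identical sessions.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_index 1-based subject number.
#' @return A list with elements `session` (an [eeg_session()]) and
#'   `ground_truth` (list: `subject`, `seed`, `informative_map`, `snr`).
#' @export
generate_synthetic_session <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  montage <- halt_montage()
  subject_id <- sprintf("SYN%02d", subject_index)
  with_seed(derive_seed(spec$seed, subject_index), {
    n_trials <- spec$trials_per_class * 6L
    order <- sample(rep(1:6, spec$trials_per_class))
    lead <- 100L
    n_samples <- lead + n_trials * (spec$run_len + spec$gap_len)
    marker <- integer(n_samples)
    onsets <- lead + (seq_len(n_trials) - 1L) * (spec$run_len + spec$gap_len) + 1L
    for (i in seq_len(n_trials))
      marker[onsets[i]:(onsets[i] + spec$run_len - 1L)] <- order[i]

    n_ch <- length(montage$names)
    data <- matrix(0, n_samples, n_ch)
    for (c in seq_len(n_ch))
      data[, c] <- spec$noise_rms_uv * pink_noise(n_samples, spec$noise_exponent)
    if (spec$common_mode_amp > 0) {
      t_s <- (seq_len(n_samples) - 1L) / spec$samp_freq
      drift <- spec$common_mode_amp *
        (sin(2 * pi * 0.3 * t_s + stats::runif(1, 0, 2 * pi)) +
           0.5 * sin(2 * pi * 0.7 * t_s + stats::runif(1, 0, 2 * pi)))
      data <- data + drift
    }
    amp <- spec$noise_rms_uv * sqrt(2 * spec$snr)
    for (i in seq_len(n_trials)) {
      cls <- order[i]
      band <- spec$osc_band_hz[[cls]]
      if (is.null(band) || spec$snr == 0) next
      freq <- stats::runif(1, band[1], band[2])
      phase <- stats::runif(1, 0, 2 * pi)
      idx <- onsets[i]:(onsets[i] + spec$run_len - 1L)
      wave <- amp * sin(2 * pi * freq * (seq_along(idx) - 1L) /
                          spec$samp_freq + phase)
      chs <- montage_match(spec$informative_map[[cls]], montage)
      data[idx, chs] <- data[idx, chs] + wave
    }
    session <- eeg_session(data, marker, spec$samp_freq, montage$names,
                           subject_id = subject_id)
    list(session = session,
         ground_truth = list(subject = subject_id,
                             seed = spec$seed,
                             informative_map = spec$informative_map,
                             snr = spec$snr))
  })
}

#' Generate, write and epoch a pooled multi-subject synthetic trial set
#'
#' Convenience wrapper: simulates `spec$n_subjects` sessions and pools the
#' epoched trials, the usual input to channel selection.
#'
#' @param spec a [synthetic_spec()].
#' @param window_len,trim epoching parameters, see [extract_trials()].
#' @return A pooled [trial_set()] with attribute `"ground_truth"`.
#' @export
generate_synthetic_trials <- function(spec, window_len = 170L, trim = 15L) {
  parts <- lapply(seq_len(spec$n_subjects), function(i) {
    extract_trials(generate_synthetic_session(spec, i)$session,
                   window_len = window_len, trim = trim)
  })
  pooled <- bind_trials(parts)
  attr(pooled, "ground_truth") <-
    list(informative_map = spec$informative_map, snr = spec$snr,
         seed = spec$seed)
  pooled
}
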