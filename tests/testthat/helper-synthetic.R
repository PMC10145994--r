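# Shared fixtures, generated in code.  The default synthetic spec plants a
# coherent six-channel sensorimotor clique (C3, Cz, C4, P3, Pz, P4) with
# class-specific oscillation bands over pink-noise background.

planted_clique <- c("C3", "Cz", "C4", "P3", "Pz", "P4")

# memoised pooled trial set under the default spec
.fixture_env <- new.env(parent = emptyenv())
default_trials <- function(seed = 11L, trials_per_class = 20L) {
  key <- paste0("tr_", seed, "_", trials_per_class)
  if (is.null(.fixture_env[[key]])) {
    spec <- synthetic_spec(trials_per_class = trials_per_class, seed = seed)
    .fixture_env[[key]] <- generate_synthetic_trials(spec)
  }
  .fixture_env[[key]]
}

# a small trial set restricted to a few channels (3 informative + 2 noise)
mini_trials <- function(seed = 11L) {
  select_channels(default_trials(seed), c("C3", "Cz", "P3", "Fp1", "T4"),
                  montage = halt_montage())
}

# tiny network configuration for fast structural tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(chans = 3L, nb_classes = 4L, samples = 24L, dropout_rate = 0,
         kern_length = 3L, F1 = 2L, D = 2L, F2 = 3L, sep_kern_length = 5L,
         pool1 = 2L, pool2 = 3L),
    list(...))
  do.call(eegnet_config, args)
}

tiny_xy <- function(cfg, n = 7L, seed = 42L) {
  set.seed(seed)
  x <- array(stats::rnorm(n * cfg$chans * cfg$samples),
             c(n, cfg$chans, cfg$samples))
  y <- sample(seq_len(cfg$nb_classes), n, replace = TRUE)
  Y <- matrix(0, n, cfg$nb_classes)
  Y[cbind(seq_len(n), y)] <- 1
  list(x = x, y = y, Y = Y)
}
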