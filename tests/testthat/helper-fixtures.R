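# Shared fixtures, all generated in code.

# Random SPD matrix with eigenvalues bounded away from zero.
random_spd <- function(d, seed = NULL) {
  gen <- function() {
    A <- matrix(rnorm(d * d), d)
    crossprod(A) / d + diag(0.5, d)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A short, cheap paradigm for unit tests (2 blocks x 3 trials).
tiny_spec <- function(state = "RESPONSIVE", ...) {
  paradigm_spec(n_blocks = 2, trials_per_block = 3, state = state, ...)
}

# Synthetic labelled epochs drawn from pure noise (exchangeable null).
null_epochs <- function(n_trials = 20, n_ch = 6, ns = 30, seed = 1) {
  withr::with_seed(seed, {
    data <- array(rnorm(n_trials * n_ch * ns), c(n_trials, n_ch, ns))
    labels <- factor(rep(c("IMAGERY", "NO_IMAGERY"), length.out = n_trials),
                     levels = c("IMAGERY", "NO_IMAGERY"))
    structure(list(data = data, labels = labels, chromophore = "HBO",
                   sampling_rate = 6.94, window = c(0, 12)),
              class = "nirs_epochs")
  })
}

# Synthetic epochs with a fixed spatial pattern added to IMAGERY trials.
patterned_epochs <- function(n_trials = 40, n_ch = 8, ns = 50, snr = 3,
                             seed = 1) {
  withr::with_seed(seed, {
    pattern <- rnorm(n_ch)
    pattern <- pattern / sqrt(sum(pattern^2))
    wave <- sin(2 * pi * seq_len(ns) / ns)
    data <- array(rnorm(n_trials * n_ch * ns), c(n_trials, n_ch, ns))
    labels <- factor(rep(c("IMAGERY", "NO_IMAGERY"), each = n_trials / 2),
                     levels = c("IMAGERY", "NO_IMAGERY"))
    for (i in which(labels == "IMAGERY"))
      data[i, , ] <- data[i, , ] + snr * pattern %o% wave
    structure(list(data = data, labels = labels, chromophore = "HBO",
                   sampling_rate = 6.94, window = c(0, 12),
                   pattern = pattern, wave = wave),
              class = "nirs_epochs")
  })
}

# One cached preprocessed dataset per state so expensive fixtures are
# built once per test run.
.fixture_env <- new.env(parent = emptyenv())
cached_epochs <- function(state, chromophore, seed = 11) {
  key <- paste(state, chromophore, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    hbkey <- paste(state, seed, sep = "_")
    if (is.null(.fixture_env[[hbkey]])) {
      runs <- simulate_dataset(state, seed = seed)
      .fixture_env[[hbkey]] <- lapply(runs, preprocess_run)
    }
    .fixture_env[[key]] <- pool_epochs(
      lapply(.fixture_env[[hbkey]], make_epochs, chromophore = chromophore))
  }
  .fixture_env[[key]]
}
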