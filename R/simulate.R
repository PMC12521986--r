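#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (unit scale) with modes at
#' `peak_s` and `undershoot_s`, normalised to unit peak.
#'
#' @param t Time points, seconds.
#' @param peak_s Time to peak, seconds.
#' @param undershoot_s Time to undershoot, seconds.
#' @param undershoot_ratio Depth of the undershoot relative to the peak.
#' @return Numeric vector of the same length as `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  h <- dgamma(t, shape = peak_s + 1, scale = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot_s + 1, scale = 1)
  h / max(h)
}

# AR(1) noise with stationary sd `sd`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = rnorm(1, 0, sd)))
}

#' Simulate haemoglobin concentration changes for one run
#'
#' Builds per-channel HbO/HbR time courses from (i) a task-evoked
#' component — a double-gamma HRF convolved with a boxcar spanning the
#' task window of every IMAGERY trial, present only in the RESPONSIVE
#' state, scaled per channel by a smooth unimodal spatial profile and
#' jittered in amplitude per trial; (ii) systemic physiology (Mayer
#' wave, cardiac pulsation, linear drift) sharing one time course across
#' channels with channel-specific gains, present on the short channel
#' too; and (iii) per-channel AR(1) low-frequency noise.  The short
#' channel carries no evoked component and no local coloured noise: it
#' sees superficial systemic physiology only.
#'
#' @param spec A [paradigm_spec()].
#' @param montage A `nirs_montage`.
#' @param truth A [ground_truth()].
#' @return An object of class `nirs_conc`: matrices `hbo`, `hbr`
#'   (channels x samples, uM), the ground-truth components `evoked_hbo`,
#'   `evoked_hbr` and `mayer`, the event table, sampling rate and
#'   montage.
#' @export
simulate_concentrations <- function(spec, montage, truth) {
  stopifnot(inherits(spec, "nirs_paradigm"), inherits(montage, "nirs_montage"),
            inherits(truth, "nirs_truth"))
  fs <- spec$sampling_rate
  n <- floor(run_duration(spec) * fs)
  tt <- (seq_len(n) - 1) / fs
  n_ch <- nrow(montage$channel_pairs)
  long <- long_channels(montage)
  short <- montage$short_channel_index
  events <- generate_events(spec)

  amp <- if (spec$state == "UNRESPONSIVE") 0 else truth$evoked_amplitude_hbo

  withr::with_seed(truth$seed, {
    # --- evoked component -------------------------------------------------
    stim <- numeric(n)
    imag <- events[events$trial_type == "IMAGERY", ]
    if (nrow(imag) > 0 && amp > 0) {
      jit <- pmax(0, 1 + rnorm(nrow(imag), 0, truth$trial_amplitude_sd))
      for (i in seq_len(nrow(imag))) {
        i0 <- round((imag$onset[i] + spec$cue_s) * fs) + 1L
        i1 <- min(n, i0 + floor(spec$task_s * fs))
        if (i0 <= n) stim[i0:i1] <- stim[i0:i1] + jit[i]
      }
    }
    th <- seq(0, 32, by = 1 / fs)
    hrf <- hrf_double_gamma(th, truth$hrf_peak_s, truth$hrf_undershoot_s,
                            truth$hrf_undershoot_ratio)
    evoked_t <- convolve(stim, rev(hrf), type = "open")[seq_len(n)] /
      (fs * spec$task_s)   # unit-peak scaling for a task_s boxcar
    lag <- round(truth$hbr_lag_s * fs)
    evoked_hbr_t <- c(numeric(lag), evoked_t)[seq_len(n)]

    profile <- truth$spatial_profile %||% {
      i <- seq_along(long)
      exp(-0.5 * ((i - (length(long) + 1) / 2) / (length(long) / 4))^2)
    }
    if (length(profile) != length(long))
      stopf("spatial_profile must have one loading per long channel")

    evoked_hbo <- matrix(0, n_ch, n)
    evoked_hbr <- matrix(0, n_ch, n)
    evoked_hbo[long, ] <- amp * profile %o% evoked_t
    evoked_hbr[long, ] <- -truth$hbr_ratio * amp * profile %o% evoked_hbr_t

    # --- systemic physiology (shared time course, channel gains) ---------
    mayer <- truth$mayer_amp *
      sin(2 * pi * truth$mayer_freq * tt + runif(1, 0, 2 * pi))
    cardiac <- truth$cardiac_amp *
      sin(2 * pi * truth$cardiac_freq * tt + runif(1, 0, 2 * pi))
    drift <- truth$drift_slope * tt
    systemic <- mayer + cardiac + drift
    gains <- runif(n_ch, 0.7, 1.3)
    gains[short] <- 1

    hbo <- evoked_hbo + gains %o% systemic
    hbr <- evoked_hbr + (-0.3 * gains) %o% systemic
    for (ch in long) {
      hbo[ch, ] <- hbo[ch, ] + ar1_noise(n, truth$colored_noise_sd, truth$ar_coef)
      hbr[ch, ] <- hbr[ch, ] + ar1_noise(n, 0.5 * truth$colored_noise_sd,
                                         truth$ar_coef)
    }
  })

  structure(
    list(hbo = hbo, hbr = hbr,
         evoked_hbo = evoked_hbo, evoked_hbr = evoked_hbr,
         mayer = mayer, events = events,
         sampling_rate = fs, montage = montage, state = spec$state),
    class = "nirs_conc")
}

#' Project concentrations to raw two-wavelength intensities
#'
#' Applies the Beer-Lambert forward model: optical-density change
#' `dOD(lambda, t) = (eHbO(lambda) dHbO + eHbR(lambda) dHbR) * d * ppf`,
#' then `I = I0 * exp(-dOD)` with multiplicative white measurement
#' noise.
#'
#' @param conc A `nirs_conc` from [simulate_concentrations()].
#' @param truth The [ground_truth()] used (supplies the noise level and
#'   seed).
#' @param ppf Partial path length factor.
#' @param i0 Baseline intensity, arbitrary units.
#' @return A `nirs_recording` (see [read_fnirs()] for the structure).
#' @export
forward_to_intensity <- function(conc, truth, ppf = 6, i0 = 1) {
  stopifnot(inherits(conc, "nirs_conc"), inherits(truth, "nirs_truth"))
  montage <- conc$montage
  E <- extinction_coefficients(montage$wavelengths)
  n_ch <- nrow(montage$channel_pairs)
  n <- ncol(conc$hbo)
  intens <- array(NA_real_, c(n_ch, 2, n))
  withr::with_seed(derive_seed(truth$seed, 1L), {
    for (w in 1:2) {
      od <- (E[w, "hbo"] * conc$hbo + E[w, "hbr"] * conc$hbr) *
        (montage$distances * ppf)
      noise <- if (truth$white_noise_sd > 0)
        matrix(rnorm(n_ch * n, 0, truth$white_noise_sd), n_ch, n)
      else 0
      intens[, w, ] <- i0 * exp(-od) * (1 + noise)
    }
  })
  if (any(intens <= 0))
    stopf("simulated intensities not positive; reduce white_noise_sd")
  new_recording(intens, conc$sampling_rate, montage, conc$events,
                annotations = list(state = conc$state,
                                   seed = truth$seed, ppf = ppf))
}

#' Simulate one complete run as a raw recording
#'
#' Convenience wrapper chaining [paradigm_spec()],
#' [simulate_concentrations()] and [forward_to_intensity()].
#'
#' @param state `"RESPONSIVE"` or `"UNRESPONSIVE"`.
#' @param seed Integer seed.
#' @param spec,montage,truth Optional overrides; defaults are built from
#'   the other arguments.
#' @param first_block_condition Condition of the first block.
#' @param ... Passed to [ground_truth()] when `truth` is `NULL`.
#' @return A `nirs_recording`.
#' @export
simulate_run <- function(state = c("RESPONSIVE", "UNRESPONSIVE"),
                         seed = 1L, spec = NULL, montage = NULL,
                         truth = NULL,
                         first_block_condition = c("IMAGERY", "NO_IMAGERY"),
                         ...) {
  state <- match.arg(state)
  first_block_condition <- match.arg(first_block_condition)
  spec <- spec %||% paradigm_spec(state = state,
                                  first_block_condition = first_block_condition)
  montage <- montage %||% default_montage()
  truth <- truth %||% ground_truth(seed = seed, state = state, ...)
  conc <- simulate_concentrations(spec, montage, truth)
  forward_to_intensity(conc, truth)
}

#' Simulate a multi-run dataset for one participant state
#'
#' Runs alternate their first-block condition so that cue-condition
#' allocation is balanced across the dataset, mirroring the paradigm's
#' counterbalancing.
#'
#' @param state `"RESPONSIVE"` or `"UNRESPONSIVE"`.
#' @param n_runs Number of runs (default 2 per state).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param ... Passed to [ground_truth()].
#' @return A list of `nirs_recording` objects.
#' @export
simulate_dataset <- function(state = c("RESPONSIVE", "UNRESPONSIVE"),
                             n_runs = 2, seed = 1L, ...) {
  state <- match.arg(state)
  firsts <- rep(c("IMAGERY", "NO_IMAGERY"), length.out = n_runs)
  lapply(seq_len(n_runs), function(r) {
    simulate_run(state, seed = derive_seed(seed, 100L + r),
                 first_block_condition = firsts[r], ...)
  })
}
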