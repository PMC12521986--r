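#' Define the timing and structure of an imagery run
#'
#' A run consists of a baseline period followed by alternating blocks of
#' IMAGERY and NO-IMAGERY trials.  Each trial is an auditory cue, a short
#' task period during which a responsive participant performs combined
#' motor-speech imagery, and a resting period.  With the defaults a run
#' holds 6 blocks of 5 trials (15 trials per condition) and lasts exactly
#' 580 s (09:40 min).
#'
#' @param sampling_rate Sampling rate of the optical recording in Hz.
#' @param baseline_s Initial rest before the first block, seconds.
#' @param n_blocks Number of trial blocks; conditions alternate by block.
#' @param trials_per_block Trials in each block.
#' @param cue_s,task_s,rest_s Durations of the auditory cue, the imagery
#'   task window and the inter-trial rest, seconds.
#' @param state `"RESPONSIVE"` (the participant follows the imagery
#'   instruction) or `"UNRESPONSIVE"` (never performs the task).
#' @param first_block_condition Condition of the first block.
#' @return An object of class `nirs_paradigm`.
#' @export
#' @examples
#' spec <- paradigm_spec()
#' run_duration(spec)  # 580 s
paradigm_spec <- function(sampling_rate = 6.94,
                          baseline_s = 40,
                          n_blocks = 6,
                          trials_per_block = 5,
                          cue_s = 1,
                          task_s = 2,
                          rest_s = 15,
                          state = c("RESPONSIVE", "UNRESPONSIVE"),
                          first_block_condition = c("IMAGERY", "NO_IMAGERY")) {
  state <- match.arg(state)
  first_block_condition <- match.arg(first_block_condition)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(baseline_s, "baseline_s")
  for (nm in c("n_blocks", "trials_per_block"))
    if (get(nm) < 1 || get(nm) != round(get(nm)))
      stopf("'%s' must be a positive integer", nm)
  for (nm in c("cue_s", "task_s", "rest_s"))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  if (baseline_s < 0) stopf("'baseline_s' must be non-negative")
  spec <- structure(
    list(sampling_rate = sampling_rate, baseline_s = baseline_s,
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         cue_s = cue_s, task_s = task_s, rest_s = rest_s,
         state = state, first_block_condition = first_block_condition),
    class = "nirs_paradigm")
  spec
}

#' Total duration of a run in seconds
#' @param spec A [paradigm_spec()] object.
#' @return Scalar duration in seconds.
#' @export
run_duration <- function(spec) {
  trial <- spec$cue_s + spec$task_s + spec$rest_s
  spec$baseline_s + spec$n_blocks * spec$trials_per_block * trial
}

#' @export
print.nirs_paradigm <- function(x, ...) {
  cat(sprintf("<nirs_paradigm> %s, %d blocks x %d trials, %.0f s (%s first)\n",
              x$state, x$n_blocks, x$trials_per_block, run_duration(x),
              x$first_block_condition))
  invisible(x)
}

#' Optode montage for a recording
#'
#' Describes the source-detector channel layout: a set of long
#' (cortex-sensitive) channels and exactly one short channel whose 1-cm
#' separation makes it sensitive only to superficial, systemic
#' physiology (notably Mayer waves), used later as a nuisance regressor.
#'
#' @param channel_pairs Two-column matrix or data frame of (source,
#'   detector) indices, one row per channel.
#' @param distances Source-detector separation per channel, cm.
#' @param short_channel_index Row index of the single short channel, or
#'   `NULL` for a montage whose short channel has been regressed out.
#' @param wavelengths Two distinct laser wavelengths, nm.
#' @param source_labels,detector_labels Optional optode labels.
#' @return An object of class `nirs_montage`.
#' @export
make_montage <- function(channel_pairs, distances, short_channel_index,
                         wavelengths = c(760, 850),
                         source_labels = NULL, detector_labels = NULL) {
  channel_pairs <- as.matrix(channel_pairs)
  if (ncol(channel_pairs) != 2L) stopf("'channel_pairs' needs 2 columns")
  n_ch <- nrow(channel_pairs)
  if (length(distances) != n_ch) stopf("one distance per channel required")
  if (any(distances <= 0)) stopf("all channel distances must be positive")
  if (!is.null(short_channel_index) &&
      (length(short_channel_index) != 1L ||
       short_channel_index < 1 || short_channel_index > n_ch))
    stopf("'short_channel_index' must identify exactly one channel")
  if (length(wavelengths) != 2L || wavelengths[1] == wavelengths[2])
    stopf("two distinct wavelengths required")
  structure(
    list(channel_pairs = channel_pairs,
         distances = as.numeric(distances),
         short_channel_index =
           if (is.null(short_channel_index)) NULL
           else as.integer(short_channel_index),
         wavelengths = as.numeric(wavelengths),
         source_labels = source_labels %||%
           paste0("S", sort(unique(channel_pairs[, 1]))),
         detector_labels = detector_labels %||%
           paste0("D", sort(unique(channel_pairs[, 2])))),
    class = "nirs_montage")
}

#' Default left-hemisphere fronto-parietal montage
#'
#' Nine sources and eight detectors over left motor and speech areas:
#' 18 long channels at 3 cm and one short channel (S9-D5) at 1 cm.
#'
#' @param wavelengths Two laser wavelengths, nm.
#' @return A `nirs_montage`.
#' @export
default_montage <- function(wavelengths = c(760, 850)) {
  pairs <- rbind(
    c(1, 1), c(1, 3),
    c(2, 2), c(2, 3), c(2, 6),
    c(3, 2), c(3, 4),
    c(4, 4), c(4, 8),
    c(5, 3), c(5, 6),
    c(6, 5), c(6, 6), c(6, 7),
    c(7, 4), c(7, 7),
    c(8, 7), c(8, 8),
    c(9, 5))                      # short channel
  d <- c(rep(3, 18), 1)
  make_montage(pairs, d, short_channel_index = 19L,
               wavelengths = wavelengths)
}

#' Indices of the long (3-cm) channels of a montage
#' @param montage A `nirs_montage`.
#' @return Integer vector.
#' @export
long_channels <- function(montage) {
  idx <- seq_len(nrow(montage$channel_pairs))
  if (is.null(montage$short_channel_index)) idx
  else setdiff(idx, montage$short_channel_index)
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat(sprintf("<nirs_montage> %d channels (%d long, %s short), %g/%g nm\n",
              nrow(x$channel_pairs), length(long_channels(x)),
              if (is.null(x$short_channel_index)) "no" else "1",
              x$wavelengths[1], x$wavelengths[2]))
  invisible(x)
}

#' Ground truth of a simulated run
#'
#' Collects the physiological parameters of the forward simulator: the
#' evoked hemodynamic response amplitude, the HbR/HbO coupling, the
#' double-gamma HRF shape, and the systemic noise components (Mayer
#' waves near 0.1 Hz, cardiac pulsation near 1 Hz, slow drift,
#' measurement noise).  In the UNRESPONSIVE state the evoked amplitude
#' is forced to zero: an unresponsive participant never performs the
#' imagery task, so no task-locked response exists.
#'
#' @param evoked_amplitude_hbo Peak task-evoked change in HbO at the most
#'   responsive channel, micromolar.  The default is calibrated so that a
#'   two-run RESPONSIVE dataset decodes at roughly 80 percent
#'   cross-validated accuracy under the default noise model.
#' @param hbr_ratio Peak HbR change as a (positive) fraction of the HbO
#'   peak; HbR deflects downward.
#' @param hbr_lag_s Lag of the HbR response behind HbO, seconds.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio Double-gamma
#'   HRF shape: time to peak, time to undershoot, undershoot depth.
#' @param trial_amplitude_sd Trial-to-trial multiplicative jitter (sd of
#'   a Gaussian factor about 1) of the evoked amplitude.
#' @param mayer_amp,mayer_freq Amplitude (uM) and frequency (Hz) of the
#'   systemic Mayer-wave oscillation.
#' @param cardiac_amp,cardiac_freq Amplitude (uM) and frequency (Hz) of
#'   the cardiac pulsation.
#' @param drift_slope Linear drift, uM per second.
#' @param colored_noise_sd Stationary sd (uM) of per-channel AR(1)
#'   low-frequency noise (local vasomotion, not removable by the short
#'   channel).
#' @param ar_coef AR(1) coefficient of the coloured noise at the
#'   recording sampling rate.
#' @param white_noise_sd Fractional sd of multiplicative white noise
#'   applied to the raw intensities.
#' @param spatial_profile Optional vector of per-long-channel loadings in
#'   `[0, 1]` for the evoked response; default is a smooth unimodal bump.
#' @param seed Integer seed for all noise realisations.
#' @param state Optional state; `"UNRESPONSIVE"` forces
#'   `evoked_amplitude_hbo = 0`.
#' @return An object of class `nirs_truth`.
#' @export
ground_truth <- function(evoked_amplitude_hbo = 0.5,
                         hbr_ratio = 1 / 3,
                         hbr_lag_s = 1,
                         hrf_peak_s = 6,
                         hrf_undershoot_s = 16,
                         hrf_undershoot_ratio = 1 / 6,
                         trial_amplitude_sd = 0.25,
                         mayer_amp = 0.5,
                         mayer_freq = 0.095,
                         cardiac_amp = 0.2,
                         cardiac_freq = 1.1,
                         drift_slope = 0.001,
                         colored_noise_sd = 0.35,
                         ar_coef = 0.97,
                         white_noise_sd = 5e-4,
                         spatial_profile = NULL,
                         seed = 1L,
                         state = NULL) {
  amps <- c(trial_amplitude_sd = trial_amplitude_sd, mayer_amp = mayer_amp,
            cardiac_amp = cardiac_amp, colored_noise_sd = colored_noise_sd,
            white_noise_sd = white_noise_sd)
  if (any(amps < 0)) stopf("noise amplitudes must be non-negative")
  if (!is.null(state) && state == "UNRESPONSIVE") evoked_amplitude_hbo <- 0
  structure(
    list(evoked_amplitude_hbo = evoked_amplitude_hbo,
         hbr_ratio = hbr_ratio, hbr_lag_s = hbr_lag_s,
         hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
         hrf_undershoot_ratio = hrf_undershoot_ratio,
         trial_amplitude_sd = trial_amplitude_sd,
         mayer_amp = mayer_amp, mayer_freq = mayer_freq,
         cardiac_amp = cardiac_amp, cardiac_freq = cardiac_freq,
         drift_slope = drift_slope,
         colored_noise_sd = colored_noise_sd, ar_coef = ar_coef,
         white_noise_sd = white_noise_sd,
         spatial_profile = spatial_profile,
         seed = as.integer(seed)),
    class = "nirs_truth")
}

#' Event table of a run
#'
#' One event per trial at cue onset, alternating condition by block.
#'
#' @param spec A [paradigm_spec()].
#' @param seed Unused for timing (the schedule is deterministic); kept so
#'   callers can thread a seed through uniformly.
#' @return A tibble with columns `onset` (s), `duration` (s) and
#'   `trial_type` (`"IMAGERY"`/`"NO_IMAGERY"`).
#' @export
#' @examples
#' ev <- generate_events(paradigm_spec())
#' nrow(ev)            # 30
#' table(ev$trial_type)  # 15 / 15
generate_events <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "nirs_paradigm"))
  trial_len <- spec$cue_s + spec$task_s + spec$rest_s
  other <- if (spec$first_block_condition == "IMAGERY") "NO_IMAGERY" else "IMAGERY"
  block_cond <- rep(c(spec$first_block_condition, other),
                    length.out = spec$n_blocks)
  onsets <- numeric(0)
  types <- character(0)
  t0 <- spec$baseline_s
  for (b in seq_len(spec$n_blocks)) {
    k <- seq_len(spec$trials_per_block) - 1
    onsets <- c(onsets, t0 + k * trial_len)
    types <- c(types, rep(block_cond[b], spec$trials_per_block))
    t0 <- t0 + spec$trials_per_block * trial_len
  }
  tibble::tibble(onset = onsets,
                 duration = rep(spec$cue_s + spec$task_s, length(onsets)),
                 trial_type = types)
}
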