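#' Convert raw intensities to optical densities
#'
#' `od(t) = -ln(I(t) / mean(I))` per channel and wavelength, so a
#' constant channel maps to zero and rescaling the source intensity
#' leaves the result unchanged.
#'
#' @param rec A `nirs_recording`.
#' @return An object of class `nirs_od` (array `od` channels x 2 x
#'   samples, plus sampling rate, montage and events).
#' @export
to_optical_density <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (any(rec$intensities <= 0)) stopf("non-positive intensities")
  d <- dim(rec$intensities)
  od <- rec$intensities
  for (ch in seq_len(d[1]))
    for (w in 1:2) {
      x <- rec$intensities[ch, w, ]
      od[ch, w, ] <- -log(x / mean(x))
    }
  structure(list(od = od, sampling_rate = rec$sampling_rate,
                 montage = rec$montage, events = rec$events),
            class = "nirs_od")
}

# Temporal derivative distribution repair for one trace: iteratively
# reweighted (Tukey biweight) robust estimate of the low-frequency
# derivative; spikes and step discontinuities receive weight ~0 and are
# removed on re-integration.  High-frequency content is left untouched.
tddr_trace <- function(x, fs, tol = 1e-8, max_iter = 50) {
  mu_x <- mean(x)
  x <- x - mu_x
  if (fs > 1) {
    bf <- signal::butter(3, 0.5 / (fs / 2), type = "low")
    x_low <- filtfilt_zi(bf, x)
  } else x_low <- x
  x_high <- x - x_low
  deriv <- diff(x_low)
  w <- rep(1, length(deriv))
  mu <- Inf
  tune <- 4.685
  for (it in seq_len(max_iter)) {
    mu0 <- mu
    mu <- sum(w * deriv) / sum(w)
    dev <- abs(deriv - mu)
    sigma <- 1.4826 * median(dev)
    if (sigma == 0) break
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) < tol * max(abs(mu), abs(mu0), 1))
      break
  }
  corrected_low <- cumsum(c(0, w * (deriv - mu)))
  corrected_low + x_high + mu_x
}

#' Temporal derivative distribution repair (TDDR)
#'
#' Robust motion-artifact correction applied independently to every
#' channel/wavelength optical-density trace: the temporal derivative of
#' the low-frequency component is reweighted with a Tukey biweight so
#' that spikes and baseline steps contribute (near-)zero weight, then
#' re-integrated.
#'
#' @param od A `nirs_od`.
#' @param tol Convergence tolerance of the robust location iteration.
#' @param max_iter Iteration cap.
#' @return A `nirs_od` of identical shape.
#' @export
tddr <- function(od, tol = 1e-8, max_iter = 50) {
  stopifnot(inherits(od, "nirs_od"))
  d <- dim(od$od)
  if (d[3] < 3) stopf("TDDR needs at least 3 samples")
  out <- od
  for (ch in seq_len(d[1]))
    for (w in 1:2)
      out$od[ch, w, ] <- tddr_trace(od$od[ch, w, ], od$sampling_rate,
                                    tol, max_iter)
  out
}

#' Regress superficial physiology out of the long channels
#'
#' For each long channel and wavelength, the least-squares projection
#' (with intercept) onto the same-wavelength short-channel trace is
#' subtracted.  The short channel samples only scalp haemodynamics, so
#' this removes Mayer waves and other systemic noise while leaving
#' cortical signal untouched.  The short channel is dropped from the
#' output.
#'
#' @param od A `nirs_od` whose montage contains a short channel.
#' @return A `nirs_od` restricted to the long channels.
#' @export
regress_short_channel <- function(od) {
  stopifnot(inherits(od, "nirs_od"))
  montage <- od$montage
  if (is.null(montage$short_channel_index))
    stopf("montage has no short channel; disable short-channel regression")
  long <- long_channels(montage)
  short <- montage$short_channel_index
  d <- dim(od$od)
  out <- array(NA_real_, c(length(long), 2, d[3]))
  for (w in 1:2) {
    s <- od$od[short, w, ]
    sc <- s - mean(s)
    den <- sum(sc^2)
    for (k in seq_along(long)) {
      y <- od$od[long[k], w, ]
      beta <- if (den > 0) sum((y - mean(y)) * sc) / den else 0
      out[k, w, ] <- y - mean(y) - beta * sc
    }
  }
  long_montage <- make_montage(montage$channel_pairs[long, , drop = FALSE],
                               montage$distances[long],
                               short_channel_index = NULL,
                               wavelengths = montage$wavelengths)
  structure(list(od = out, sampling_rate = od$sampling_rate,
                 montage = long_montage, events = od$events),
            class = "nirs_od")
}

#' Modified Beer-Lambert law
#'
#' Solves, per channel and sample, the 2 x 2 linear system
#' `dOD(lambda) = eps(lambda, chromophore) * dC * d * ppf` for the
#' haemoglobin concentration changes `(dHbO, dHbR)`.
#'
#' @param od A `nirs_od` (long channels; run [regress_short_channel()]
#'   first, or pass an OD series without a short channel).
#' @param ppf Partial path length factor (dimensionless).
#' @return An object of class `nirs_hb` with matrices `hbo` and `hbr`
#'   (channels x samples, uM).
#' @export
mbll <- function(od, ppf = 6) {
  stopifnot(inherits(od, "nirs_od"))
  E <- extinction_coefficients(od$montage$wavelengths)
  if (abs(det(E)) < 1e-12) stopf("singular extinction matrix")
  Einv <- solve(E)
  d <- dim(od$od)
  hbo <- matrix(NA_real_, d[1], d[3])
  hbr <- matrix(NA_real_, d[1], d[3])
  for (ch in seq_len(d[1])) {
    pl <- od$montage$distances[ch] * ppf
    conc <- Einv %*% (od$od[ch, , ] / pl)
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, sampling_rate = od$sampling_rate,
                 montage = od$montage, events = od$events),
            class = "nirs_hb")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase; the effective order therefore doubles) to every channel
#' of both chromophores.
#'
#' @param hb A `nirs_hb`.
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < Nyquist`.
#' @return A filtered `nirs_hb`.
#' @export
bandpass <- function(hb, low_hz = 0.01, high_hz = 0.4) {
  stopifnot(inherits(hb, "nirs_hb"))
  nyq <- hb$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("invalid band [%g, %g] Hz for Nyquist %g Hz", low_hz, high_hz, nyq)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- hb
  for (ch in seq_len(nrow(hb$hbo))) {
    out$hbo[ch, ] <- filtfilt_zi(bf, hb$hbo[ch, ])
    out$hbr[ch, ] <- filtfilt_zi(bf, hb$hbr[ch, ])
  }
  out
}

# Steady-state initial filter state for a step input of unit height
# (solves the direct-form-II-transposed state equations at equilibrium),
# so filtering a signal starting at level x[1] produces no start-up
# transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

# Zero-phase filtering: odd-reflection padding plus steady-state
# initial conditions, applied forward and backward.
filtfilt_zi <- function(bf, x) {
  b <- bf$b; a <- bf$a
  nfilt <- max(length(a), length(b))
  padlen <- min(3L * (nfilt - 1L), length(x) - 1L)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

# Remove the least-squares line from each row of a matrix.
detrend_rows <- function(m) {
  ns <- ncol(m)
  x <- seq_len(ns) - (ns + 1) / 2          # centred regressor
  sxx <- sum(x^2)
  slope <- (m %*% x) / sxx
  mean_ <- rowMeans(m)
  m - outer(as.numeric(mean_), rep(1, ns)) - outer(as.numeric(slope), x)
}

#' Segment a haemoglobin series into labelled trial epochs
#'
#' Cuts a window from cue onset to `tmax_s` seconds post-onset for every
#' event and removes the per-channel least-squares linear trend from
#' each epoch.  For `chromophore = "BOTH"` the HbO and HbR channel
#' blocks are stacked, doubling the channel count.
#'
#' @param hb A `nirs_hb`.
#' @param events Event tibble; defaults to the one carried by `hb`.
#' @param chromophore `"HBO"`, `"HBR"` or `"BOTH"`.
#' @param tmax_s Epoch end, seconds post cue onset.
#' @return An object of class `nirs_epochs`: array `data` (trials x
#'   channels x samples), factor `labels`, `chromophore`,
#'   `sampling_rate`, `window`.
#' @export
make_epochs <- function(hb, events = NULL,
                        chromophore = c("HBO", "HBR", "BOTH"),
                        tmax_s = 12) {
  stopifnot(inherits(hb, "nirs_hb"))
  chromophore <- match.arg(chromophore)
  events <- events %||% hb$events
  if (is.null(events) || nrow(events) == 0) stopf("no events to epoch")
  fs <- hb$sampling_rate
  n <- ncol(hb$hbo)
  len <- floor(tmax_s * fs) + 1L
  starts <- round(events$onset * fs) + 1L
  ok <- starts >= 1L & (starts + len - 1L) <= n
  if (any(!ok))
    warnf("dropping %d epoch(s) extending past the recording", sum(!ok))
  if (!any(ok)) stopf("no complete epochs in recording")
  starts <- starts[ok]
  labels <- events$trial_type[ok]
  sig <- switch(chromophore,
                HBO = list(hb$hbo),
                HBR = list(hb$hbr),
                BOTH = list(hb$hbo, hb$hbr))
  n_ch <- nrow(hb$hbo) * length(sig)
  data <- array(NA_real_, c(length(starts), n_ch, len))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + len - 1L)
    blocks <- lapply(sig, function(m) m[, idx, drop = FALSE])
    data[i, , ] <- detrend_rows(do.call(rbind, blocks))
  }
  structure(list(data = data,
                 labels = factor(labels, levels = c("IMAGERY", "NO_IMAGERY")),
                 chromophore = chromophore, sampling_rate = fs,
                 window = c(0, tmax_s)),
            class = "nirs_epochs")
}

#' @export
print.nirs_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nirs_epochs> %s: %d trials x %d ch x %d samples (%s)\n",
              x$chromophore, d[1], d[2], d[3],
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Concatenate epoch sets from several runs
#'
#' @param epoch_list List of compatible `nirs_epochs`.
#' @return A single pooled `nirs_epochs`.
#' @export
pool_epochs <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1)
  e1 <- epoch_list[[1]]
  for (e in epoch_list[-1])
    if (!identical(dim(e$data)[2:3], dim(e1$data)[2:3]) ||
        e$chromophore != e1$chromophore)
      stopf("epoch sets are not compatible")
  data <- do.call(abind3, lapply(epoch_list, `[[`, "data"))
  labels <- factor(unlist(lapply(epoch_list, function(e) as.character(e$labels))),
                   levels = levels(e1$labels))
  structure(list(data = data, labels = labels, chromophore = e1$chromophore,
                 sampling_rate = e1$sampling_rate, window = e1$window),
            class = "nirs_epochs")
}

# rbind 3-d arrays along the first (trial) axis
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Optical density, TDDR, optional short-channel regression, modified
#' Beer-Lambert conversion and zero-phase band-pass, in that order.
#'
#' @param rec A `nirs_recording`.
#' @param config List of options: `ppf` (default 6), `band.low_hz`
#'   (0.01), `band.high_hz` (0.4), `short_channel.enabled` (TRUE),
#'   `tddr.enabled` (TRUE).
#' @return A `nirs_hb` restricted to long channels.
#' @export
preprocess_run <- function(rec, config = list()) {
  cfg <- modifyList(list(ppf = 6, band.low_hz = 0.01, band.high_hz = 0.4,
                         short_channel.enabled = TRUE, tddr.enabled = TRUE),
                    config)
  od <- to_optical_density(rec)
  if (isTRUE(cfg$tddr.enabled)) od <- tddr(od)
  if (isTRUE(cfg$short_channel.enabled)) {
    od <- regress_short_channel(od)
  } else {
    long <- long_channels(od$montage)
    od$od <- od$od[long, , , drop = FALSE]
    od$montage <- make_montage(od$montage$channel_pairs[long, , drop = FALSE],
                               od$montage$distances[long], NULL,
                               od$montage$wavelengths)
  }
  hb <- mbll(od, ppf = cfg$ppf)
  bandpass(hb, cfg$band.low_hz, cfg$band.high_hz)
}
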