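#' Construct a raw recording
#'
#' The in-memory representation of a continuous-wave fNIRS recording:
#' strictly positive raw intensities per channel and wavelength, the
#' montage, the sampling rate and the trial event table.
#'
#' @param intensities Numeric array, channels x wavelengths(2) x samples.
#' @param sampling_rate Hz.
#' @param montage A `nirs_montage`.
#' @param events Event tibble (`onset`, `duration`, `trial_type`); may be
#'   `NULL` for event-free recordings (most operations then refuse to
#'   run).
#' @param annotations Free-form metadata list.
#' @return An object of class `nirs_recording`.
#' @export
new_recording <- function(intensities, sampling_rate, montage, events,
                          annotations = list()) {
  if (length(dim(intensities)) != 3L || dim(intensities)[2] != 2L)
    stopf("'intensities' must be a channels x 2 x samples array")
  if (dim(intensities)[1] < 1L) stopf("recording has no channels")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stopf("intensities must be finite and strictly positive")
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot(inherits(montage, "nirs_montage"))
  if (dim(intensities)[1] != nrow(montage$channel_pairs))
    stopf("channel count mismatch between intensities and montage")
  dur <- dim(intensities)[3] / sampling_rate
  if (!is.null(events) && nrow(events) > 0 && any(events$onset >= dur))
    stopf("event onset beyond recording duration")
  structure(list(intensities = intensities, sampling_rate = sampling_rate,
                 montage = montage, events = events,
                 annotations = annotations),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<nirs_recording> %d ch x 2 wl x %d samples @ %.2f Hz, %s events\n",
              d[1], d[3], x$sampling_rate,
              if (is.null(x$events)) "no" else nrow(x$events)))
  invisible(x)
}

#' Write a recording to disk
#'
#' Serialises a recording as a portable plain-text bundle: a JSON header
#' (`<stem>.json`) with sampling rate, montage and annotations, a
#' tab-separated intensity matrix (`<stem>_intensity.tsv`, one column
#' per channel/wavelength, full double precision) and an events file
#' (`<stem>_events.tsv` with columns `onset`, `duration`, `trial_type`).
#' The round trip through [read_fnirs()] is lossless.
#'
#' @param rec A `nirs_recording`.
#' @param stem Path stem (without extension) to write to.
#' @return `stem`, invisibly.
#' @export
write_fnirs <- function(rec, stem) {
  stopifnot(inherits(rec, "nirs_recording"))
  d <- dim(rec$intensities)
  header <- list(
    format = "nirsaware-raw", version = 1L,
    sampling_rate = rec$sampling_rate,
    n_channels = d[1], n_samples = d[3],
    wavelengths = rec$montage$wavelengths,
    channel_pairs = rec$montage$channel_pairs,
    distances = rec$montage$distances,
    short_channel_index = rec$montage$short_channel_index,
    source_labels = rec$montage$source_labels,
    detector_labels = rec$montage$detector_labels,
    annotations = rec$annotations)
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # columns ordered channel-major then wavelength: ch1_wl1 ch1_wl2 ch2_wl1 ...
  m <- matrix(aperm(rec$intensities, c(3, 2, 1)), nrow = d[3])
  cols <- as.vector(t(outer(seq_len(d[1]), 1:2,
                            function(ch, w) sprintf("ch%02d_wl%d", ch, w))))
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(cols, collapse = "\t"), txt),
             paste0(stem, "_intensity.tsv"))
  if (!is.null(rec$events)) write_events(rec$events, paste0(stem, "_events.tsv"))
  invisible(stem)
}

#' Read a recording written by [write_fnirs()]
#'
#' @param stem Path stem used at write time.
#' @param require_events Error if no events file is present (default):
#'   downstream decoding is meaningless without trial labels.
#' @return A `nirs_recording`.
#' @export
read_fnirs <- function(stem, require_events = TRUE) {
  hpath <- paste0(stem, ".json")
  if (!file.exists(hpath)) stopf("no header file at '%s'", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, "nirsaware-raw"))
    stopf("'%s' is not a nirsaware raw bundle", hpath)
  m <- as.matrix(read.delim(paste0(stem, "_intensity.tsv"),
                            check.names = FALSE))
  intens <- aperm(array(m, c(h$n_samples, 2, h$n_channels)), c(3, 2, 1))
  montage <- make_montage(h$channel_pairs, h$distances,
                          h$short_channel_index, h$wavelengths,
                          h$source_labels, h$detector_labels)
  epath <- paste0(stem, "_events.tsv")
  events <- if (file.exists(epath)) read_events(epath) else NULL
  if (is.null(events) && require_events)
    stopf("recording '%s' has no events file", stem)
  ann <- h$annotations
  if (length(ann) == 0) ann <- list()
  new_recording(intens, h$sampling_rate, montage, events, ann)
}

#' Read / write an event table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param path File path.
#' @return [read_events()] returns a tibble.
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stopf("events file '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  tibble::as_tibble(ev[need])
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
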