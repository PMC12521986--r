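#' Serialise an epoch set
#'
#' Writes a JSON header (shape, labels, chromophore, window, sampling
#' rate, provenance) next to a flat binary container of little-endian
#' doubles holding the trials x channels x samples array.
#'
#' @param epochs A `nirs_epochs`.
#' @param stem Path stem; writes `<stem>.json` and `<stem>.dat`.
#' @param provenance Optional list stored in the header.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem, provenance = list()) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  header <- list(format = "nirsaware-epochs", version = 1L,
                 dim = dim(epochs$data),
                 labels = as.character(epochs$labels),
                 chromophore = epochs$chromophore,
                 sampling_rate = epochs$sampling_rate,
                 window = epochs$window,
                 provenance = provenance)
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  h <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(h$format, "nirsaware-epochs"))
    stopf("'%s' is not a serialised epoch set", stem)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  n <- prod(h$dim)
  data <- array(readBin(con, "double", n, size = 8, endian = "little"),
                dim = h$dim)
  structure(list(data = data,
                 labels = factor(h$labels,
                                 levels = c("IMAGERY", "NO_IMAGERY")),
                 chromophore = h$chromophore,
                 sampling_rate = h$sampling_rate,
                 window = h$window),
            class = "nirs_epochs")
}
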