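#' Canonical EEG frequency bands
#'
#' The five bands used throughout the pipeline: delta 1--4 Hz, theta 4--8 Hz,
#' alpha 8--13 Hz, beta 13--30 Hz and gamma 30--48 Hz. Bands are treated as
#' half-open intervals `[low, high)` wherever spectra are summarised, so the
#' shared edges (4, 8, 13, 30 Hz) belong unambiguously to the lower band's
#' upper neighbour.
#'
#' @param names optional character vector selecting a subset, in the order
#'   given. Defaults to all five bands in canonical (delta ... gamma) order.
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' eeg_bands()
#' eeg_bands(c("alpha", "gamma"))
#' @export
eeg_bands <- function(names = NULL) {
  tab <- data.frame(
    name    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 48),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(tab)
  miss <- setdiff(names, tab$name)
  if (length(miss)) stopf("unknown band(s): %s", paste(miss, collapse = ", "))
  tab[match(names, tab$name), , drop = FALSE]
}

#' Construct and validate a single band definition
#'
#' @param name band label (any non-empty string; the five canonical names are
#'   conventional but not required for custom analyses).
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return A one-row data.frame compatible with [eeg_bands()].
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stopf("band name must be a non-empty string")
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      !(low_hz > 0) || !(low_hz < high_hz))
    stopf("band edges must satisfy 0 < low_hz < high_hz (got %s, %s)",
          format(low_hz), format(high_hz))
  data.frame(name = name, low_hz = as.numeric(low_hz),
             high_hz = as.numeric(high_hz), stringsAsFactors = FALSE)
}

band_order <- c("delta", "theta", "alpha", "beta", "gamma")
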