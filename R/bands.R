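#' Canonical EEG frequency bands
#'
#' The five canonical bands used throughout: delta (0-4 Hz), theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-40 Hz). Bands are treated
#' as half-open intervals [lo, hi) so that abutting edges never double-count
#' a frequency bin; together they partition 0-40 Hz.
#'
#' @param names optional character vector selecting a subset, in the given
#'   order.
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
#' canonical_bands(c("delta", "theta", "alpha"))
canonical_bands <- function(names = NULL) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0, 4, 8, 13, 30),
    hi   = c(4, 8, 13, 30, 40),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    bad <- setdiff(names, b$name)
    if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "))
    b <- b[match(names, b$name), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

#' Bands analysed for connectivity by default
#'
#' Connectivity analysis is restricted to delta, theta and alpha by default:
#' beta/gamma sensor-space estimates are vulnerable to broadband EMG
#' contamination in patient recordings.
#' @return data.frame as [canonical_bands()].
#' @export
analysis_bands <- function() canonical_bands(c("delta", "theta", "alpha"))

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) stop("each band must have lo < hi")
  invisible(bands)
}
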