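# Welch power spectra, band-relative power contributions and their temporal
# variability across epochs.

hamming_window <- function(n) signal::hamming(n)

# Welch PSD of one channels x samples matrix: mean modified periodogram over
# `seg` -sample segments with 50% overlap, Hamming taper, zero-padded to
# nfft points. One-sided density in uV^2/Hz.
welch_psd_matrix <- function(x, fs, seg, nfft) {
  n <- ncol(x); nch <- nrow(x)
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- hamming_window(seg)
  scale <- fs * sum(w^2)
  nf <- nfft %/% 2L + 1L
  acc <- matrix(0, nf, nch)
  for (s in starts) {
    segm <- w * t(x[, s:(s + seg - 1L), drop = FALSE])   # seg x nch
    if (nfft > seg) segm <- rbind(segm, matrix(0, nfft - seg, nch))
    X <- stats::mvfft(segm)[seq_len(nf), , drop = FALSE]
    acc <- acc + (Mod(X)^2) / scale
  }
  p <- acc / length(starts)
  p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]     # one-sided: double interior bins
  t(p)                                          # channels x freq
}

#' Welch power spectrum of an epoched recording
#'
#' Per channel, the modified periodogram is averaged over 4-second Hamming
#' segments with 50% overlap within every epoch and across epochs, zero-
#' padded so frequency bins have exactly the requested width.
#'
#' @param rec epoched [eeg_recording()].
#' @param bin_width frequency bin width in Hz (default 0.25). The epoch must
#'   be at least `1/bin_width` seconds long.
#' @param seg_seconds Welch segment length in seconds (default 4, capped at
#'   the epoch length).
#' @param epochs optional integer subset of epochs to use.
#' @return object of class `spectrum_welch`: `power` (channels x bins,
#'   uV^2/Hz), `freq` (Hz), `bin_width`, `labels`.
#' @export
welch_spectrum <- function(rec, bin_width = 0.25, seg_seconds = 4,
                           epochs = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), is_epoched(rec))
  fs <- rec$sampling_rate
  ep_len <- epoch_length(rec)
  if (ep_len < 1 / bin_width)
    stop(sprintf("bin width %g Hz needs epochs of >= %g s (have %g s)",
                 bin_width, 1 / bin_width, ep_len))
  seg <- round(min(seg_seconds, ep_len) * fs)
  nfft <- round(fs / bin_width)
  if (nfft < seg) nfft <- seg                  # never truncate a segment
  if (is.null(epochs)) epochs <- seq_len(dim(rec$data)[2])
  nf <- nfft %/% 2L + 1L
  acc <- matrix(0, dim(rec$data)[1], nf)
  for (e in epochs)
    acc <- acc + welch_psd_matrix(matrix(rec$data[, e, ], nrow = dim(rec$data)[1]),
                                  fs, seg, nfft)
  power <- acc / length(epochs)
  rownames(power) <- rec$labels
  structure(list(power = power, freq = (seq_len(nf) - 1) * fs / nfft,
                 bin_width = fs / nfft, labels = rec$labels),
            class = "spectrum_welch")
}

band_power_from_spectrum <- function(spec, bands) {
  validate_bands(bands)
  out <- vapply(seq_len(nrow(bands)), function(b) {
    idx <- spec$freq >= bands$lo[b] & spec$freq < bands$hi[b]
    rowSums(spec$power[, idx, drop = FALSE]) * spec$bin_width
  }, numeric(nrow(spec$power)))
  matrix(out, nrow = nrow(spec$power), ncol = nrow(bands),
         dimnames = list(rownames(spec$power), NULL))
}

#' Band-relative power contributions
#'
#' Converts a Welch spectrum into the percentage contribution of each
#' canonical band to the total power over all five bands (0-40 Hz), per
#' channel. Bands are half-open `[lo, hi)` so abutting edges are counted
#' once. Channel rows sum to 100.
#'
#' @param spec a [welch_spectrum()] result.
#' @param bands band definition table (default [canonical_bands()]).
#' @return object of class `band_power_table`: `contributions` (channels x
#'   bands matrix of percentages), `zero_power_channels` (labels whose total
#'   power was 0; their rows are NaN).
#' @export
band_contributions <- function(spec, bands = canonical_bands()) {
  bp <- band_power_from_spectrum(spec, bands)
  colnames(bp) <- bands$name
  tot <- rowSums(bp)
  contrib <- bp / tot * 100
  zero <- spec$labels[tot == 0]
  structure(list(contributions = contrib, zero_power_channels = zero,
                 bands = bands), class = "band_power_table")
}

#' @export
print.band_power_table <- function(x, ...) {
  cat("<band_power_table> channel-averaged contributions (%):\n")
  print(round(colMeans(x$contributions), 2))
  invisible(x)
}

#' Temporal variability of band power contributions
#'
#' Computes band contributions from each single epoch's Welch spectrum
#' (same settings as the grand spectrum), averages them over channels, and
#' returns the SD of these channel-averaged percentages across epochs, per
#' band. Low values indicate stationary band power over the recording.
#'
#' @param rec epoched [eeg_recording()].
#' @param bands band table (default [canonical_bands()]).
#' @param bin_width Welch bin width (Hz).
#' @return named numeric vector, SD of channel-averaged contribution
#'   percentage per band.
#' @export
band_variability <- function(rec, bands = canonical_bands(), bin_width = 0.25) {
  stopifnot(is_epoched(rec))
  nep <- dim(rec$data)[2]
  if (nep < 2) stop("band_variability needs >= 2 epochs")
  per_epoch <- vapply(seq_len(nep), function(e) {
    sp <- welch_spectrum(rec, bin_width = bin_width, epochs = e)
    colMeans(band_contributions(sp, bands)$contributions)
  }, numeric(nrow(bands)))
  out <- apply(per_epoch, 1, stats::sd)
  names(out) <- bands$name
  out
}
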