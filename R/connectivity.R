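# Debiased weighted phase lag index (dwPLI) connectivity from short-time
# Fourier cross-spectra.
#
# The estimator, per channel pair and time-frequency bin, with I_e the
# imaginary part of the cross-spectrum in epoch e:
#
#   dwPLI = ( (sum_e I_e)^2 - sum_e I_e^2 ) / ( (sum_e |I_e|)^2 - sum_e I_e^2 )
#
# It is insensitive to zero-lag (volume-conducted) coupling - a phase
# difference of exactly 0 or pi has no imaginary cross-spectral mass - and
# the subtraction of sum I_e^2 removes the positive small-sample bias of the
# squared weighted PLI. The measure is dimensionless: rescaling either
# channel rescales numerator and denominator alike.

#' Time-frequency decomposition configuration
#'
#' @param freq_bin target frequency bin width in Hz; the FFT length is the
#'   next power of two of `fs / freq_bin`, so the achieved width is at most
#'   the target (0.49 Hz at 250 Hz gives nfft 512, i.e. 0.488 Hz).
#' @param window STFT window length in seconds (Hanning taper).
#' @param hop hop between window starts in seconds.
#' @param max_freq highest frequency retained in the grid (Hz).
#' @return object of class `tf_config`.
#' @export
#' @examples
#' tf_config()          # full resolution: 0.49 Hz x 0.04 s bins
#' tf_config_coarse()   # desk-scale grid for simulation studies
tf_config <- function(freq_bin = 0.49, window = 2, hop = 0.04, max_freq = 45) {
  stopifnot(freq_bin > 0, window > 0, hop > 0, max_freq > 0)
  structure(list(freq_bin = freq_bin, window = window, hop = hop,
                 max_freq = max_freq), class = "tf_config")
}

#' @rdname tf_config
#' @export
tf_config_coarse <- function() tf_config(freq_bin = 0.98, window = 1, hop = 0.5)

#' Short-time Fourier decomposition of an epoched recording
#'
#' Hanning-tapered STFT per channel and epoch on the configured grid. The
#' complex coefficients define the cross-spectrum of every channel pair at
#' every (frequency, time) bin: `X_ab = A_a * Conj(A_b)`.
#'
#' @param rec preprocessed epoched [eeg_recording()] with >= 2 epochs.
#' @param config a [tf_config()].
#' @return object of class `tf_decomp`: `coef` (channels x freq x time x
#'   epochs complex array), `freq` (Hz), `times` (window-centre seconds),
#'   `labels`, `config`.
#' @export
tf_decompose <- function(rec, config = tf_config()) {
  stopifnot(inherits(rec, "eeg_recording"), is_epoched(rec),
            inherits(config, "tf_config"))
  if (dim(rec$data)[2] < 2) stop("need >= 2 epochs for cross-spectra")
  fs <- rec$sampling_rate
  win <- round(config$window * fs)
  hop <- round(config$hop * fs)
  nfft <- stats::nextn(ceiling(fs / config$freq_bin), 2)
  if (win > nfft)
    stop(sprintf(
      "window (%d samples) exceeds the FFT length (%d) implied by a %g Hz bin; achievable bin width >= %g Hz",
      win, nfft, config$freq_bin, fs / win))
  samp <- dim(rec$data)[3]
  if (win > samp) stop("window longer than an epoch")
  starts <- seq(1L, samp - win + 1L, by = hop)
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  keep_f <- which(freq <= config$max_freq)
  nch <- dim(rec$data)[1]; nep <- dim(rec$data)[2]
  taper <- signal::hanning(win)
  coef <- array(complex(real = 0), dim = c(nch, length(keep_f),
                                           length(starts), nep))
  pad <- matrix(0, nfft - win, nch)
  for (e in seq_len(nep)) {
    ep <- matrix(rec$data[, e, ], nrow = nch)
    for (s in seq_along(starts)) {
      segm <- taper * t(ep[, starts[s]:(starts[s] + win - 1L), drop = FALSE])
      X <- stats::mvfft(rbind(segm, pad))
      coef[, , s, e] <- t(X[keep_f, , drop = FALSE])
    }
  }
  structure(list(coef = coef, freq = freq[keep_f],
                 times = (starts - 1 + win / 2) / fs,
                 labels = rec$labels, config = config),
            class = "tf_decomp")
}

#' Cross-spectrum of one channel pair
#'
#' @param tf a [tf_decompose()] result.
#' @param a,b channel indices or labels.
#' @return complex freq x time x epochs array `A_a * Conj(A_b)`.
#' @export
cross_spectrum <- function(tf, a, b) {
  if (is.character(a)) a <- match(a, tf$labels)
  if (is.character(b)) b <- match(b, tf$labels)
  tf$coef[a, , , , drop = TRUE] * Conj(tf$coef[b, , , , drop = TRUE])
}

#' Debiased weighted phase lag index for one pair and bin
#'
#' @param x complex vector: the cross-spectrum of one channel pair at one
#'   (frequency, time) bin, one value per epoch (>= 2 epochs).
#' @return dwPLI value in [-1, 1]; defined as 0 when there is no imaginary
#'   cross-spectral mass (denominator 0).
#' @export
dwpli_estimate <- function(x) {
  if (length(x) < 2) stop("dwPLI is undefined for a single epoch")
  I <- Im(x)
  sI <- sum(I); sI2 <- sum(I^2); sA <- sum(abs(I))
  den <- sA^2 - sI2
  if (den <= 0) return(0)
  (sI^2 - sI2) / den
}

# dwPLI matrices for all channel pairs at one (f, t) bin, across epochs.
# A: channels x epochs complex STFT coefficients. Uses the identities
#   sum_e I_e        = M R' - R M'
#   sum_e I_e^2      = (M^2)(R^2)' - 2 (MR)(MR)' + (R^2)(M^2)'
# with R = Re(A), M = Im(A), since I_e(a,b) = M_a R_b - R_a M_b; the
# absolute-value sum needs one pass over epochs.
dwpli_matrix_slice <- function(A) {
  R <- Re(A); M <- Im(A)
  sI <- M %*% t(R) - R %*% t(M)
  R2 <- R * R; M2 <- M * M; MR <- M * R
  sI2 <- M2 %*% t(R2) - 2 * (MR %*% t(MR)) + R2 %*% t(M2)
  sAbs <- matrix(0, nrow(A), nrow(A))
  for (e in seq_len(ncol(A)))
    sAbs <- sAbs + abs(tcrossprod(M[, e], R[, e]) - tcrossprod(R[, e], M[, e]))
  den <- sAbs^2 - sI2
  out <- ifelse(den > 0, (sI^2 - sI2) / den, 0)
  diag(out) <- 0
  out
}

#' Band dwPLI connectivity matrix
#'
#' For every channel pair, dwPLI is estimated across epochs at each
#' (frequency, time) bin whose frequency lies in the band, and aggregated
#' over bins. The default aggregation records the peak dwPLI across all
#' bins in the band (the ambient connectivity); `"mean"` averages over bins
#' instead, which avoids the positive selection bias the maximum has on
#' uncoupled data.
#'
#' @param tf a [tf_decompose()] result.
#' @param band a band name (see [canonical_bands()]) or one-row band table.
#' @param aggregate `"peak"` (default) or `"mean"`.
#' @return object of class `connectivity_matrix`: `values` (symmetric N x N,
#'   zero diagonal), `band`, `aggregate`, `labels`.
#' @export
band_connectivity <- function(tf, band, aggregate = c("peak", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.character(band)) band <- canonical_bands(band)
  stopifnot(inherits(tf, "tf_decomp"), nrow(band) == 1)
  fidx <- which(tf$freq >= band$lo & tf$freq < band$hi)
  if (!length(fidx))
    stop(sprintf("band %s [%g, %g) contains no frequency bins of the grid",
                 band$name, band$lo, band$hi))
  nch <- dim(tf$coef)[1]
  agg <- matrix(if (aggregate == "peak") -Inf else 0, nch, nch)
  nbins <- 0L
  for (f in fidx) for (s in seq_len(dim(tf$coef)[3])) {
    A <- matrix(tf$coef[, f, s, ], nrow = nch)
    d <- dwpli_matrix_slice(A)
    if (aggregate == "peak") agg <- pmax(agg, d) else agg <- agg + d
    nbins <- nbins + 1L
  }
  if (aggregate == "mean") agg <- agg / nbins
  diag(agg) <- 0
  agg <- pmax(agg, -1)
  dimnames(agg) <- list(tf$labels, tf$labels)
  structure(list(values = agg, band = band$name, aggregate = aggregate,
                 labels = tf$labels), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> band %s (%s over TF bins), %d channels, mean %.3f\n",
              x$band, x$aggregate, nrow(x$values), mean_connectivity(x)))
  invisible(x)
}

#' Mean connectivity over all channel pairs
#'
#' @param m a [band_connectivity()] result or plain symmetric matrix.
#' @return average of the upper-triangle entries.
#' @export
mean_connectivity <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  mean(v[upper.tri(v)])
}

#' dwPLI connectivity matrices for the analysis bands
#'
#' @param rec preprocessed epoched [eeg_recording()].
#' @param config a [tf_config()].
#' @param bands band table (default [analysis_bands()]: delta, theta, alpha).
#' @param aggregate see [band_connectivity()].
#' @return named list of `connectivity_matrix` objects.
#' @export
connectivity_matrices <- function(rec, config = tf_config(),
                                  bands = analysis_bands(),
                                  aggregate = "peak") {
  cfg <- config
  cfg$max_freq <- min(cfg$max_freq, max(bands$hi) + cfg$freq_bin)
  tf <- tf_decompose(rec, cfg)
  out <- lapply(seq_len(nrow(bands)), function(b)
    band_connectivity(tf, bands[b, , drop = FALSE], aggregate))
  names(out) <- bands$name
  out
}
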