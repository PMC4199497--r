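# Preprocessing: zero-phase band-pass filtering, epoching with baseline
# correction, variance-based artifact rejection with neighbour interpolation,
# average referencing, and the EOG-variability control analysis.
# Fixed pipeline order: filter -> epoch/baseline -> reject -> interpolate ->
# average reference.

# Zero-phase FIR filtering. A linear-phase Hamming-window FIR is applied once
# by FFT convolution and its constant group delay removed exactly, which is
# phase-neutral (dwPLI downstream is a pure phase statistic, so any phase
# distortion here would corrupt connectivity). Signal edges are
# reflection-padded by half the filter length.
fir_apply <- function(x, h) {
  # x: channels x samples matrix; h: odd-length symmetric FIR
  L <- length(h)
  half <- (L - 1L) %/% 2L
  n <- ncol(x)
  npad <- min(half, n - 1L)
  idx_pre <- (npad + 1L):2L
  idx_post <- (n - 1L):(n - npad)
  xp <- cbind(x[, idx_pre, drop = FALSE], x, x[, idx_post, drop = FALSE])
  m <- ncol(xp)
  nfft <- stats::nextn(m + L - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - L)))
  out <- matrix(0, nrow(x), n)
  chunk <- 16L
  starts <- seq(1L, nrow(x), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nrow(x))
    X <- stats::mvfft(t(cbind(xp[rows, , drop = FALSE],
                              matrix(0, length(rows), nfft - m))))
    Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
    out[rows, ] <- t(Y[(npad + half + 1L):(npad + half + n), , drop = FALSE])
  }
  out
}

design_fir <- function(lo, hi, fs, n_samples, transition_frac = 0.25) {
  nyq <- fs / 2
  if (lo < 0 || lo >= hi || hi >= nyq)
    stop("require 0 <= lo < hi < Nyquist")
  trans <- if (lo > 0) transition_frac * lo else transition_frac * hi
  taps <- ceiling(3.3 * fs / trans)
  taps <- min(taps, n_samples - 1L)           # cap at the available data
  if (taps %% 2 == 0) taps <- taps + 1L
  if (taps < 9) stop("signal too short to design a usable filter")
  if (lo > 0) {
    signal::fir1(taps - 1L, c(lo, hi) / nyq, type = "pass")
  } else {
    signal::fir1(taps - 1L, hi / nyq, type = "low")
  }
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a zero-phase Hamming-window FIR band-pass
#' (transition width 25% of the relevant cutoff, capped by the data length).
#' When `lo > 0` the DC component is removed. Works on continuous and on
#' epoched recordings (each epoch filtered independently).
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz, `0 <= lo < hi < ` Nyquist.
#' @return filtered recording.
#' @export
bandpass <- function(rec, lo = 0.5, hi = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  n_samp <- if (is_epoched(rec)) dim(rec$data)[3] else ncol(rec$data)
  if (lo > 0 && n_samp / fs < 3 / lo)
    stop(sprintf(paste0("recording (%.1f s) is shorter than ~3 cycles of the ",
                        "%.2g Hz high-pass edge; use longer epochs"),
                 n_samp / fs, lo))
  h <- design_fir(lo, hi, fs, n_samp)
  if (is_epoched(rec)) {
    d <- rec$data
    for (e in seq_len(dim(d)[2]))
      d[, e, ] <- fir_apply(matrix(d[, e, ], nrow = dim(d)[1]), h)
    rec$data <- d
  } else {
    rec$data <- fir_apply(rec$data, h)
  }
  if (lo > 0) {
    # windowed-sinc band-pass passes a small DC residue; remove it exactly
    if (is_epoched(rec)) {
      mu <- rowMeans(rec$data, dims = 2)
      rec$data <- rec$data - as.vector(mu)
    } else {
      rec$data <- rec$data - rowMeans(rec$data)
    }
  }
  add_provenance(rec, sprintf("bandpass(%g-%g Hz, %d taps)", lo, hi, length(h)))
}

#' Segment a continuous recording into baseline-corrected epochs
#'
#' Takes exactly the first `n_epochs * epoch_length` seconds and segments
#' them into consecutive epochs; each epoch is baseline-corrected relative to
#' its own mean voltage (per channel), so per-channel epoch means are 0.
#'
#' @param rec continuous [eeg_recording()].
#' @param epoch_length epoch duration in seconds.
#' @param n_epochs number of epochs.
#' @return epoched recording.
#' @export
epoch_and_baseline <- function(rec, epoch_length = 10, n_epochs = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is_epoched(rec)) stop("recording is already epoched")
  fs <- rec$sampling_rate
  samp <- round(epoch_length * fs)
  need <- samp * n_epochs
  if (ncol(rec$data) < need)
    stop(sprintf("need %.0f s of data for %d x %g s epochs, have %.1f s",
                 need / fs, n_epochs, epoch_length, ncol(rec$data) / fs))
  nch <- nrow(rec$data)
  arr <- array(0, dim = c(nch, n_epochs, samp))
  for (e in seq_len(n_epochs))
    arr[, e, ] <- rec$data[, ((e - 1) * samp + 1):(e * samp)]
  mu <- rowMeans(arr, dims = 2)
  arr <- arr - as.vector(mu)     # recycles over the samples dimension
  out <- eeg_recording(arr, fs, rec$labels, rec$provenance)
  add_provenance(out, sprintf("epoch_and_baseline(%g s x %d)", epoch_length,
                              n_epochs))
}

robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s) || s == 0) return(numeric(length(x)))
  (x - med) / s
}

#' Reject abnormally noisy channels and epochs by normalised variance
#'
#' Log-variance of every channel (pooled over epochs) and every epoch (pooled
#' over channels) is converted to a robust z-score (median/MAD); entries with
#' a score above the threshold are rejected. Rejected epochs are dropped from
#' the data; rejected channels are reported (and subsequently filled by
#' [interpolate_channels()] so the channel count is preserved).
#'
#' @param rec epoched [eeg_recording()].
#' @param z_channel,z_epoch rejection thresholds on the robust z-score of log
#'   variance (default 4).
#' @return list with `recording` (rejected epochs removed) and `report`
#'   (class `rejection_report`: `rejected_channels`, `rejected_epochs`,
#'   `channel_z`, `epoch_z`).
#' @export
reject_by_variance <- function(rec, z_channel = 4, z_epoch = 4) {
  stopifnot(inherits(rec, "eeg_recording"), is_epoched(rec))
  d <- rec$data
  nch <- dim(d)[1]; nep <- dim(d)[2]
  if (nch < 4 || nep < 4)
    stop("need >= 4 channels and >= 4 epochs for variance z-scores")
  nsamp <- dim(d)[3]
  m <- rowMeans(d, dims = 2)
  v <- (rowSums(d^2, dims = 2) - nsamp * m^2) / (nsamp - 1)  # channels x epochs
  chan_lv <- log(rowMeans(v))
  chan_z <- robust_z(chan_lv)
  bad_ch <- which(chan_z > z_channel)
  keep_ch <- setdiff(seq_len(nch), bad_ch)
  ep_lv <- log(colMeans(v[keep_ch, , drop = FALSE]))
  ep_z <- robust_z(ep_lv)
  bad_ep <- which(ep_z > z_epoch)
  if (length(bad_ch) > nch / 2 || length(bad_ep) > nep / 2)
    stop(sprintf("more than half of channels (%d/%d) or epochs (%d/%d) would be rejected; aborting",
                 length(bad_ch), nch, length(bad_ep), nep))
  if (length(bad_ep)) rec$data <- d[, -bad_ep, , drop = FALSE]
  report <- structure(list(
    rejected_channels = rec$labels[bad_ch],
    rejected_epochs = as.integer(bad_ep),
    channel_z = stats::setNames(chan_z, rec$labels),
    epoch_z = ep_z
  ), class = "rejection_report")
  rec <- add_provenance(rec, sprintf(
    "reject_by_variance(z_ch=%g, z_ep=%g): %d channels, %d epochs rejected",
    z_channel, z_epoch, length(bad_ch), length(bad_ep)))
  list(recording = rec, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d channel(s), %d epoch(s) rejected\n",
              length(x$rejected_channels), length(x$rejected_epochs)))
  invisible(x)
}

#' Fill rejected channels by inverse-distance neighbour average
#'
#' Each listed channel is replaced, in every epoch, by the inverse-distance
#' weighted average of its `k` nearest non-rejected neighbours on the scalp.
#' A simple spatial fill that preserves the channel count; it is not a
#' spherical-spline interpolation and is flagged as such in provenance.
#'
#' @param rec epoched [eeg_recording()].
#' @param mont the recording's [montage()].
#' @param labels channel labels to fill.
#' @param k number of neighbours (default 4).
#' @return recording with the listed channels replaced.
#' @export
interpolate_channels <- function(rec, mont, labels, k = 4) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(mont, "montage"))
  if (!length(labels)) return(rec)
  miss <- setdiff(labels, rec$labels)
  if (length(miss)) stop("channels not in recording: ", paste(miss, collapse = ", "))
  good <- setdiff(rec$labels, labels)
  if (length(good) < k) stop("not enough intact channels to interpolate from")
  D <- mont$distances[rec$labels, rec$labels]
  for (lab in labels) {
    d <- D[lab, good]
    nb <- good[order(d)][seq_len(k)]
    w <- 1 / pmax(D[lab, nb], 1e-9)
    w <- w / sum(w)
    i <- match(lab, rec$labels)
    j <- match(nb, rec$labels)
    if (is_epoched(rec)) {
      acc <- array(0, dim = dim(rec$data)[2:3])
      for (q in seq_along(j)) acc <- acc + w[q] * rec$data[j[q], , ]
      rec$data[i, , ] <- acc
    } else {
      rec$data[i, ] <- as.vector(w %*% rec$data[j, , drop = FALSE])
    }
  }
  add_provenance(rec, sprintf(
    "interpolate_channels(k=%d, inverse-distance fill, not spline): %s",
    k, paste(labels, collapse = ",")))
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean over all channels, so
#' the channel-mean is 0 everywhere. Idempotent.
#'
#' @param rec an [eeg_recording()] with >= 2 channels.
#' @return re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stop("average reference needs >= 2 channels")
  if (is_epoched(rec)) {
    mu <- colMeans(rec$data, dims = 1)       # epochs x samples
    rec$data <- rec$data - rep(mu, each = dim(rec$data)[1])
  } else {
    rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  }
  add_provenance(rec, "average_reference")
}

#' EOG variability timecourse
#'
#' Derives vertical bipolar electro-oculographic channels from the raw
#' (pre-rejection) recording as the difference of two channel pairs, filters
#' them to 1-3 Hz to isolate eye-movement activity, computes the SD within
#' 1-second non-overlapping windows, averages the two derivations, and
#' normalises the result by its own mean (so the mean over windows is 1).
#' The mean over the first and second half of the recording supports a
#' sleep-onset check: a progressive decline in eye activity would depress the
#' second half.
#'
#' @param rec continuous [eeg_recording()] before channel rejection.
#' @param left_pair,right_pair character vectors of 2 channel labels whose
#'   difference forms each EOG derivation. Defaults are the conventional
#'   high-density net derivations (channels 25-127 and 8-126).
#' @param window window length in seconds (default 1).
#' @return object of class `eog_timecourse`: `values` (normalised SD per
#'   window), `halves_means` (length 2), `degenerate` (TRUE when all windows
#'   had zero SD).
#' @export
eog_variability <- function(rec, left_pair = c("25", "127"),
                            right_pair = c("8", "126"), window = 1) {
  stopifnot(inherits(rec, "eeg_recording"), !is_epoched(rec))
  need <- c(left_pair, right_pair)
  miss <- setdiff(need, rec$labels)
  if (length(miss)) stop("EOG channels missing from recording: ",
                         paste(miss, collapse = ", "))
  fs <- rec$sampling_rate
  der <- rbind(rec$data[match(left_pair[1], rec$labels), ] -
                 rec$data[match(left_pair[2], rec$labels), ],
               rec$data[match(right_pair[1], rec$labels), ] -
                 rec$data[match(right_pair[2], rec$labels), ])
  der <- fir_apply(der, design_fir(1, 3, fs, ncol(der)))
  wlen <- round(window * fs)
  nwin <- floor(ncol(der) / wlen)
  sds <- vapply(seq_len(nwin), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    mean(apply(der[, idx, drop = FALSE], 1, stats::sd))
  }, numeric(1))
  degenerate <- all(sds == 0)
  values <- if (degenerate) sds else sds / mean(sds)
  half <- floor(nwin / 2)
  halves <- c(mean(values[seq_len(half)]), mean(values[(half + 1):nwin]))
  structure(list(values = values, halves_means = halves,
                 degenerate = degenerate, window = window),
            class = "eog_timecourse")
}

#' Run the fixed preprocessing pipeline on a continuous recording
#'
#' Order: band-pass filter, epoch + baseline-correct, variance-based
#' rejection, inverse-distance fill of rejected channels, average reference.
#'
#' @param rec continuous [eeg_recording()].
#' @param mont the [montage()] (needed for channel interpolation).
#' @param lo,hi filter band (Hz).
#' @param epoch_length,n_epochs epoch grid.
#' @param z_channel,z_epoch rejection thresholds.
#' @return list `recording` (clean epoched recording), `report`
#'   (rejection report).
#' @export
preprocess_recording <- function(rec, mont, lo = 0.5, hi = 45,
                                 epoch_length = 10, n_epochs = 60,
                                 z_channel = 4, z_epoch = 4) {
  rec <- bandpass(rec, lo, hi)
  rec <- epoch_and_baseline(rec, epoch_length, n_epochs)
  rej <- reject_by_variance(rec, z_channel, z_epoch)
  rec <- rej$recording
  if (length(rej$report$rejected_channels))
    rec <- interpolate_channels(rec, mont, rej$report$rejected_channels)
  rec <- average_reference(rec)
  list(recording = rec, report = rej$report)
}
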