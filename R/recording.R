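#' EEG recording containers
#'
#' Two container shapes are used. A *continuous* recording holds a
#' channels x samples matrix; an *epoched* recording holds a
#' channels x epochs x samples array. Both carry the sampling rate (Hz),
#' channel labels, and a provenance log of applied operations (each entry a
#' character string; seeds of randomized operations are recorded there).
#'
#' @param data channels x samples matrix (continuous) or
#'   channels x epochs x samples array (epoched), in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param labels channel labels (one per row of `data`).
#' @param provenance character vector of processing steps already applied.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, labels = NULL,
                          provenance = character()) {
  stopifnot_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("data must be a 2D matrix or 3D array")
  n_ch <- dim(data)[1]
  if (is.null(labels)) labels <- paste0("E", seq_len(n_ch))
  labels <- as.character(labels)
  if (length(labels) != n_ch) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  structure(list(data = data, sampling_rate = sampling_rate,
                 labels = labels, provenance = provenance),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  if (is_epoched(x)) {
    cat(sprintf("<eeg_recording> %d ch x %d epochs x %d samples @ %g Hz (%g s epochs)\n",
                d[1], d[2], d[3], x$sampling_rate, d[3] / x$sampling_rate))
  } else {
    cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (continuous, %.1f s)\n",
                d[1], d[2], x$sampling_rate, d[2] / x$sampling_rate))
  }
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Is a recording epoched?
#' @param x an [eeg_recording()].
#' @return TRUE if `x` holds a channels x epochs x samples array.
#' @export
is_epoched <- function(x) length(dim(x$data)) == 3L

n_channels <- function(x) dim(x$data)[1]
n_epochs <- function(x) if (is_epoched(x)) dim(x$data)[2] else NA_integer_
epoch_length <- function(x) {
  if (!is_epoched(x)) return(NA_real_)
  dim(x$data)[3] / x$sampling_rate
}

add_provenance <- function(x, step) {
  x$provenance <- c(x$provenance, step)
  x
}

#' Write a recording to the internal single-file container
#'
#' The internal container is a single serialized file holding the data
#' tensor, sampling rate, labels and the provenance log. Round-trips are
#' bit-identical.
#'
#' @param rec an [eeg_recording()].
#' @param path output path (conventionally `.rec.rds`).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path, version = 3, compress = "gzip")
  invisible(path)
}

#' Read a recording (internal container or EDF)
#'
#' @param path file path.
#' @param format `"internal"` for the package's own container, `"edf"` for
#'   European Data Format. EDF input is returned as a continuous recording
#'   (epoching is a preprocessing step).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("internal", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "internal") {
    rec <- tryCatch(readRDS(path), error = function(e)
      stop("not a readable internal recording: ", path, call. = FALSE))
    if (!inherits(rec, "eeg_recording"))
      stop("file does not contain an eeg_recording: ", path)
    return(rec)
  }
  read_edf(path)
}

# ---- minimal EDF support (continuous, 16-bit) -------------------------------
# EDF: 256-byte fixed header, 256 bytes per signal header block, then data
# records of 2-byte little-endian integers. Only what the pipeline needs for
# ingest: equal sampling rates across channels, continuous recordings.

read_edf_header_field <- function(con, nbytes) {
  trimws(rawToChar(readBin(con, "raw", nbytes)))
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_header_field(con, 8)
  if (!nzchar(version)) stop("unreadable EDF header in ", path)
  readBin(con, "raw", 80 + 80 + 8 + 8)          # patient, recording, date, time
  read_edf_header_field(con, 8)                 # header bytes (recomputed below)
  readBin(con, "raw", 44)                       # reserved
  n_rec <- as.integer(read_edf_header_field(con, 8))
  dur <- as.numeric(read_edf_header_field(con, 8))
  ns <- as.integer(read_edf_header_field(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF file declares no signals: ", path)
  fld <- function(w) vapply(seq_len(ns), function(i)
    read_edf_header_field(con, w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                               # transducer, physical dim
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                                       # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)                                       # reserved
  if (length(unique(nsamp)) != 1)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- nsamp[1] / dur
  gain <- (pmax - pmin) / (dmax - dmin)
  dat <- matrix(0, nrow = ns, ncol = n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * nsamp[1], size = 2,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = nsamp[1], ncol = ns)
    idx <- ((r - 1) * nsamp[1] + 1):(r * nsamp[1])
    dat[, idx] <- t(block * rep(gain, each = nsamp[1]) +
                      rep(pmin - dmin * gain, each = nsamp[1]))
  }
  eeg_recording(dat, fs, labels,
                provenance = sprintf("read_edf(%s)", basename(path)))
}

#' Write a continuous recording as a minimal EDF file
#'
#' 16-bit EDF with one data record per second; physical range taken from the
#' data. Intended for interoperability checks, not archival.
#'
#' @param rec continuous [eeg_recording()].
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"), !is_epoched(rec))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- n_channels(rec)
  nsamp <- as.integer(fs)
  n_rec <- floor(ncol(rec$data) / nsamp)
  if (n_rec < 1) stop("recording shorter than one 1-second data record")
  x <- rec$data[, seq_len(n_rec * nsamp), drop = FALSE]
  pmin <- floor(min(x)); pmax <- ceiling(max(x))
  if (pmax <= pmin) pmax <- pmin + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  hdr_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(hdr_bytes), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (l in rec$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(as.character(pmin), 8)
  for (i in seq_len(ns)) wr(as.character(pmax), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(nsamp), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * nsamp + 1):(r * nsamp)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
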