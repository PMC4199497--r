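# Synthetic EEG cohorts with planted spectral and network structure.
#
# The generator emulates the study conditions the pipeline is built for:
# 91-channel, 250 Hz, 10-minute recordings (60 x 10 s epochs); control-like
# subjects carry strong long-range alpha modules (plus inter-modular hub
# channels), patient-like subjects carry spatially compact delta/theta
# clusters, a weak long-range alpha remnant whose strength kappa varies
# across subjects, and delta-dominant spectra; all sources are projected
# through a zero-lag distance-decaying mixing kernel (volume conduction) on
# top of 1/f background noise; synthetic CRS-R scores are tied linearly to
# the planted alpha coupling strength.

#' Specification of a synthetic cohort
#'
#' @param n_controls,n_patients subject counts per group.
#' @param n_channels electrodes (default 91).
#' @param sampling_rate Hz (default 250).
#' @param n_epochs,epoch_length epoch grid (default 60 x 10 s).
#' @param regimes list of per-group coupling regimes; see Details.
#' @param noise list: `exponent` (1/f slope, default 1) and `amplitude`
#'   (per-channel RMS of the background, default 1).
#' @param mixing list: `kernel_width`, the Gaussian width (in normalised
#'   scalp distance) of the instantaneous volume-conduction kernel.
#' @param crs_r_model list: `intercept`, `slope` (on the planted alpha
#'   coupling strength kappa), `sd` (score noise), `range` (integer clip).
#' @param seed master seed for the cohort.
#'
#' @details Each regime entry has fields `freq` (Hz), `kappa` (coupling
#' strength in `[0,1]` scaling source amplitude; a length-2 vector is a
#' per-subject uniform sampling range), `phase_lag_scale` (spread of
#' per-channel phase offsets, radians), `n_modules`, `layout` (`"long"`:
#' modules pair opposite azimuthal scalp sectors and a ring of apex channels
#' acts as inter-modular hubs; `"short"`: modules are compact spatial
#' clusters, rotated by a per-subject random angle so patient topologies are
#' idiosyncratic), `amp_var` (SD of per-epoch amplitude modulation, driving
#' temporal variability of band power), and optionally `amp_scale` (extra
#' source amplitude multiplier, letting a regime's spectral power be set
#' independently of its phase stability). The per-subject alpha kappa
#' draw is the subject's "network quality" used by `crs_r_model`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 15, n_patients = 15, n_channels = 91,
                        sampling_rate = 250, n_epochs = 60, epoch_length = 10,
                        regimes = default_regimes(),
                        noise = list(exponent = 1, amplitude = 1),
                        mixing = list(kernel_width = 0.12),
                        crs_r_model = list(intercept = 6, slope = 14, sd = 1,
                                           range = c(7L, 19L)),
                        seed = 1) {
  stopifnot(n_controls >= 0, n_patients >= 0, n_channels >= 2,
            sampling_rate > 0, n_epochs >= 1, epoch_length > 0)
  for (grp in names(regimes)) for (rg in regimes[[grp]]) {
    if (any(rg$kappa < 0) || any(rg$kappa > 1))
      stop("regime kappa must lie in [0,1]")
    if (rg$freq <= 0 || rg$freq >= sampling_rate / 2)
      stop("regime frequency must lie below Nyquist")
    if (!is.null(rg$phase_lag_scale) &&
        (rg$phase_lag_scale <= 0 || rg$phase_lag_scale > pi))
      stop("phase_lag_scale must lie in (0, pi]")
  }
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 n_channels = n_channels, sampling_rate = sampling_rate,
                 n_epochs = n_epochs, epoch_length = epoch_length,
                 regimes = regimes, noise = noise, mixing = mixing,
                 crs_r_model = crs_r_model, seed = seed),
            class = "cohort_spec")
}

#' Default coupling regimes for the two synthetic groups
#'
#' Controls: one strong long-range alpha regime (10 Hz, kappa 0.9, two
#' diametral sector modules plus apex hubs, strongly amplitude-modulated).
#' Patients: compact delta (2.5 Hz) and theta (6 Hz) patch regimes plus a
#' long-range alpha remnant whose kappa is drawn per subject from
#' `[0.05, 0.7]`, spanning near-absent to moderately preserved alpha
#' networks.
#' @return nested list of regimes by group.
#' @export
default_regimes <- function() {
  list(
    control = list(
      alpha = list(freq = 10, kappa = 0.9, phase_lag_scale = pi / 2,
                   n_modules = 2, layout = "long", amp_var = 0.5)
    ),
    patient = list(
      delta = list(freq = 2.5, kappa = 0.9, amp_scale = 1.2,
                   phase_lag_scale = pi / 2, n_modules = 12,
                   patch_size = c(5, 4), layout = "short", amp_var = 0.15),
      theta = list(freq = 6, kappa = 0.8, amp_scale = 0.85,
                   phase_lag_scale = pi / 2, n_modules = 10,
                   patch_size = c(5, 4), layout = "short", amp_var = 0.15),
      alpha = list(freq = 10, kappa = c(0.05, 0.7), phase_lag_scale = pi / 2,
                   n_modules = 2, layout = "long", amp_var = 0.15)
    )
  )
}

# Reference source amplitude: a kappa = 0.9 source has oscillation power
# equal to the default unit-variance background.
.base_amp <- sqrt(2) / 0.9

# Coupling strength -> phase stability. kappa controls how tightly member
# channels hold their planted phase offsets across epochs: per channel and
# epoch the offset is jittered by N(0, sigma^2) with sigma = 2.2 * (1 -
# kappa) radians. dwPLI measures phase-lag consistency, which saturates with
# amplitude, so without this mapping any nonzero coupling would read as a
# near-perfect network; with it, dwPLI rises smoothly from noise level
# (kappa near 0) to near 1 (kappa near 1).
.jitter_rad <- 2.2
phase_jitter_sd <- function(kappa) .jitter_rad * (1 - kappa)

# ---- module layouts ---------------------------------------------------------

# Long-range layout: 2*m azimuthal sectors; module j = sectors j and j+m
# (diametrically opposite), so every module spans the scalp. The n_hubs
# channels nearest the cap apex couple into every module (inter-modular
# hubs).
layout_long <- function(mont, n_modules,
                        n_hubs = round(length(mont$labels) / 9)) {
  pos <- mont$positions
  theta <- atan2(pos[, 2], pos[, 1])
  sec <- floor((theta + pi) / (2 * pi) * (2 * n_modules))
  sec[sec == 2 * n_modules] <- 0
  assign <- (sec %% n_modules) + 1L
  hubs <- order(pos[, 3], decreasing = TRUE)[seq_len(min(n_hubs, nrow(pos)))]
  list(assignment = as.integer(assign), hubs = as.integer(hubs))
}

# Short-range layout: n_modules small spatial patches of `patch_size`
# channels each, seeded by farthest-point sampling from a rotated start so
# that different subjects get different (idiosyncratic) patch maps. Patches
# do not tile the scalp: channels outside every patch carry no source for
# this regime (assignment 0), mirroring focal patches of locally
# synchronised cortex surrounded by unstructured background.
layout_short <- function(mont, n_modules, patch_size = 5, angle = 0) {
  patch_size <- rep_len(patch_size, n_modules)
  pos <- mont$positions
  rot <- cbind(c(cos(angle), sin(angle), 0),
               c(-sin(angle), cos(angle), 0),
               c(0, 0, 1))
  p <- pos %*% rot
  n <- nrow(p)
  if (sum(patch_size) > n)
    stop("patch layout needs sum(patch_size) <= n_channels")
  D <- mont$distances
  # farthest-point seeds, starting from the channel most aligned with the
  # rotated x-axis (rotation = per-subject idiosyncrasy)
  seeds <- integer(n_modules)
  seeds[1] <- which.max(p[, 1])
  if (n_modules > 1) for (m in 2:n_modules)
    seeds[m] <- which.max(apply(D[, seeds[seq_len(m - 1)], drop = FALSE], 1, min))
  assign <- integer(n)
  for (m in seq_len(n_modules)) {
    free <- which(assign == 0L)
    nb <- free[order(D[seeds[m], free])]
    assign[nb[seq_len(patch_size[m])]] <- m
  }
  list(assignment = assign, hubs = integer(0))
}

regime_layout <- function(regime, mont, subject_angle = 0) {
  if (identical(regime$layout, "long")) layout_long(mont, regime$n_modules)
  else layout_short(mont, regime$n_modules,
                    patch_size = regime$patch_size %||% 5,
                    angle = subject_angle)
}

# ---- source synthesis -------------------------------------------------------

# Band-limited oscillatory sources for one regime. Each module carries a
# common sinusoid with a fresh random phase and amplitude per epoch; each
# member channel receives it with a fixed per-channel phase offset
# (low-discrepancy spread over +/- phase_lag_scale), so almost all member
# pairs have a nonzero, non-pi phase lag. Hub channels (long layout) receive
# every module's rhythm, with the SAME per-epoch phase draw, at reduced
# amplitude - that shared phase is what couples hubs into all modules.
regime_sources <- function(regime, layout, amp, n_epochs, samp_per_epoch, fs,
                           jitter_sd = 0) {
  n_ch <- length(layout$assignment)
  S <- matrix(0, n_ch, n_epochs * samp_per_epoch)
  tt <- (seq_len(samp_per_epoch) - 1) / fs
  golden <- (sqrt(5) - 1) / 2
  mods <- setdiff(sort(unique(layout$assignment)), 0L)   # 0 = no source
  for (m in mods) {
    members <- setdiff(which(layout$assignment == m), layout$hubs)
    phase_off <- ((seq_along(members) * golden) %% 1 - 0.5) *
      2 * regime$phase_lag_scale
    hub_off <- if (length(layout$hubs))
      ((seq_along(layout$hubs) * golden + 0.31 * m) %% 1 - 0.5) *
        2 * regime$phase_lag_scale else numeric(0)
    hub_gain <- 1 / sqrt(max(1, length(mods)))
    for (e in seq_len(n_epochs)) {
      psi <- runif(1, 0, 2 * pi)
      a_e <- amp * max(0.1, 1 + regime$amp_var * rnorm(1))
      s <- a_e * sin(2 * pi * regime$freq * tt + psi)
      c_ <- a_e * cos(2 * pi * regime$freq * tt + psi)
      idx <- ((e - 1) * samp_per_epoch + 1):(e * samp_per_epoch)
      if (length(members)) {
        off_e <- phase_off + rnorm(length(members), 0, jitter_sd)
        S[members, idx] <- S[members, idx] +
          outer(cos(off_e), s) + outer(sin(off_e), c_)
      }
      if (length(layout$hubs)) {
        hub_e <- hub_off + rnorm(length(layout$hubs), 0, jitter_sd)
        S[layout$hubs, idx] <- S[layout$hubs, idx] +
          hub_gain * (outer(cos(hub_e), s) + outer(sin(hub_e), c_))
      }
    }
  }
  S
}

# 1/f^exponent background noise, one independent trace per channel,
# scaled to the requested RMS amplitude.
pink_noise <- function(n_ch, n_samp, fs, exponent = 1, amplitude = 1) {
  freqs <- seq(0, fs, length.out = n_samp + 1)[seq_len(n_samp)]
  f <- pmin(freqs, fs - freqs)
  shape <- ifelse(f < fs / n_samp, 0, f^(-exponent / 2))
  out <- matrix(0, n_ch, n_samp)
  for (ch in seq_len(n_ch)) {
    z <- complex(real = rnorm(n_samp), imaginary = rnorm(n_samp)) * shape
    x <- Re(stats::fft(z, inverse = TRUE))
    out[ch, ] <- x / stats::sd(x) * amplitude
  }
  out
}

gaussian_mixing_kernel <- function(mont, width) {
  exp(-mont$distances^2 / (2 * width^2))
}

#' Simulate a lag-coupled two-channel recording
#'
#' Channel 2 carries channel 1's oscillation phase-shifted by `lag`; both
#' channels add independent Gaussian noise. The per-epoch initial phase is
#' random. This is the oracle fixture for the dwPLI estimator: a lag of 0 is
#' a pure common source (invisible to dwPLI by construction), a lag of pi/2
#' is maximally visible.
#'
#' @param freq oscillation frequency (Hz, below Nyquist).
#' @param lag phase lag in radians (normalised into (-pi, pi]).
#' @param snr oscillation power / noise power per channel. `snr = 0` gives
#'   independent noise channels.
#' @param n_epochs,sampling_rate,epoch_length recording grid.
#' @param seed integer seed.
#' @return epoched [eeg_recording()] with 2 channels.
#' @export
simulate_coupled_pair <- function(freq = 10, lag = pi / 2, snr = 10,
                                  n_epochs = 60, sampling_rate = 250,
                                  epoch_length = 10, seed = 1) {
  if (freq <= 0 || freq >= sampling_rate / 2)
    stop("freq must lie strictly between 0 and Nyquist")
  lag <- ((lag + pi) %% (2 * pi)) - pi
  if (lag == -pi) lag <- pi
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  samp <- round(epoch_length * sampling_rate)
  tt <- (seq_len(samp) - 1) / sampling_rate
  amp <- sqrt(2 * snr)                      # unit-variance noise per channel
  dat <- array(0, dim = c(2, n_epochs, samp))
  for (e in seq_len(n_epochs)) {
    psi <- runif(1, 0, 2 * pi)
    dat[1, e, ] <- amp * sin(2 * pi * freq * tt + psi) + rnorm(samp)
    dat[2, e, ] <- amp * sin(2 * pi * freq * tt + psi + lag) + rnorm(samp)
  }
  eeg_recording(dat, sampling_rate, c("ch1", "ch2"),
                provenance = sprintf(
                  "simulate_coupled_pair(f=%g, lag=%.3f, snr=%g, seed=%d)",
                  freq, lag, snr, as.integer(seed)))
}

#' Simulate one synthetic subject
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @param seed per-subject seed.
#' @param mont shared cohort [montage()]; generated from the cohort spec's seed when
#'   NULL.
#' @return list with `recording` (continuous [eeg_recording()], epochs
#'   concatenated), `truth` (planted module assignments per regime, per-
#'   subject kappa draws), and `crs_r` (integer, patients only).
#' @export
simulate_subject <- function(spec, group = c("control", "patient"), seed = 1,
                             mont = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  if (is.null(mont)) mont <- generate_montage(spec$n_channels, spec$seed)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  samp <- round(spec$epoch_length * spec$sampling_rate)
  total <- samp * spec$n_epochs
  regimes <- spec$regimes[[group]]
  subject_angle <- runif(1, 0, 2 * pi)
  S <- matrix(0, spec$n_channels, total)
  truth <- list(group = group, seed = as.integer(seed), regimes = list())
  kappa_alpha <- NA_real_
  for (nm in names(regimes)) {
    rg <- regimes[[nm]]
    kappa <- if (length(rg$kappa) == 2) runif(1, rg$kappa[1], rg$kappa[2])
             else rg$kappa
    lay <- regime_layout(rg, mont, subject_angle)
    if (kappa > 0)
      S <- S + regime_sources(rg, lay,
                              kappa * (rg$amp_scale %||% 1) * .base_amp,
                              spec$n_epochs, samp, spec$sampling_rate,
                              jitter_sd = phase_jitter_sd(kappa))
    truth$regimes[[nm]] <- list(freq = rg$freq, kappa = kappa,
                                assignment = lay$assignment,
                                hubs = lay$hubs)
    if (nm == "alpha") kappa_alpha <- kappa
  }
  truth$kappa_alpha <- kappa_alpha
  G <- gaussian_mixing_kernel(mont, spec$mixing$kernel_width)
  X <- G %*% S + pink_noise(spec$n_channels, total, spec$sampling_rate,
                            spec$noise$exponent, spec$noise$amplitude)
  crs_r <- NA_integer_
  if (group == "patient") {
    cm <- spec$crs_r_model
    raw <- cm$intercept + cm$slope * kappa_alpha + rnorm(1, 0, cm$sd)
    crs_r <- as.integer(min(max(round(raw), cm$range[1]), cm$range[2]))
  }
  rec <- eeg_recording(X, spec$sampling_rate, mont$labels,
                       provenance = sprintf(
                         "simulate_subject(group=%s, seed=%d)", group,
                         as.integer(seed)))
  list(recording = rec, truth = truth, crs_r = crs_r)
}

#' Simulate a full cohort to disk
#'
#' Writes one internal-format recording per subject, the shared montage
#' file, a subject metadata CSV (`subject_id, group, crs_r, imagery`) and a
#' ground-truth JSON (planted assignments and kappa per subject). Patients
#' are labelled VS when their synthetic CRS-R is <= 8 and MCS otherwise;
#' the imagery flag is a random draw (rate 1/3) independent of the network,
#' mirroring its role as an external annotation.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if missing).
#' @return manifest list: `dir`, `montage_path`, `metadata_path`,
#'   `truth_path`, `recordings` (named paths), `subjects` (the metadata
#'   data.frame), `truth` (in-memory ground truth).
#' @export
simulate_cohort <- function(spec, dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mont <- generate_montage(spec$n_channels, spec$seed)
  montage_path <- file.path(dir, "montage.txt")
  write_montage(mont, montage_path)
  n <- spec$n_controls + spec$n_patients
  seeds <- derive_seeds(spec$seed, n + 1)
  groups <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
  ids <- c(sprintf("C%02d", seq_len(spec$n_controls)),
           sprintf("P%02d", seq_len(spec$n_patients)))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seeds[n + 1])
  imagery_draw <- runif(n) < 1 / 3
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rec_paths <- character(n)
  crs <- rep(NA_integer_, n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- simulate_subject(spec, groups[i], seeds[i], mont)
    rec_paths[i] <- file.path(dir, paste0(ids[i], ".rec.rds"))
    write_recording(sub$recording, rec_paths[i])
    crs[i] <- sub$crs_r
    truth[[i]] <- sub$truth
    ms_log(sprintf("simulated %s (%s)", ids[i], groups[i]))
  }
  names(truth) <- ids
  names(rec_paths) <- ids
  grp_label <- ifelse(groups == "control", "control",
                      ifelse(crs <= 8, "VS", "MCS"))
  subjects <- data.frame(
    subject_id = ids, group = grp_label, crs_r = crs,
    imagery = ifelse(groups == "control", NA, imagery_draw),
    stringsAsFactors = FALSE)
  metadata_path <- file.path(dir, "subjects.csv")
  utils::write.csv(subjects, metadata_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = spec$seed,
         kappa_alpha = stats::setNames(
           vapply(truth, function(t) t$kappa_alpha %||% NA_real_, numeric(1)),
           ids),
         subjects = truth),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(dir = dir, montage_path = montage_path, metadata_path = metadata_path,
       truth_path = truth_path, recordings = rec_paths, subjects = subjects,
       truth = truth, spec = spec)
}
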