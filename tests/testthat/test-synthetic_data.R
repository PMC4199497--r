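small_spec <- function(...) {
  # desk-scale cohort: fewer channels/epochs, same generative structure
  reg <- default_regimes()
  reg$patient$delta$n_modules <- 6
  reg$patient$theta$n_modules <- 5
  cohort_spec(n_controls = 2, n_patients = 2, n_channels = 32,
              n_epochs = 12, epoch_length = 10, regimes = reg, ...)
}

test_that("generated montages are deterministic with sane geometry", {
  m1 <- generate_montage(91, seed = 5)
  m2 <- generate_montage(91, seed = 5)
  expect_identical(m1, m2)
  m3 <- generate_montage(91, seed = 6)
  expect_false(isTRUE(all.equal(m1$positions, m3$positions)))

  expect_equal(generate_montage(2, seed = 1)$distances[1, 2], 1)

  # quasi-uniformity: nearest-neighbour distance CV < 0.5 (brute force)
  d <- m1$distances; diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.5)
  expect_error(generate_montage(1), ">= 2")
})

test_that("coupled pairs are reproducible and respect the lag convention", {
  r1 <- simulate_coupled_pair(10, pi / 2, 10, n_epochs = 5, seed = 3)
  r2 <- simulate_coupled_pair(10, pi / 2, 10, n_epochs = 5, seed = 3)
  expect_identical(r1$data, r2$data)
  # lag is normalised into (-pi, pi]
  r3 <- simulate_coupled_pair(10, 2 * pi + 0.4, 10, n_epochs = 2, seed = 3)
  expect_match(r3$provenance, "lag=0.400")
  expect_error(simulate_coupled_pair(200, 0, 1), "Nyquist")
})

test_that("subjects are deterministic given the seed", {
  spec <- small_spec(seed = 9)
  mont <- generate_montage(spec$n_channels, spec$seed)
  s1 <- simulate_subject(spec, "patient", seed = 77, mont)
  s2 <- simulate_subject(spec, "patient", seed = 77, mont)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$crs_r, s2$crs_r)
})

test_that("planted spectra: control alpha dominance, patient delta dominance", {
  spec <- small_spec(seed = 11)
  mont <- generate_montage(spec$n_channels, spec$seed)
  ctrl <- simulate_subject(spec, "control", seed = 21, mont)
  pp_c <- preprocess_recording(ctrl$recording, mont, n_epochs = spec$n_epochs)
  cc <- colMeans(band_contributions(welch_spectrum(pp_c$recording))$contributions)
  expect_gt(cc["alpha"], cc["delta"])

  pat <- simulate_subject(spec, "patient", seed = 22, mont)
  pp_p <- preprocess_recording(pat$recording, mont, n_epochs = spec$n_epochs)
  cp <- colMeans(band_contributions(welch_spectrum(pp_p$recording))$contributions)
  expect_gt(cp["delta"], 50)
})

test_that("signals are finite with variance near the configured noise scale", {
  spec <- small_spec(seed = 12)
  mont <- generate_montage(spec$n_channels, spec$seed)
  for (grp in c("control", "patient")) {
    s <- simulate_subject(spec, grp, seed = 31, mont)
    expect_true(all(is.finite(s$recording$data)))
    v <- apply(s$recording$data, 1, var)
    expect_true(all(v < 10 * spec$noise$amplitude^2))
    expect_true(all(v > spec$noise$amplitude^2 / 10))
  }
})

test_that("ground truth carries planted modules and kappa", {
  spec <- small_spec(seed = 13)
  mont <- generate_montage(spec$n_channels, spec$seed)
  s <- simulate_subject(spec, "patient", seed = 41, mont)
  expect_named(s$truth$regimes, c("delta", "theta", "alpha"))
  expect_length(s$truth$regimes$delta$assignment, spec$n_channels)
  expect_true(s$truth$kappa_alpha >= 0.05 && s$truth$kappa_alpha <= 0.7)
  expect_true(s$crs_r >= 7 && s$crs_r <= 19)
})

test_that("cohort simulation writes a complete, loadable file set", {
  spec <- small_spec(seed = 14)
  dir <- file.path(tempdir(), "cohort14")
  man <- simulate_cohort(spec, dir)
  expect_length(man$recordings, 4)
  expect_true(all(file.exists(man$recordings)))
  expect_true(file.exists(man$montage_path))
  expect_true(file.exists(man$metadata_path))
  expect_true(file.exists(man$truth_path))
  subj <- validate_subject_table(man$metadata_path)
  expect_equal(nrow(subj), 4)
  expect_equal(sum(is_patient_group(subj$group)), 2)
  rec <- read_recording(man$recordings[[1]])
  expect_equal(dim(rec$data), c(32, 12 * 10 * 250))
  tru <- jsonlite::read_json(man$truth_path, simplifyVector = TRUE)
  expect_length(tru$kappa_alpha, 4)
})

test_that("crs_r model: planted positive slope shows in the metadata, null stays flat", {
  reg <- default_regimes()
  reg$patient$delta <- modifyList(reg$patient$delta,
                                  list(n_modules = 3, patch_size = 4))
  reg$patient$theta <- modifyList(reg$patient$theta,
                                  list(n_modules = 2, patch_size = 4))
  spec_pos <- cohort_spec(n_controls = 0, n_patients = 25, n_channels = 24,
                          n_epochs = 2, epoch_length = 4, regimes = reg,
                          seed = 15)
  mont <- generate_montage(24, spec_pos$seed)
  seeds <- derive_seeds(spec_pos$seed, 25)
  kap <- crs <- numeric(25)
  for (i in 1:25) {
    s <- simulate_subject(spec_pos, "patient", seeds[i], mont)
    kap[i] <- s$truth$kappa_alpha; crs[i] <- s$crs_r
  }
  expect_gt(cor(kap, crs), 0.5)

  spec_null <- spec_pos
  spec_null$crs_r_model$slope <- 0
  spec_null$crs_r_model$sd <- 2
  crs0 <- kap0 <- numeric(25)
  for (i in 1:25) {
    s <- simulate_subject(spec_null, "patient", seeds[i], mont)
    kap0[i] <- s$truth$kappa_alpha; crs0[i] <- s$crs_r
  }
  r <- robust_regression(kap0, crs0)
  expect_true(r$slope_lo <= 0 && r$slope_hi >= 0)
})

test_that("zero-lag volume conduction alone leaves mean dwPLI near zero", {
  # kappa = 0: only mixed background noise reaches the electrodes
  reg <- default_regimes()
  for (nm in names(reg$control)) reg$control[[nm]]$kappa <- 0
  spec <- cohort_spec(n_controls = 1, n_patients = 0, n_channels = 12,
                      n_epochs = 30, epoch_length = 10, regimes = reg,
                      mixing = list(kernel_width = 0.3), seed = 16)
  mont <- generate_montage(12, spec$seed)
  s <- simulate_subject(spec, "control", seed = 51, mont)
  ep <- epoch_and_baseline(s$recording, 10, 30)
  tf <- tf_decompose(ep, tf_config_coarse())
  for (b in c("delta", "theta", "alpha")) {
    cm <- band_connectivity(tf, b, aggregate = "mean")
    expect_lt(mean(abs(cm$values[upper.tri(cm$values)])), 0.05)
  }
})
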