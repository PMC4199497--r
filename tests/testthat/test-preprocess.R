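make_cont <- function(x, fs = 250, nch = 1) {
  eeg_recording(matrix(rep(x, each = nch), nrow = nch), fs)
}

test_that("band-pass keeps the passband and removes the stopband", {
  fs <- 250
  tt <- (0:(fs * 40 - 1)) / fs
  tone10 <- make_cont(sin(2 * pi * 10 * tt), fs)
  out <- bandpass(tone10, 0.5, 45)
  mid <- (fs * 10):(fs * 30)
  ratio <- stats::sd(out$data[1, mid]) / stats::sd(tone10$data[1, mid])
  expect_gt(ratio, 0.99)

  tone60 <- make_cont(sin(2 * pi * 60 * tt), fs)
  out60 <- bandpass(tone60, 0.5, 45)
  expect_lt(stats::sd(out60$data[1, mid]) / stats::sd(tone60$data[1, mid]),
            0.05)

  set.seed(1)
  wn <- make_cont(rnorm(fs * 40), fs)
  outw <- bandpass(wn, 0.5, 45)
  expect_lt(stats::var(outw$data[1, ]), stats::var(wn$data[1, ]))
})

test_that("band-pass rejects too-short recordings and bad edges", {
  short <- make_cont(rnorm(250 * 2))
  expect_error(bandpass(short, 0.5, 45), "3 cycles")
  ok <- make_cont(rnorm(250 * 20))
  expect_error(bandpass(ok, 45, 0.5), "lo < hi")
  expect_error(bandpass(ok, 1, 130), "Nyquist")
})

test_that("epoching uses exactly the first span and zeroes epoch means", {
  rec <- make_cont(rep(3.7, 250 * 600))
  ep <- epoch_and_baseline(rec, 10, 60)
  expect_equal(dim(ep$data), c(1, 60, 2500))
  expect_true(all(ep$data == 0))        # constant offset removed exactly

  set.seed(2)
  rec2 <- eeg_recording(matrix(rnorm(3 * 250 * 70), nrow = 3), 250)
  ep2 <- epoch_and_baseline(rec2, 10, 6)
  mu <- apply(ep2$data, c(1, 2), mean)
  expect_lt(max(abs(mu)), 1e-10)
  expect_error(epoch_and_baseline(rec2, 10, 8), "have")
})

test_that("variance rejection flags a gross-variance channel at z = 3", {
  set.seed(3)
  nch <- 12; nep <- 10
  d <- array(rnorm(nch * nep * 2000), dim = c(nch, nep, 2000))
  d[5, , ] <- d[5, , ] * 10          # 100x variance
  rec <- eeg_recording(d, 50)
  out <- reject_by_variance(rec, z_channel = 3, z_epoch = 5)
  expect_equal(out$report$rejected_channels, "E5")
  # brute-force the score: robust z of per-channel log mean variance
  v <- matrix(0, nch, nep)
  for (i in seq_len(nch)) for (e in seq_len(nep)) v[i, e] <- var(d[i, e, ])
  lv <- log(rowMeans(v))
  z <- (lv - median(lv)) / mad(lv)
  expect_equal(unname(out$report$channel_z), z, tolerance = 1e-12)
  expect_true(z[5] > 3)
})

test_that("homogeneous recordings yield no rejections at z = 5", {
  set.seed(4)
  rec <- eeg_recording(array(rnorm(6 * 8 * 300), dim = c(6, 8, 300)), 50)
  out <- reject_by_variance(rec, z_channel = 5, z_epoch = 5)
  expect_length(out$report$rejected_channels, 0)
  expect_length(out$report$rejected_epochs, 0)
  expect_equal(dim(out$recording$data), dim(rec$data))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(5)
  rec <- eeg_recording(array(rnorm(4 * 3 * 100), dim = c(4, 3, 100)), 50)
  ref <- average_reference(rec)
  expect_lt(max(abs(colMeans(ref$data, dims = 1))), 1e-10)
  ref2 <- average_reference(ref)
  expect_equal(ref2$data, ref$data, tolerance = 1e-12)

  two <- eeg_recording(array(rep(rnorm(100), each = 2), dim = c(2, 1, 100)), 50)
  z <- average_reference(two)
  expect_lt(max(abs(z$data)), 1e-12)   # identical channels cancel
})

test_that("average reference and baseline correction commute", {
  set.seed(6)
  cont <- eeg_recording(matrix(rnorm(5 * 250 * 30), nrow = 5), 250)
  a <- average_reference(epoch_and_baseline(cont, 10, 3))
  b_ep <- epoch_and_baseline(cont, 10, 3)
  b <- b_ep
  mu <- colMeans(b$data, dims = 1)
  b$data <- b$data - rep(mu, each = 5)              # reference first
  mu2 <- rowMeans(b$data, dims = 2)
  b$data <- b$data - as.vector(mu2)                 # then baseline
  expect_lt(max(abs(a$data - b$data)), 1e-9)
})

test_that("interpolated channels are weighted neighbour averages", {
  mont <- generate_montage(12, seed = 7)
  set.seed(7)
  rec <- eeg_recording(array(rnorm(12 * 2 * 100), dim = c(12, 2, 100)), 50,
                       mont$labels)
  out <- interpolate_channels(rec, mont, "E3", k = 4)
  expect_equal(dim(out$data), dim(rec$data))
  good <- setdiff(mont$labels, "E3")
  d <- mont$distances["E3", good]
  nb <- good[order(d)][1:4]
  w <- 1 / d[nb]; w <- w / sum(w)
  manual <- 0
  for (q in 1:4) manual <- manual + w[q] * rec$data[match(nb[q], rec$labels), , ]
  expect_equal(out$data[3, , ], manual, tolerance = 1e-12)
})

test_that("EOG variability is normalised, stationary-flat, and flags bursts", {
  fs <- 100
  n <- fs * 60
  set.seed(8)
  mk <- function(ch25, ch127, ch8, ch126) {
    dat <- rbind(ch25, ch127, ch8, ch126)
    eeg_recording(dat, fs, c("25", "127", "8", "126"))
  }
  stat <- mk(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  tc <- eog_variability(stat)
  expect_equal(mean(tc$values), 1, tolerance = 1e-10)
  expect_lt(abs(diff(tc$halves_means)), 0.1)

  tt <- (0:(n - 1)) / fs
  burst <- sin(2 * pi * 2 * tt) * (tt < 30) * 5
  bursty <- mk(burst + rnorm(n, sd = 0.1), rnorm(n, sd = 0.1),
               burst + rnorm(n, sd = 0.1), rnorm(n, sd = 0.1))
  tb <- eog_variability(bursty)
  expect_gt(tb$halves_means[1], tb$halves_means[2])

  silent <- mk(numeric(n), numeric(n), numeric(n), numeric(n))
  ts_ <- eog_variability(silent)
  expect_true(ts_$degenerate)
  expect_true(all(ts_$values == 0))

  expect_error(eog_variability(stat, left_pair = c("25", "999")), "999")
})
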