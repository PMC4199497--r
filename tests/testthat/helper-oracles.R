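# Independent brute-force oracles. Every function here is a deliberately
# naive transcription of the defining formula (explicit loops, Floyd-
# Warshall), kept free of any code shared with the package internals.

oracle_dwpli <- function(x) {
  # literal transcription of the debiased weighted PLI-square estimator
  imx <- numeric(length(x))
  for (e in seq_along(x)) imx[e] <- Im(x[e])
  sum_im <- 0; sum_sq <- 0; sum_abs <- 0
  for (e in seq_along(imx)) {
    sum_im <- sum_im + imx[e]
    sum_sq <- sum_sq + imx[e]^2
    sum_abs <- sum_abs + abs(imx[e])
  }
  denom <- sum_abs^2 - sum_sq
  if (denom <= 0) return(0)
  (sum_im^2 - sum_sq) / denom
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  if (n < 3) return(0)
  Wn <- if (max(W) > 0) W / max(W) else W
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0
    for (j in seq_len(n)) if (j != i && Wn[i, j] > 0) k <- k + 1
    if (k < 2) { ci[i] <- 0; next }
    tri <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tri <- tri + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    ci[i] <- tri / (k * (k - 1))
  }
  mean(ci)
}

oracle_distance_matrix <- function(W) {
  # Floyd-Warshall on lengths 1/normalised weight
  n <- nrow(W)
  Wn <- if (max(W) > 0) W / max(W) else W
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && Wn[i, j] > 0) D[i, j] <- 1 / Wn[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_path_length <- function(W) {
  D <- oracle_distance_matrix(W)
  vals <- c()
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D)))
    if (i != j && is.finite(D[i, j])) vals <- c(vals, D[i, j])
  mean(vals)
}

oracle_efficiency <- function(W) {
  D <- oracle_distance_matrix(W)
  n <- nrow(D)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) acc <- acc + 1 / D[i, j]
  acc / (n * (n - 1))
}

oracle_participation <- function(W, mem) {
  n <- nrow(W)
  p <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(W[i, ])
    if (ki == 0) { p[i] <- 0; next }
    s <- 0
    for (m in unique(mem)) {
      kim <- 0
      for (j in seq_len(n)) if (mem[j] == m) kim <- kim + W[i, j]
      s <- s + (kim / ki)^2
    }
    p[i] <- 1 - s
  }
  p
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0
  for (x in ua) { px <- sum(a == x) / n; ha <- ha - px * log(px) }
  hb <- 0
  for (y in ub) { py <- sum(b == y) / n; hb <- hb - py * log(py) }
  if (ha + hb == 0) return(1)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  2 * mi / (ha + hb)
}

oracle_modular_span <- function(W, mem, D, module) {
  nodes <- which(mem == module)
  if (length(nodes) < 2) return(NULL)
  s <- 0
  for (ii in seq_along(nodes)) for (jj in seq_along(nodes)) {
    if (jj <= ii) next
    i <- nodes[ii]; j <- nodes[jj]
    if (W[i, j] > 0) s <- s + W[i, j] * D[i, j]
  }
  s / length(nodes)
}

# random symmetric weighted test graph (connected-ish, weights in (0, 1])
random_weighted_graph <- function(n, density = 0.4, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- sample(ut, max(1, round(density * length(ut))))
  W[on] <- runif(length(on), 0.05, 1)
  W + t(W)
}

# two-channel recording holding pure tones (equal per channel)
tone_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 250,
                           n_epochs = 4, epoch_length = 10, n_channels = 1,
                           phase = 0) {
  samp <- round(epoch_length * fs)
  tt <- (seq_len(samp) - 1) / fs
  x <- rowSums(sapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * tt + phase)))
  dat <- array(rep(x, each = n_channels * n_epochs),
               dim = c(n_channels, n_epochs, samp))
  for (e in seq_len(n_epochs)) for (ch in seq_len(n_channels))
    dat[ch, e, ] <- x
  eeg_recording(dat, fs, paste0("T", seq_len(n_channels)))
}
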