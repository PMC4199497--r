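test_that("proportional thresholding keeps the strongest edges with weights", {
  set.seed(41)
  m <- random_weighted_graph(8, density = 1, seed = 41)
  g <- threshold_proportional(m, 1)
  expect_equal(unname(g$adjacency), unname(m))

  # 4-node hand case: 6 weights, density 0.5 keeps the top 3
  m4 <- matrix(0, 4, 4)
  m4[upper.tri(m4)] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  m4 <- m4 + t(m4)
  g4 <- threshold_proportional(m4, 0.5)
  expect_equal(sort(g4$adjacency[upper.tri(g4$adjacency)], decreasing = TRUE)[1:3],
               c(0.9, 0.8, 0.7))
  expect_equal(g4$retained_edges, 3)

  # N = 91 at 10%: round-half-up of 409.5 -> 410
  m91 <- random_weighted_graph(91, density = 1, seed = 42)
  expect_equal(threshold_proportional(m91, 0.10)$retained_edges, 410)
  expect_error(threshold_proportional(m4, 0), "density")
})

test_that("ties at the cutoff break deterministically", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(1, 0.5, 0.5, 0.5, 0.5, 0.2)
  m <- m + t(m)
  g1 <- threshold_proportional(m, 0.5)
  g2 <- threshold_proportional(m, 0.5)
  expect_identical(g1$adjacency, g2$adjacency)
  expect_equal(g1$retained_edges, 3)
})

test_that("the density sweep yields 17 nested graphs", {
  m <- random_weighted_graph(30, density = 1, seed = 43)
  sweep <- density_sweep(m)
  expect_length(sweep, 17)
  edges <- vapply(sweep, function(g) g$retained_edges, numeric(1))
  expect_true(all(diff(edges) <= 0))
  for (i in 2:17) {
    sup <- sweep[[i - 1]]$adjacency > 0
    sub <- sweep[[i]]$adjacency > 0
    expect_true(all(sup[sub]))          # smaller density edge set is contained
  }
})

test_that("clustering matches hand cases and the brute-force oracle", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(clustering_coefficient(k5), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(star), 0)
  set.seed(44)
  for (s in 1:5) {
    W <- random_weighted_graph(10, density = 0.5, seed = 100 + s)
    expect_equal(clustering_coefficient(W), oracle_clustering(W),
                 tolerance = 1e-12)
  }
})

test_that("path length and efficiency match hand computations", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(characteristic_path_length(tri), 1)
  expect_equal(global_efficiency(tri), 1)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)

  dyads <- matrix(0, 4, 4); dyads[1, 2] <- dyads[3, 4] <- 1
  dyads <- dyads + t(dyads)
  expect_equal(characteristic_path_length(dyads), 1)
  expect_equal(global_efficiency(dyads), 1 / 3)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "empty")
})

test_that("Louvain recovers two cliques with Q = 0.5 and is deterministic", {
  two <- matrix(0, 6, 6)
  two[1:3, 1:3] <- 1; two[4:6, 4:6] <- 1; diag(two) <- 0
  lv <- louvain_partitions(two, n_reps = 10, seed = 5)
  expect_true(all(lv$q == 0.5))
  for (r in 1:10) {
    expect_equal(length(unique(lv$partitions[, r])), 2)
    expect_equal(length(unique(lv$partitions[1:3, r])), 1)
    expect_equal(length(unique(lv$partitions[4:6, r])), 1)
  }
  lv2 <- louvain_partitions(two, n_reps = 10, seed = 5)
  expect_identical(lv$partitions, lv2$partitions)

  empty <- louvain_partitions(matrix(0, 4, 4), n_reps = 10, seed = 5)
  expect_equal(empty$mean_q, 0)
  expect_equal(unique(as.vector(empty$partitions)), 1L)
})

test_that("participation coefficients match examples and the oracle", {
  two <- matrix(0, 6, 6)
  two[1:3, 1:3] <- 1; two[4:6, 4:6] <- 1; diag(two) <- 0
  mem <- c(1, 1, 1, 2, 2, 2)
  expect_equal(participation_coefficient(two, mem), rep(0, 6))
  expect_equal(participation_sd(two, mem), 0)

  # node 1 split equally between two modules -> P = 0.5
  w <- matrix(0, 3, 3); w[1, 2] <- w[1, 3] <- 1; w <- w + t(w)
  expect_equal(participation_coefficient(w, c(1, 1, 2))[1], 0.5)

  set.seed(45)
  for (s in 1:5) {
    W <- random_weighted_graph(12, density = 0.4, seed = 200 + s)
    mem <- sample(1:3, 12, TRUE)
    expect_equal(participation_coefficient(W, mem),
                 oracle_participation(W, mem), tolerance = 1e-12)
  }
})

test_that("NMI obeys its conventions and stays low for unrelated partitions", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(2, 2, 3, 3, 1, 1)), 1)     # same up to relabelling
  expect_equal(nmi(rep(1, 6), rep(1, 6)), 1)       # both single-module
  expect_equal(nmi(rep(1, 6), a), 0)               # one side uninformative
  set.seed(46)
  sym <- replicate(50, {
    x <- sample(1:4, 91, TRUE); y <- sample(1:4, 91, TRUE)
    c(nmi(x, y), nmi(y, x))
  })
  expect_equal(sym[1, ], sym[2, ], tolerance = 1e-12)
  expect_lt(mean(sym[1, ]), 0.15)
})

test_that("modular span matches its defining hand computations", {
  mont2 <- montage(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)))
  w2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ms <- modular_span(w2, c(1, 1), mont2)
  expect_equal(ms$largest_module_span, 0.5)

  # 3-node module with edges (w, d) = (0.5, 0.2), (0.5, 0.2), (1.0, 0.4)
  pos <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(0.4, 0, 0), c(1, 0, 0))
  mont4 <- montage(c("a", "b", "c", "d"), pos)   # normalised d: 0.2, 0.2, 0.4
  w4 <- matrix(0, 4, 4, dimnames = list(mont4$labels, mont4$labels))
  w4["a", "b"] <- w4["b", "a"] <- 0.5
  w4["b", "c"] <- w4["c", "b"] <- 0.5
  w4["a", "c"] <- w4["c", "a"] <- 1.0
  ms4 <- modular_span(w4, c(1, 1, 1, 2), mont4)
  expect_equal(ms4$largest_module_span, 0.2)      # 0.6 / 3
  # degenerate single-node module excluded
  expect_equal(ms4$spans$module, 1)

  dbl <- modular_span(2 * w4, c(1, 1, 1, 2), mont4)
  expect_equal(dbl$largest_module_span, 0.4)      # linear in the weights
})

test_that("modular span oracle agreement on random partitions", {
  mont <- generate_montage(12, seed = 47)
  set.seed(47)
  for (s in 1:5) {
    W <- random_weighted_graph(12, density = 0.4, seed = 300 + s)
    dimnames(W) <- list(mont$labels, mont$labels)
    mem <- sample(1:3, 12, TRUE)
    ms <- modular_span(W, mem, mont)
    for (i in seq_len(nrow(ms$spans))) {
      o <- oracle_modular_span(W, mem, mont$distances, ms$spans$module[i])
      expect_equal(ms$spans$span[i], o, tolerance = 1e-12)
    }
  }
})

test_that("subject-level metrics are deterministic and density-averaged", {
  mont <- generate_montage(20, seed = 48)
  W <- random_weighted_graph(20, density = 1, seed = 48)
  dimnames(W) <- list(mont$labels, mont$labels)
  r1 <- metrics_for_subject(W, mont, n_reps = 8, seed = 9)
  r2 <- metrics_for_subject(W, mont, n_reps = 8, seed = 9)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$partitions, r2$partitions)
  expect_equal(nrow(r1$per_density), 17)
  expect_equal(unname(unlist(r1$summary)),
               unname(colMeans(r1$per_density[, -1])), tolerance = 1e-12)

  # constant matrix: surviving weights are untouched and, once max-
  # normalised, every density reduces to the binary graph of the kept edges
  cm <- matrix(0.4, 10, 10); diag(cm) <- 0
  dimnames(cm) <- list(mont$labels[1:10], mont$labels[1:10])
  for (d in c(0.5, 0.2)) {
    gt <- threshold_proportional(cm, d)
    kept <- gt$adjacency[gt$adjacency > 0]
    expect_true(all(kept == 0.4))
    expect_equal(clustering_coefficient(gt),
                 clustering_coefficient((gt$adjacency > 0) * 1),
                 tolerance = 1e-12)
  }
})

test_that("inter-subject NMI matrices are symmetric with unit diagonal", {
  mont <- generate_montage(15, seed = 49)
  parts <- list()
  set.seed(49)
  for (s in 1:3) {
    W <- random_weighted_graph(15, density = 0.6, seed = 400 + s)
    dimnames(W) <- list(mont$labels, mont$labels)
    parts[[paste0("S", s)]] <- metrics_for_subject(
      W, mont, densities = c(0.4, 0.2), n_reps = 5, seed = s)$partitions
  }
  M <- nmi_matrix(parts)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))
  # identical subjects give NMI exactly 1
  M2 <- nmi_matrix(list(a = parts[[1]], b = parts[[1]]))
  expect_equal(M2["a", "b"], 1)
})
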