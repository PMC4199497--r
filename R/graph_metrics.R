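# Weighted graph metrics on proportionally thresholded connectivity
# matrices: clustering, characteristic path length, global efficiency,
# Louvain modularity with repetition averaging, participation-coefficient
# SD, normalised mutual information between partitions, and the topographic
# modular-span metric.

#' Proportional threshold of a connectivity matrix
#'
#' Keeps the top `round(density * N(N-1)/2)` upper-triangle weights (with
#' their original values - graphs are weighted, not binarised) and zeroes the
#' rest. Ties at the cutoff are broken deterministically by channel-pair
#' lexicographic order.
#'
#' @param m symmetric matrix or `connectivity_matrix`.
#' @param density fraction of strongest possible edges to retain, in (0, 1].
#' @return object of class `thresholded_graph`: `adjacency` (weighted,
#'   symmetric, zero diagonal), `density`, `retained_edges`, `labels`.
#' @export
threshold_proportional <- function(m, density) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  labels <- rownames(v) %||% paste0("E", seq_len(nrow(v)))
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  if (max(abs(v - t(v))) > 1e-10) stop("input matrix must be symmetric")
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[upper.tri(v)]
  k <- round_half_up(density * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, length(w)))]
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  adj[ut[keep, , drop = FALSE]] <- w[keep]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = density,
                 retained_edges = length(keep), labels = labels),
            class = "thresholded_graph")
}

#' Density sweep of thresholded graphs
#'
#' @param m symmetric matrix or `connectivity_matrix`.
#' @param densities vector of densities; the default is the 17-step sweep
#'   from 50% down to 10% in steps of 2.5%.
#' @return list of [threshold_proportional()] graphs (edge sets are nested
#'   along the sweep).
#' @export
density_sweep <- function(m, densities = default_densities()) {
  lapply(densities, function(d) threshold_proportional(m, d))
}

#' @rdname density_sweep
#' @export
default_densities <- function() seq(0.50, 0.10, by = -0.025)

as_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) g$adjacency
  else if (inherits(g, "connectivity_matrix")) g$values
  else as.matrix(g)
}

# per-graph max normalisation used by the weighted metrics
normalize_weights <- function(adj) {
  mx <- max(adj)
  if (mx > 0) adj / mx else adj
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the weighted clustering coefficient in the
#' geometric-mean-of-triangles form, on per-graph max-normalised weights:
#' `C_i = sum_(j,k) (w_ij w_ik w_jk)^(1/3) / (k_i (k_i - 1))` with `k_i` the
#' number of neighbours. Nodes with fewer than 2 neighbours contribute 0.
#'
#' @param g a thresholded graph or weighted adjacency matrix (weights >= 0).
#' @return scalar in [0, 1].
#' @export
clustering_coefficient <- function(g) {
  W <- normalize_weights(as_adjacency(g))
  if (nrow(W) < 3) return(0)
  if (any(W < 0)) stop("clustering_coefficient requires non-negative weights")
  K <- rowSums(W > 0)
  W13 <- W^(1 / 3)
  cyc <- diag(W13 %*% W13 %*% W13)
  denom <- K * (K - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  mean(ci)
}

graph_distances <- function(W) {
  # shortest-path distances with edge length 1/weight (Dijkstra via igraph)
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    return(D)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs, with edge lengths
#' the inverse of max-normalised weights. Disconnected pairs are excluded
#' from the average (their count is reported by [global_efficiency()]'s
#' complement behaviour); an edgeless graph errors.
#'
#' @param g thresholded graph or weighted adjacency matrix.
#' @return scalar L >= 0.
#' @export
characteristic_path_length <- function(g) {
  W <- normalize_weights(as_adjacency(g))
  if (all(W == 0)) stop("characteristic path length undefined on an empty graph")
  D <- graph_distances(W)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over all ordered node pairs;
#' disconnected pairs contribute 0, so fragmentation is handled natively.
#' With max-normalised weights, E lies in [0, 1].
#'
#' @param g thresholded graph or weighted adjacency matrix.
#' @return scalar in [0, 1].
#' @export
global_efficiency <- function(g) {
  W <- normalize_weights(as_adjacency(g))
  if (all(W == 0)) stop("global efficiency undefined on an empty graph")
  D <- graph_distances(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(W) * (nrow(W) - 1))
}

relabel_contiguous <- function(mem) {
  u <- unique(mem)
  match(mem, u)
}

#' Repeated Louvain community detection
#'
#' Runs the Louvain heuristic `n_reps` times, seeding the RNG with a distinct
#' derived seed before each repetition (the heuristic randomises its vertex
#' processing order), so repetitions explore different local optima while
#' staying reproducible. Modularity Q is computed on the weighted adjacency
#' for every repetition; all partitions are retained so that downstream
#' metrics can be averaged per repetition rather than on a single "best"
#' partition.
#'
#' @param g thresholded graph or weighted adjacency matrix.
#' @param n_reps number of repetitions (default 50).
#' @param seed master integer seed.
#' @return list: `partitions` (nodes x n_reps integer matrix, labels
#'   contiguous from 1), `q` (modularity per repetition), `mean_q`.
#' @export
louvain_partitions <- function(g, n_reps = 50, seed = 1) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (all(W == 0)) {
    return(list(partitions = matrix(1L, n, 1), q = 0, mean_q = 0))
  }
  gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  seeds <- derive_seeds(seed, n_reps)
  parts <- matrix(0L, n, n_reps)
  q <- numeric(n_reps)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  ew <- igraph::E(gr)$weight
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    cl <- igraph::cluster_louvain(gr)
    parts[, r] <- relabel_contiguous(as.integer(igraph::membership(cl)))
    q[r] <- igraph::modularity(gr, parts[, r], weights = ew)
  }
  list(partitions = parts, q = q, mean_q = mean(q))
}

#' Participation coefficients and their SD
#'
#' For node i with weighted degree `k_i` and within-module degrees `k_im`,
#' `P_i = 1 - sum_m (k_im / k_i)^2`. Isolated nodes get `P_i = 0`. The SD of
#' `P_i` across nodes indexes how strongly a network relies on a subset of
#' inter-modular hub nodes.
#'
#' @param g thresholded graph or weighted adjacency matrix.
#' @param membership integer module assignment covering all nodes.
#' @return `participation_coefficient`: numeric vector of `P_i`;
#'   `participation_sd`: their standard deviation.
#' @export
participation_coefficient <- function(g, membership) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (length(membership) != n) stop("partition must cover all nodes")
  k <- rowSums(W)
  mods <- sort(unique(membership))
  ind <- outer(membership, mods, "==") * 1
  km <- W %*% ind
  frac <- km / ifelse(k > 0, k, 1)
  p <- unname(1 - rowSums(frac^2))
  p[k == 0] <- 0
  p
}

#' @rdname participation_coefficient
#' @export
participation_sd <- function(g, membership) {
  stats::sd(participation_coefficient(g, membership))
}

# fast path used in inner loops: contingency via tabulate
nmi_fast <- function(a, b) {
  n <- length(a)
  ka <- max(a); kb <- max(b)
  tab <- tabulate((a - 1L) * kb + b, ka * kb)
  tab <- tab[tab > 0] / n
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)       # both single-module: identical partitions
  idx <- which(tabulate((a - 1L) * kb + b, ka * kb) > 0)
  i <- (idx - 1L) %/% kb + 1L
  j <- (idx - 1L) %% kb + 1L
  mi <- sum(tab * log(tab / (pa[i] * pb[j])))
  min(max(2 * mi / (ha + hb), 0), 1)
}

#' Normalised mutual information between two partitions
#'
#' Mutual information of the module-label distributions normalised by the
#' arithmetic mean of their entropies (so NMI = 2 MI / (H_a + H_b)),
#' symmetric in its arguments and in [0, 1]. When both partitions are a
#' single module (both entropies 0) they are identical and NMI is 1; when
#' exactly one has zero entropy, MI is 0 and so is NMI.
#'
#' @param a,b integer vectors assigning each node to a module (same node
#'   set; labels need not match).
#' @return scalar in [0, 1].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same node set")
  a <- relabel_contiguous(as.integer(a))
  b <- relabel_contiguous(as.integer(b))
  nmi_fast(a, b)
}

#' Topographic modular span
#'
#' The modular span of a non-degenerate module M (>= 2 nodes) is the
#' weighted sum of the topographic lengths of the retained intra-modular
#' edges, scaled by the module size:
#' `S(M) = (1/n_M) * sum_(i<j in M, edge present) w_ij * d_ij`,
#' where `d_ij` is the normalised scalp distance (1 for the most distant
#' electrode pair) - dimensionless, linear in the edge weights. Single-node
#' modules are excluded. The largest module is selected by node count, ties
#' broken by larger total intra-modular weight.
#'
#' @param g thresholded graph (or weighted adjacency) whose rows match the
#'   montage channel order.
#' @param membership integer module assignment.
#' @param mont the [montage()] providing `d_ij`.
#' @param size_divisor function of the module node count used as the scale
#'   divisor (default `identity`, i.e. divide by `n_M`).
#' @return list: `spans` (data.frame module, n_nodes, span),
#'   `largest_module_span` (span of the largest non-degenerate module; 0
#'   when none exists).
#' @export
modular_span <- function(g, membership, mont, size_divisor = identity) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (length(membership) != n) stop("partition must cover all nodes")
  D <- mont$distances
  if (!all(rownames(W) %in% rownames(D)))
    stop("graph channels missing from montage")
  D <- D[rownames(W), rownames(W)]
  mods <- sort(unique(membership))
  rows <- lapply(mods, function(m) {
    nodes <- which(membership == m)
    if (length(nodes) < 2) return(NULL)
    sub <- W[nodes, nodes, drop = FALSE] * D[nodes, nodes, drop = FALSE]
    data.frame(module = m, n_nodes = length(nodes),
               intra_weight = sum(W[nodes, nodes]) / 2,
               span = sum(sub[upper.tri(sub)]) / size_divisor(length(nodes)))
  })
  spans <- do.call(rbind, rows)
  if (is.null(spans) || !nrow(spans))
    return(list(spans = data.frame(module = integer(), n_nodes = integer(),
                                   intra_weight = numeric(), span = numeric()),
                largest_module_span = 0))
  ord <- order(-spans$n_nodes, -spans$intra_weight)
  list(spans = spans[, c("module", "n_nodes", "span")],
       largest_module_span = spans$span[ord[1]])
}

# fast path for the repetition loop: span of the largest module (node count,
# ties by intra weight) without data.frame overhead. WD = W * D precomputed.
span_largest_fast <- function(WD, W, membership) {
  best_n <- 0L; best_w <- -Inf; best_span <- 0
  for (m in unique(membership)) {
    nodes <- which(membership == m)
    nm <- length(nodes)
    if (nm < 2) next
    iw <- sum(W[nodes, nodes]) / 2
    if (nm > best_n || (nm == best_n && iw > best_w)) {
      best_n <- nm; best_w <- iw
      best_span <- sum(WD[nodes, nodes]) / 2 / nm
    }
  }
  best_span
}

#' All graph metrics for one subject's band matrix
#'
#' Thresholds the connectivity matrix at every density of the sweep and
#' computes: weighted clustering C, characteristic path length L, global
#' efficiency E (partition-free, once per density), and - per Louvain
#' repetition, then averaged over the repetitions - modularity Q,
#' participation-coefficient SD, and the modular span of the largest module.
#' Everything is finally averaged across densities with equal weight.
#'
#' @param m `connectivity_matrix` or symmetric matrix.
#' @param mont the [montage()].
#' @param densities density sweep (default [default_densities()]).
#' @param n_reps Louvain repetitions per density (default 50).
#' @param seed master seed (per-density, per-repetition seeds are derived).
#' @param keep_partitions retain all partitions (needed for inter-subject
#'   NMI)? Default TRUE.
#' @return object of class `graph_metrics_result`: `summary` (one-row
#'   data.frame of density-averaged metrics), `per_density` (data.frame, one
#'   row per density), `partitions` (nodes x n_reps x n_densities integer
#'   array or NULL), `fragmented` (densities at which the graph was
#'   disconnected).
#' @export
metrics_for_subject <- function(m, mont, densities = default_densities(),
                                n_reps = 50, seed = 1,
                                keep_partitions = TRUE) {
  v <- as_adjacency(m)
  n <- nrow(v)
  dens_seeds <- derive_seeds(seed, length(densities))
  per <- vector("list", length(densities))
  parts <- if (keep_partitions)
    array(0L, dim = c(n, n_reps, length(densities))) else NULL
  fragmented <- numeric(0)
  for (di in seq_along(densities)) {
    g <- threshold_proportional(v, densities[di])
    W <- g$adjacency
    Wn <- normalize_weights(W)
    D <- graph_distances(Wn)
    off <- D[row(D) != col(D)]
    if (any(!is.finite(off))) fragmented <- c(fragmented, densities[di])
    L <- mean(off[is.finite(off)])
    inv <- 1 / D; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    E <- sum(inv) / (n * (n - 1))
    C <- clustering_coefficient(g)
    lv <- louvain_partitions(g, n_reps = n_reps, seed = dens_seeds[di])
    nr <- ncol(lv$partitions)
    Dm <- mont$distances[g$labels, g$labels]
    WD <- W * Dm
    psd <- numeric(nr); span <- numeric(nr)
    for (r in seq_len(nr)) {
      mem <- lv$partitions[, r]
      psd[r] <- participation_sd(W, mem)
      span[r] <- span_largest_fast(WD, W, mem)
    }
    if (keep_partitions) {
      if (nr < n_reps)  # degenerate all-zero graph: replicate trivial partition
        lv$partitions <- matrix(lv$partitions[, 1], n, n_reps)
      parts[, , di] <- lv$partitions
    }
    per[[di]] <- data.frame(
      density = densities[di], clustering = C, path_length = L,
      efficiency = E, modularity = mean(lv$q),
      participation_sd = mean(psd), modular_span = mean(span))
  }
  per <- do.call(rbind, per)
  summary <- as.data.frame(t(colMeans(per[, -1])))
  structure(list(summary = summary, per_density = per, partitions = parts,
                 fragmented = fragmented, densities = densities,
                 n_reps = n_reps, seed = seed),
            class = "graph_metrics_result")
}

#' @export
print.graph_metrics_result <- function(x, ...) {
  cat("<graph_metrics_result> density-averaged metrics:\n")
  print(round(x$summary, 4))
  if (length(x$fragmented))
    cat("  fragmented at densities:", paste(x$fragmented, collapse = ", "), "\n")
  invisible(x)
}

#' Inter-subject NMI matrix
#'
#' For every pair of subjects, NMI is computed between their partitions at
#' matched (density, repetition) indices and averaged, giving a symmetric
#' subjects x subjects similarity matrix with unit diagonal.
#'
#' @param partition_list named list, one nodes x n_reps x n_densities
#'   integer array per subject (as returned in
#'   `metrics_for_subject()$partitions`).
#' @return symmetric matrix of mean NMI values, unit diagonal.
#' @export
nmi_matrix <- function(partition_list) {
  ns <- length(partition_list)
  if (ns < 2) stop("need >= 2 subjects")
  dims <- dim(partition_list[[1]])
  out <- diag(1, ns)
  ids <- names(partition_list) %||% paste0("S", seq_len(ns))
  dimnames(out) <- list(ids, ids)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    pi_ <- partition_list[[i]]; pj <- partition_list[[j]]
    acc <- 0
    for (d in seq_len(dims[3])) for (r in seq_len(dims[2]))
      acc <- acc + nmi_fast(pi_[, r, d], pj[, r, d])
    out[i, j] <- out[j, i] <- acc / (dims[2] * dims[3])
  }
  out
}
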