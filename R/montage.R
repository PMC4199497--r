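#' Construct a montage from electrode coordinates
#'
#' A montage holds channel labels, 3D positions and the matrix of pairwise
#' Euclidean distances normalised so that the most distant electrode pair is
#' exactly 1 (d_ij is therefore dimensionless and any Cartesian input unit is
#' accepted).
#'
#' @param labels character vector of unique channel labels.
#' @param positions numeric matrix, one row per label, 3 columns (x, y, z).
#' @return object of class `montage` with elements `labels`, `positions`,
#'   `distances`.
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  if (length(labels) < 2) stop("a montage needs at least 2 channels")
  if (nrow(positions) != length(labels) || ncol(positions) != 3)
    stop("positions must be a length(labels) x 3 matrix")
  if (!all(is.finite(positions))) stop("non-finite electrode coordinates")
  d <- as.matrix(stats::dist(positions))
  mx <- max(d)
  if (mx <= 0) stop("all electrodes are co-located; distances undefined")
  d <- d / mx
  dimnames(d) <- list(labels, labels)
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions, distances = d),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, normalised max distance %.3f\n",
              length(x$labels), max(x$distances)))
  invisible(x)
}

#' Load a montage from a plain-text coordinates file
#'
#' Expected format: one electrode per line, whitespace-delimited
#' `label x y z`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [montage()].
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 4)
    stop("montage file must have 4 columns: label x y z")
  montage(tab[[1]], as.matrix(tab[, 2:4]))
}

#' Write a montage to the plain-text coordinates format
#' @param m a [montage()].
#' @param path output file path.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  lines <- sprintf("%s %.10g %.10g %.10g", m$labels,
                   m$positions[, 1], m$positions[, 2], m$positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Generate a quasi-uniform scalp montage
#'
#' Places `n_channels` electrodes quasi-uniformly on a spherical cap covering
#' the upper 60% of a unit sphere (a stylised scalp), using a Fibonacci
#' lattice with a seeded random azimuthal rotation. Deterministic given the
#' seed.
#'
#' @param n_channels number of electrodes (>= 2).
#' @param seed integer seed.
#' @return a [montage()] with labels `E1..En`.
#' @export
generate_montage <- function(n_channels = 91, seed = 1) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  rot <- runif(1, 0, 2 * pi)
  # cap covering 60% of the sphere surface: z in (1 - 2*0.6, 1]
  z0 <- 1 - 2 * 0.6
  k <- seq_len(n_channels)
  z <- 1 - (k - 0.5) / n_channels * (1 - z0)
  golden <- pi * (3 - sqrt(5))
  th <- rot + golden * (k - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  montage(paste0("E", k), pos)
}
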