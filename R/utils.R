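#' @importFrom stats fft rnorm runif sd var qt pt cor quantile kmeans t.test p.adjust median
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream of child seeds from a master seed
#'
#' All randomized operations in the package take an explicit integer seed;
#' multi-part operations (cohorts, Louvain repetitions) derive one child seed
#' per part from the master seed so that parts are independent yet
#' reproducible. Child seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Structured log line to stderr
#'
#' @param ... message parts, pasted together.
#' @param verbose emit the line? Default taken from option
#'   `modspan.verbose` (FALSE if unset).
#' @export
ms_log <- function(..., verbose = getOption("modspan.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[modspan] ", paste0(...))
  invisible(NULL)
}

round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
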