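#' True parameters of the three-component benchmark design
#'
#' The `k = 3` benchmark mixture: the first two coordinates come from
#' bivariate normals with means `(0,0)`, `(2,6)` and `(6,0)` and diagonal
#' covariances `diag(2,2)`, `diag(3,1)` and `diag(1,2)`; a third (and,
#' optionally, a fourth) independent noise coordinate is `N(0, 100)` in
#' every component. Component weights are proportional to the design sizes
#' 50, 20, 20.
#'
#' @param higher_p Add the fourth `N(0, 100)` noise coordinate.
#' @return A [mixture_params()] object.
#' @export
design_a_params <- function(higher_p = FALSE) {
  p_extra <- if (higher_p) 2L else 1L
  means2 <- rbind(c(0, 0), c(2, 6), c(6, 0))
  covs2 <- list(diag(c(2, 2)), diag(c(3, 1)), diag(c(1, 2)))
  means <- cbind(means2, matrix(0, 3, p_extra))
  sigmas <- lapply(covs2, function(S) {
    M <- diag(rep(100, 2 + p_extra))
    M[1:2, 1:2] <- S
    M
  })
  colnames(means) <- paste0("x", seq_len(2 + p_extra))
  mixture_params(weights = c(50, 20, 20) / 90, means = means, sigmas = sigmas)
}

#' Simulate the three-component benchmark design
#'
#' Draws a sample from the design of [design_a_params()] with component
#' sizes 50, 20, 20 (doubled to 100, 40, 40 when `higher_n = TRUE`).
#'
#' @param higher_p Add a fourth `N(0, 100)` noise coordinate.
#' @param higher_n Double the component sizes.
#' @param seed Optional integer seed.
#' @return A tibble with the feature columns and an integer `component`
#'   column holding the true labels; the true parameters are attached as
#'   attribute `"params"` (see [true_params()]).
#' @examples
#' d <- sim_design_a(seed = 1)
#' nrow(d) # 90
#' @export
sim_design_a <- function(higher_p = FALSE, higher_n = FALSE, seed = NULL) {
  params <- design_a_params(higher_p)
  sizes <- c(50, 20, 20) * (1 + higher_n)
  sample_mixture(params, sizes = sizes, seed = seed)
}

#' True parameters of the six-component benchmark design
#'
#' Six spherical bivariate components sharing the same scatter, with means
#' `(-4.5, 3.6)`, `(0.40, 3.6)`, `(-4.4, -1)`, `(9.2, -1)`, `(0.4, -1)`
#' and `(9.2, 3.6)` and sizes 23, 36, 93, 38, 123, 12, plus an independent
#' `N(0, 100)` noise coordinate that elongates every cluster. The in-plane
#' variance is 1 (the printed means are several units apart, consistent
#' with visibly separated spherical clusters).
#'
#' @return A [mixture_params()] object.
#' @export
design_b_params <- function() {
  means2 <- rbind(
    c(-4.5, 3.6), c(0.40, 3.6), c(-4.4, -1),
    c(9.2, -1), c(0.4, -1), c(9.2, 3.6)
  )
  sizes <- c(23, 36, 93, 38, 123, 12)
  means <- cbind(means2, 0)
  colnames(means) <- paste0("x", 1:3)
  sigmas <- rep(list(diag(c(1, 1, 100))), 6)
  mixture_params(weights = sizes / sum(sizes), means = means, sigmas = sigmas)
}

#' Simulate the six-component benchmark design
#'
#' Draws the fixed-size sample (`n = 325`) from [design_b_params()].
#'
#' @inheritParams sim_design_a
#' @return A tibble as in [sim_design_a()].
#' @export
sim_design_b <- function(seed = NULL) {
  sample_mixture(design_b_params(), sizes = c(23, 36, 93, 38, 123, 12),
                 seed = seed)
}

#' Sample observations from a Gaussian mixture
#'
#' Draws observations from each component of a mixture, either with exact
#' per-component counts (`sizes`) or with multinomially allocated counts
#' for a total of `n` draws.
#'
#' @param params A [mixture_params()] object.
#' @param n Total number of draws (component counts multinomial in the
#'   weights); ignored when `sizes` is given.
#' @param sizes Exact per-component counts (length `k`).
#' @param seed Optional integer seed.
#' @return A tibble with the feature columns and an integer `component`
#'   column; the generating parameters are attached as attribute
#'   `"params"`.
#' @export
sample_mixture <- function(params, n = NULL, sizes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- params$k
  p <- params$p
  if (is.null(sizes)) {
    stopifnot(!is.null(n), n >= 1)
    sizes <- as.integer(stats::rmultinom(1, n, params$weights))
  }
  stopifnot(length(sizes) == k, sum(sizes) >= 1)
  blocks <- lapply(seq_len(k), function(j) {
    nj <- sizes[j]
    if (nj == 0) return(matrix(0, 0, p))
    L <- chol(params$sigmas[[j]]) # upper triangular
    Z <- matrix(rnorm(nj * p), nj, p)
    sweep(Z %*% L, 2L, params$means[j, ], `+`)
  })
  X <- do.call(rbind, blocks)
  colnames(X) <- colnames(params$means) %||% paste0("x", seq_len(p))
  out <- tibble::as_tibble(as.data.frame(X))
  out$component <- rep(seq_len(k), sizes)
  attr(out, "params") <- params
  out
}

#' True generating parameters attached to a simulated dataset
#'
#' @param data A tibble produced by one of the simulation functions.
#' @return The [mixture_params()] attribute, or `NULL`.
#' @export
true_params <- function(data) attr(data, "params", exact = TRUE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelled partitions of the same
#' observations, computed from the contingency table by pair counting.
#' The index is 1 for identical partitions (up to relabelling), has
#' expectation 0 under random labellings, and can be negative. When the
#' chance-correction denominator vanishes (both partitions put everything
#' in one cluster) the index is defined as 1 if the partitions are
#' identical.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same partition
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    return(if (sum_ij == (sum_a + sum_b) / 2) 1 else 0)
  }
  (sum_ij - expected) / denom
}
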