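#' Pairwise overlap of a Gaussian mixture
#'
#' Estimates, by Monte Carlo, the directed misclassification probabilities
#' `w[j|l] = P(pi_l phi(X; mu_l, Sigma_l) < pi_j phi(X; mu_j, Sigma_j))`
#' for `X` drawn from component `l`, and summarises them as the average
#' pairwise overlap: the sum of the two directed probabilities of each
#' pair, averaged over the `k (k - 1) / 2` pairs. This is the quantity the
#' overlap-controlled generator calibrates, and a standard difficulty
#' measure for mixture simulations.
#'
#' @param params A [mixture_params()] object.
#' @param draws Monte-Carlo draws per component (at least 1e4; the
#'   binomial standard error of each directed probability is about
#'   `sqrt(w (1 - w) / draws)`).
#' @param seed Optional integer seed.
#' @return An object of class `parsmix_overlap`: a list with `w` (the
#'   `k x k` matrix of directed probabilities, zero diagonal), `average`
#'   and `draws`.
#' @examples
#' th <- mixture_params(c(.5, .5), rbind(0, 4), list(matrix(1), matrix(1)))
#' pairwise_overlap(th, draws = 2e4, seed = 1)$average # about 2 * pnorm(-2)
#' @export
pairwise_overlap <- function(params, draws = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(draws >= 1e4)
  k <- params$k
  p <- params$p
  sig <- sigma_array(params$sigmas, p)
  w <- matrix(0, k, k)
  for (l in seq_len(k)) {
    L <- chol(params$sigmas[[l]])
    Z <- matrix(rnorm(draws * p), draws, p)
    X <- sweep(Z %*% L, 2L, params$means[l, ], `+`)
    logW <- cpp_log_weights(X, params$weights, params$means, sig)
    for (j in seq_len(k)) {
      if (j != l) w[j, l] <- mean(logW[, j] > logW[, l])
    }
  }
  structure(
    list(w = w, average = sum(w) / (k * (k - 1) / 2), draws = draws),
    class = "parsmix_overlap"
  )
}

#' @export
print.parsmix_overlap <- function(x, ...) {
  cat("<parsmix_overlap> average pairwise overlap:",
      signif(x$average, 4), "(", x$draws, "draws per component )\n")
  invisible(x)
}

#' Random mixture parameters with a prefixed average overlap
#'
#' Generates the parameters of a `k`-component Gaussian mixture whose
#' covariance matrices satisfy a chosen parsimonious constraint pattern
#' and whose average pairwise overlap (see [pairwise_overlap()]) hits a
#' prefixed target. Covariances are built constraint-first: volumes
#' log-uniform within the allowed determinant ratio, shapes drawn at
#' random and then passed through the within/between optimal truncations
#' (so the pattern holds by construction), rotations Haar-uniform (shared
#' or identity as the pattern requires). Component means are drawn
#' uniformly in the unit hypercube and the configuration is scaled about
#' its centroid by a scalar found by bisection until the Monte-Carlo
#' average overlap matches the target; scaling the means leaves the
#' covariance pattern untouched.
#'
#' When a three-letter limit-model code is supplied, the infinite
#' constants of the pattern are replaced by large finite surrogates --
#' 100 for the determinant and within-shape constants, 10 for the
#' between-shape constant -- so the generated matrices vary but remain
#' numerically tame.
#'
#' @param k Number of components (`>= 2`).
#' @param p Data dimension.
#' @param model A three-letter limit-model code (e.g. `"VVV"`, see
#'   [limit_models()]) or a [constraint_spec()] with finite constants.
#' @param overlap Target average pairwise overlap, in `(0, 1)`.
#' @param weights Mixture weights (default equal).
#' @param seed Optional integer seed.
#' @param calib_draws Monte-Carlo draws per component used inside the
#'   bisection (common random numbers across scale evaluations).
#' @param tol Calibration tolerance on the average overlap.
#' @return A [mixture_params()] object whose covariances satisfy the
#'   pattern and whose realised average overlap is within `tol` of
#'   `overlap` (up to Monte-Carlo error).
#' @examples
#' th <- sim_overlap_mixture(3, 2, "VVI", overlap = 0.05, seed = 1,
#'                           calib_draws = 1e4)
#' th$k
#' @export
sim_overlap_mixture <- function(k = 3, p = 2, model = "VVV", overlap = 0.05,
                                weights = rep(1 / k, k), seed = NULL,
                                calib_draws = 5e4, tol = 0.002) {
  stopifnot(k >= 2, p >= 1, overlap > 0, overlap < 1,
            length(weights) == k, all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)

  if (is.character(model)) {
    pat <- limit_models()
    row <- pat[pat$code == model, ]
    if (nrow(row) != 1L) stop("unknown model code: ", model, call. = FALSE)
    finite <- function(v, s) if (is.infinite(v)) s else v
    spec <- constraint_spec(
      finite(row$c_det, 100), finite(row$c_shw, 100),
      min(finite(row$c_shb, 10), shb_bound(finite(row$c_shw, 100), p)),
      row$rot
    )
  } else {
    spec <- spec_effective(model, p)
    if (any(is.infinite(c(spec$c_det, spec$c_shw, spec$c_shb)))) {
      stop("`model` given as a spec must have finite constants", call. = FALSE)
    }
  }

  for (attempt in 1:20) {
    theta <- try(overlap_mixture_once(k, p, spec, overlap, weights,
                                      calib_draws, tol), silent = TRUE)
    if (!inherits(theta, "try-error")) return(theta)
  }
  stop("overlap calibration failed after 20 parameter redraws: ",
       attr(theta, "condition")$message, call. = FALSE)
}

# one attempt: draw a random pattern-conforming parameter set and calibrate
# the mean scale; errors if the drawn configuration cannot reach the target
overlap_mixture_once <- function(k, p, spec, overlap, weights,
                                 calib_draws, tol) {
  # volumes: log-uniform within the allowed determinant ratio
  d <- if (spec$c_det == 1) rep(1, k) else {
    exp(runif(k, 0, log(spec$c_det) / p))
  }
  # shapes: random, then constrained by the truncation operators
  if (spec$c_shw == 1 || p == 1) {
    shape <- matrix(1, p, k)
  } else {
    shape <- matrix(exp(runif(p * k, -log(spec$c_shw) / 2,
                              log(spec$c_shw) / 2)), p, k)
    for (it in 1:50) {
      prev <- shape
      for (j in seq_len(k)) {
        g <- opt_trunc(shape[, j], c = spec$c_shw)
        shape[, j] <- g / exp(mean(log(g)))
      }
      if (spec$rot == "V") shape <- apply(shape, 2L, sort, decreasing = TRUE)
      for (l in seq_len(p)) {
        shape[l, ] <- opt_trunc(shape[l, ], c = spec$c_shb)
      }
      if (max(abs(shape - prev)) < 1e-12) break
    }
    shape <- apply(shape, 2L, function(g) g / exp(mean(log(g))))
    shape <- matrix(shape, p, k)
  }
  # rotations: Haar-uniform, shared or identity per regime
  haar <- function() {
    Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
    Q %*% diag(sign(diag(Q) + (diag(Q) == 0)), p)
  }
  R <- switch(spec$rot,
    I = rep(list(diag(p)), k),
    E = rep(list(haar()), k),
    V = replicate(k, haar(), simplify = FALSE)
  )
  sigmas <- lapply(seq_len(k), function(j) {
    compose_scatter(d[j], shape[, j], R[[j]], tol = 1e-6)
  })

  mu0 <- matrix(runif(k * p), k, p)
  mu0 <- sweep(mu0, 2L, colMeans(mu0))

  # common random numbers: one fixed draw set per component
  Z <- lapply(seq_len(k), function(j) matrix(rnorm(calib_draws * p),
                                             calib_draws, p))
  Ls <- lapply(sigmas, chol)
  sig <- sigma_array(sigmas, p)
  ov_at <- function(s) {
    means <- s * mu0
    tot <- 0
    for (l in seq_len(k)) {
      X <- sweep(Z[[l]] %*% Ls[[l]], 2L, means[l, ], `+`)
      logW <- cpp_log_weights(X, weights, means, sig)
      tot <- tot + sum(colMeans(logW > logW[, l])[-l])
    }
    tot / (k * (k - 1) / 2)
  }

  lo <- 1e-3; hi <- 1
  it <- 0
  while (ov_at(hi) > overlap && it < 60) { hi <- hi * 2; it <- it + 1 }
  it <- 0
  while (ov_at(lo) < overlap && it < 60) { lo <- lo / 2; it <- it + 1 }
  if (ov_at(lo) < overlap || ov_at(hi) > overlap) {
    stop("overlap calibration failed to bracket the target (target = ",
         overlap, ", at lo = ", signif(ov_at(lo), 4), ", at hi = ",
         signif(ov_at(hi), 4), ")", call. = FALSE)
  }
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    o <- ov_at(mid)
    if (abs(o - overlap) <= tol) { lo <- hi <- mid; break }
    if (o > overlap) lo <- mid else hi <- mid
  }
  s <- sqrt(lo * hi)

  means <- s * mu0
  colnames(means) <- paste0("x", seq_len(p))
  out <- mixture_params(weights = weights, means = means, sigmas = sigmas,
                        rot = spec$rot)
  rep_ok <- check_constraints(out, spec, tol = 1e-6)
  if (!rep_ok$satisfied) {
    stop("internal error: generated covariances violate the pattern",
         call. = FALSE)
  }
  out
}
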