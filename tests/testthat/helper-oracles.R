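# Independent oracles and fixture builders used across the suite.

# random symmetric positive-definite matrix
rspd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p, p)
  scale * (crossprod(A) + diag(p) * 0.1)
}

# random valid mixture parameters
rmix <- function(k, p, sep = 4) {
  w <- runif(k, 0.5, 2)
  mixture_params(
    weights = w / sum(w),
    means = matrix(rnorm(k * p, sd = sep), k, p),
    sigmas = replicate(k, rspd(p), simplify = FALSE)
  )
}

# naive multivariate normal density (explicit inverse; independent of the
# Cholesky path used by the package)
dmvn_naive <- function(x, mu, S) {
  p <- length(mu)
  xc <- as.numeric(x - mu)
  (2 * pi)^(-p / 2) * det(S)^(-1 / 2) * exp(-0.5 * sum(xc * solve(S, xc)))
}

# double-loop mixture log-likelihood oracle
loglik_oracle <- function(X, params) {
  X <- as.matrix(X)
  sum(apply(X, 1L, function(x) {
    log(sum(vapply(seq_len(params$k), function(j) {
      params$weights[j] * dmvn_naive(x, params$means[j, ], params$sigmas[[j]])
    }, numeric(1))))
  }))
}

# grid-search oracle for the optimal-truncation operator: returns the best
# objective value over a dense grid of thresholds
trunc_grid_oracle <- function(values, weights, c, npts = 1e6) {
  tg <- seq(max(values) * 1.05 / npts, max(values) * 1.05, length.out = npts)
  ct <- if (is.finite(c)) outer(values, tg * c, pmin) else
    matrix(values, length(values), npts)
  m <- pmax(ct, matrix(tg, length(values), npts, byrow = TRUE))
  fo <- colSums(weights * (log(m) + values / m))
  list(f = min(fo), t = tg[which.min(fo)])
}

# objective value achieved by a clamped output vector (recover t from the
# smallest output value, which equals t unless nothing was clamped)
trunc_obj_of_output <- function(values, weights, c, out) {
  if (isTRUE(all.equal(out, values))) {
    return(sum(weights * (log(values) + 1)))
  }
  cand <- c(min(out), max(out) / c)
  min(vapply(cand[cand > 0], function(t) trunc_objective(values, weights, t, c),
             numeric(1)))
}

# pair-counting adjusted Rand index oracle (O(n^2) direct enumeration)
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  tot <- n11 + n00 + n10 + n01
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- (2 * n11 + n10 + n01) / 2
  if (max_idx == exp_idx) return(if (n10 + n01 == 0) 1 else 0)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# random unit-determinant shape vector with within-ratio <= c_shw
rshape <- function(p, c_shw) {
  g <- exp(runif(p, 0, log(c_shw)))
  g <- opt_trunc(g, c = c_shw)
  g / exp(mean(log(g)))
}

# complete-data covariance objective: sum_j n_j [log|Sigma_j| + tr(Sigma_j^{-1} S_j)]
cov_objective <- function(Sigma, S, n_j) {
  sum(vapply(seq_along(S), function(j) {
    n_j[j] * (as.numeric(determinant(Sigma[[j]])$modulus) +
                sum(diag(solve(Sigma[[j]], S[[j]]))))
  }, numeric(1)))
}

# random weighted moments (tau, n_j, S_j) from random data
rmoments <- function(n, p, k) {
  X <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p)
  tau <- matrix(runif(n * k), n, k)
  tau <- tau / rowSums(tau)
  c(m_step_moments(X, tau), list(X = X, tau = tau))
}

# strict controls that iterate the nested covariance update to its fixed
# point (used when comparing with closed-form limit estimators)
strict_control <- function() {
  parsmix_control(iter_max_ddr = 100, iter_max_shape = 100,
                  iter_max_rot = 100, tol_ddr = 1e-300,
                  tol_shape = 1e-300, tol_rot = 1e-300)
}
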