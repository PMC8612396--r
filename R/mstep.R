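#' Observation weights (E-step)
#'
#' Computes the posterior component weights `tau_ij` of every observation
#' given the current parameters. In EM mode the rows are the normalised
#' posterior probabilities `pi_j phi_j(x_i) / sum_l pi_l phi_l(x_i)`; in
#' CEM mode each row is the one-hot indicator of the component with the
#' largest `pi_j phi_j(x_i)` (the lowest component index wins exact ties).
#' All work happens in log space so underflow cannot produce zero rows.
#'
#' @inheritParams mixture_loglik
#' @param mode `"em"` (soft weights) or `"cem"` (hard assignment).
#' @return A list with `tau` (`n x k` matrix), `n_j` (component masses,
#'   `colSums(tau)`) and `labels` (the row-wise argmax, in `1..k`).
#' @export
e_step <- function(data, params, mode = c("em", "cem")) {
  mode <- match.arg(mode)
  X <- data_matrix(data)
  logW <- cpp_log_weights(X, params$weights, params$means,
                          sigma_array(params$sigmas, params$p))
  labels <- max.col(logW, ties.method = "first")
  if (mode == "cem") {
    tau <- matrix(0, nrow(X), params$k)
    tau[cbind(seq_len(nrow(X)), labels)] <- 1
  } else {
    m <- apply(logW, 1L, max)
    tau <- exp(logW - m)
    tau <- tau / rowSums(tau)
  }
  list(tau = tau, n_j = colSums(tau), labels = labels)
}

#' Weight, mean and scatter moments (first half of the M-step)
#'
#' Given observation weights, computes the closed-form updates of the
#' mixture weights and means together with the weighted covariance matrix
#' of each component, the raw material for the constrained scatter update.
#'
#' @inheritParams mixture_loglik
#' @param tau `n x k` matrix of observation weights (soft or one-hot).
#' @return A list with `pi` (weights), `mu` (`k x p` means), `n_j`
#'   (masses) and `S` (list of `k` weighted covariance matrices, each with
#'   denominator `n_j`).
#' @export
m_step_moments <- function(data, tau) {
  X <- data_matrix(data)
  tau <- as.matrix(tau)
  stopifnot(nrow(tau) == nrow(X))
  n_j <- colSums(tau)
  if (any(n_j <= 0)) stop("empty component (zero mass)", call. = FALSE)
  mu <- crossprod(tau, X) / n_j
  S <- lapply(seq_len(ncol(tau)), function(j) {
    Xc <- sweep(X, 2L, mu[j, ])
    Sj <- crossprod(Xc * tau[, j], Xc) / n_j[j]
    (Sj + t(Sj)) / 2
  })
  list(pi = n_j / nrow(X), mu = mu, n_j = n_j, S = S)
}

#' Constrained shape update
#'
#' Improves the unit-determinant diagonal shape matrices given fixed
#' volumes and rotations by iterating: within-component optimal truncation
#' at `c_shw` (unit weights), renormalisation to unit determinant, a
#' decreasing sort under the free-rotation regime, and between-component
#' optimal truncation at `c_shb` (component masses as weights), undoing
#' the sort afterwards.
#'
#' @param S List of weighted component covariance matrices.
#' @param n_j Component masses.
#' @param d Current volume parameters.
#' @param R List of current rotation matrices.
#' @param spec A [constraint_spec()].
#' @param iter_max,tol Inner-loop controls.
#' @return A `p x k` matrix of shape elements (unit-determinant columns).
#' @export
update_shapes <- function(S, n_j, d, R, spec, iter_max = 20, tol = 1e-6) {
  p <- nrow(S[[1]])
  cpp_update_shapes(sigma_array(S, p), n_j, d, sigma_array(R, p),
                    spec$c_shw, spec$c_shb, rot_code(spec$rot),
                    iter_max, tol)
}

#' Constrained volume update
#'
#' Improves the volume parameters given fixed shapes and rotations: the
#' unconstrained per-component optimum is
#' `nu_j = trace(D_j^{-1} R_j' S_j R_j) / p`, to which the optimal
#' truncation at `c_det^(1/p)` (component masses as weights) is applied so
#' the determinant ratio never exceeds `c_det`.
#'
#' @inheritParams update_shapes
#' @param D `p x k` matrix of shape elements.
#' @param c_det Determinant constraint constant.
#' @return Vector of `k` volumes.
#' @export
update_volumes <- function(S, n_j, D, R, c_det) {
  p <- nrow(S[[1]])
  as.numeric(cpp_update_volumes(sigma_array(S, p), n_j,
                                matrix(D, nrow = p), sigma_array(R, p), c_det))
}

#' Common-rotation update (equal-rotation regime)
#'
#' Improves the rotation matrix shared by all components by
#' majorisation-minimisation of the complete-data objective
#' `sum_j n_j / (n d_j) * trace(D_j^{-1} R' S_j R)`: each step solves an
#' orthogonal Procrustes problem built from `W_j = (n_j / n) S_j` and its
#' largest eigenvalue, and a guard stops the loop if the objective would
#' ever increase.
#'
#' @inheritParams update_volumes
#' @param R_init Starting orthogonal matrix.
#' @param iter_max,tol Inner-loop controls (`tol` applies to the rotation
#'   change monitor, see [rotation_change()]).
#' @return A list with `R` (orthogonal matrix), `iterations` and
#'   `converged`.
#' @export
update_rotation_common <- function(S, n_j, d, D, R_init, iter_max = 20,
                                   tol = 1e-6) {
  p <- nrow(S[[1]])
  cpp_update_rotation(sigma_array(S, p), n_j, d, matrix(D, nrow = p),
                      R_init, iter_max, tol)
}

#' Full constrained covariance update
#'
#' The complete scatter part of the M-step: initialises volumes as
#' `det(S_j)^(1/p)` and rotations per regime (eigenvectors of `S_j` under
#' free rotations, the identity under axis alignment, eigenvectors of the
#' volume-standardised pooled matrix under equal rotations), then cycles
#' shape, volume and rotation improvements until the largest relative
#' change falls below `tol_ddr`.
#'
#' @inheritParams update_shapes
#' @param control A [parsmix_control()] (only the inner-loop entries are
#'   used).
#' @return A list with `d`, `D` (`p x k`), `R` (list of rotations),
#'   `Sigma` (list of covariance matrices), `iterations` and `converged`.
#' @export
update_scatters <- function(S, n_j, spec, control = parsmix_control()) {
  p <- nrow(S[[1]])
  res <- cpp_update_scatters(
    sigma_array(S, p), n_j, spec$c_det, spec$c_shw, spec$c_shb,
    rot_code(spec$rot),
    control$iter_max_ddr, control$tol_ddr,
    control$iter_max_shape, control$tol_shape,
    control$iter_max_rot, control$tol_rot
  )
  k <- length(n_j)
  list(
    d = as.numeric(res$d), D = matrix(res$D, nrow = p),
    R = lapply(seq_len(k), function(j) matrix(res$R[, , j], p, p)),
    Sigma = lapply(seq_len(k), function(j) matrix(res$Sigma[, , j], p, p)),
    iterations = res$iterations, converged = res$converged
  )
}

#' Relative parameter change between iterations
#'
#' The convergence monitor of all nested loops: for a parameter made of
#' per-component blocks, the maximum over components of
#' `||vec(b_j) - vec(b_j_prev)|| / ||vec(b_j_prev)||`. A zero-norm
#' previous block yields `Inf` (forcing another iteration) unless the
#' current block is also zero.
#'
#' @param prev,curr Numeric vectors/matrices, or lists of them (one
#'   element per component).
#' @return A single non-negative number (possibly `Inf`).
#' @export
relative_change <- function(prev, curr) {
  if (!is.list(prev)) {
    prev <- list(prev)
    curr <- list(curr)
  }
  stopifnot(length(prev) == length(curr))
  max(vapply(seq_along(prev), function(j) {
    a <- as.numeric(prev[[j]])
    b <- as.numeric(curr[[j]])
    na <- sqrt(sum(a^2))
    if (na == 0) {
      if (sqrt(sum(b^2)) == 0) 0 else Inf
    } else {
      sqrt(sum((b - a)^2)) / na
    }
  }, numeric(1)))
}

#' Rotation change monitor
#'
#' The dedicated monitor for iterated rotation matrices:
#' `|p - trace((R' R_prev)' (R R_prev'))| / p`, which is zero exactly when
#' the rotation did not move.
#'
#' @param R_prev,R_curr Orthogonal matrices of equal size.
#' @return A single non-negative number.
#' @export
rotation_change <- function(R_prev, R_curr) {
  stopifnot(all(dim(R_prev) == dim(R_curr)))
  cpp_rotation_change(R_prev, R_curr)
}
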