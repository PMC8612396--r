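#' Random initial parameters from subsampled observations
#'
#' Draws `k * (p + 1)` observations at random, splits them into `k` groups
#' of `p + 1`, and uses each group's mean and sample covariance as the
#' initial component parameters (weights start equal). The initial
#' covariances need not satisfy the constraints: those are imposed by the
#' first M-step. When fewer than `k * (p + 1)` observations are available
#' the draw is taken with replacement, and any group covariance that comes
#' out singular receives a diagonal ridge `1e-6 * tr(S) / p * I` (a warning
#' is emitted in both cases).
#'
#' @inheritParams mixture_loglik
#' @param k Number of components.
#' @return A [mixture_params()] object.
#' @export
init_params <- function(data, k) {
  X <- data_matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  m <- k * (p + 1)
  if (n >= m) {
    idx <- sample.int(n, m)
  } else {
    warning("n < k * (p + 1): initial draw taken with replacement",
            call. = FALSE)
    idx <- sample.int(n, m, replace = TRUE)
  }
  groups <- split(idx, rep(seq_len(k), each = p + 1))
  means <- matrix(0, k, p)
  sigmas <- vector("list", k)
  ridged <- FALSE
  for (j in seq_len(k)) {
    Y <- X[groups[[j]], , drop = FALSE]
    means[j, ] <- colMeans(Y)
    Yc <- sweep(Y, 2L, means[j, ])
    S <- crossprod(Yc) / nrow(Y)
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(abs(ev), 1e-300)) {
      scale <- sum(diag(S)) / p
      if (scale <= 0) scale <- 1
      S <- S + 1e-6 * scale * diag(p)
      ridged <- TRUE
    }
    sigmas[[j]] <- S
  }
  if (ridged) {
    warning("singular initial group covariance: diagonal ridge applied",
            call. = FALSE)
  }
  colnames(means) <- colnames(X)
  mixture_params(weights = rep(1 / k, k), means = means, sigmas = sigmas)
}

#' Fit a constrained parsimonious Gaussian mixture
#'
#' Maximum-likelihood clustering of multivariate data with `k` Gaussian
#' components whose covariance matrices obey the constraints in a
#' [constraint_spec()]: a cap on the determinant ratio, on within-component
#' shape and on between-component shape, plus a rotation regime. The
#' fitting algorithm is a nested ECM: a soft (EM) or hard (CEM) E-step,
#' closed-form weight and mean updates, and a constrained covariance update
#' that cycles optimal-truncation shape improvements, truncated volume
#' updates and (under equal rotations) a majorised common-rotation step.
#' `nstart` random initialisations are run and the parameters achieving the
#' best target likelihood are returned.
#'
#' @inheritParams mixture_loglik
#' @param k Number of components.
#' @param c_det,c_shw,c_shb,rot Constraint constants and rotation regime
#'   (ignored when `spec` is supplied).
#' @param mode `"em"` maximises the mixture likelihood, `"cem"` the
#'   classification likelihood through hard assignments.
#' @param control A [parsmix_control()] with iteration limits, tolerances
#'   and `nstart`.
#' @param seed Optional integer seed for reproducible starts; each start
#'   draws its own sub-seed so results do not depend on evaluation order.
#' @param extra_inits Optional list of [mixture_params()] used as
#'   additional deterministic starts (e.g. warm starts).
#' @param spec Optional [constraint_spec()] overriding the four constraint
#'   arguments.
#' @return An object of class `parsmix_fit` with elements `params`
#'   (a [mixture_params()]), `loglik` (best achieved target), `labels`,
#'   `tau`, `spec`, `mode`, `bic` and `penalty` (EM mode), a constraint
#'   report, the per-iteration target `trace` of the best start,
#'   `start_targets`, `n_starts_ok`, `iterations` and `converged`.
#'   Methods: [tidy()], [glance()], [augment()], [autoplot()], `print()`.
#' @examples
#' data <- sim_design_a(seed = 1)
#' fit <- parsmix(data[1:3], k = 3, c_det = 2, c_shw = 100, c_shb = 2,
#'                control = parsmix_control(nstart = 5), seed = 1)
#' glance(fit)
#' @export
parsmix <- function(data, k, c_det = Inf, c_shw = Inf, c_shb = Inf,
                    rot = c("V", "E", "I"), mode = c("em", "cem"),
                    control = parsmix_control(), seed = NULL,
                    extra_inits = NULL, spec = NULL) {
  mode <- match.arg(mode)
  X <- data_matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(spec)) {
    spec <- constraint_spec(c_det, c_shw, c_shb, match.arg(rot))
  }
  spec <- spec_effective(spec, p)
  stopifnot(k >= 1)
  if (n < k * (p + 1)) {
    warning("fewer than k * (p + 1) observations; initialisation falls back ",
            "to resampling", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, control$nstart)

  inits <- c(
    lapply(start_seeds, function(s) {
      set.seed(s)
      suppressWarnings(init_params(X, k))
    }),
    extra_inits %||% list()
  )

  best <- NULL
  start_targets <- rep(NA_real_, length(inits))
  n_ok <- 0L
  for (i in seq_along(inits)) {
    th0 <- inits[[i]]
    res <- tryCatch(
      cpp_ecm_run(
        X, th0$weights, th0$means, sigma_array(th0$sigmas, p),
        spec$c_det, spec$c_shw, spec$c_shb, rot_code(spec$rot),
        mode == "cem",
        control$iter_max, control$tol,
        control$iter_max_ddr, control$tol_ddr,
        control$iter_max_shape, control$tol_shape,
        control$iter_max_rot, control$tol_rot
      ),
      error = function(e) NULL
    )
    if (is.null(res) || res$status != 0L) next
    n_ok <- n_ok + 1L
    start_targets[i] <- res$target
    if (is.null(best) || res$target > best$target) best <- res
  }
  if (is.null(best)) {
    stop("all ", length(inits), " starts ended degenerate (empty component ",
         "or singular covariance); consider tightening the constraints",
         call. = FALSE)
  }

  var_names <- colnames(X) %||% paste0("x", seq_len(p))
  params <- params_from_cpp(best, spec$rot, var_names)
  report <- check_constraints(params, spec, tol = 10 * control$tol_ddr)
  penalty <- penalty_terms(k, p, spec)
  bic <- if (mode == "em") bic_score(best$target, k, p, n, spec) else NA_real_

  structure(
    list(
      params = params, loglik = best$target, mode = mode, spec = spec,
      labels = as.integer(best$labels), tau = best$tau,
      n_j = colSums(best$tau),
      trace = as.numeric(best$trace),
      start_targets = start_targets, n_starts_ok = n_ok,
      iterations = best$iterations, converged = as.logical(best$converged),
      constraints = report, penalty = penalty, bic = bic,
      n = n, p = p, k = k, var_names = var_names,
      data = tibble::as_tibble(as.data.frame(X)),
      control = control
    ),
    class = "parsmix_fit"
  )
}

#' @export
print.parsmix_fit <- function(x, ...) {
  cat("<parsmix_fit> k = ", x$k, ", n = ", x$n, ", p = ", x$p,
      ", mode = ", toupper(x$mode), "\n", sep = "")
  print(x$spec)
  cat("  target loglik = ", format(x$loglik), if (!is.na(x$bic)) {
    paste0(", BIC = ", format(x$bic))
  }, "\n", sep = "")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  cat("  ", x$n_starts_ok, "/", length(x$start_targets),
      " starts completed, best start ", if (x$converged) "converged"
      else "hit iter_max", " after ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
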