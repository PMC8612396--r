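#' Tidy a constrained mixture fit
#'
#' One row per mixture component: weight, cluster size (hard count),
#' volume, the within-component shape ratio, and the estimated mean of
#' every feature (columns `mean_<feature>`).
#'
#' @param x A [parsmix()] fit.
#' @param ... Unused.
#' @return A tibble with `k` rows.
#' @export
tidy.parsmix_fit <- function(x, ...) {
  means <- x$params$means
  colnames(means) <- paste0("mean_", x$var_names)
  tibble::tibble(
    component = seq_len(x$k),
    weight = x$params$weights,
    size = tabulate(x$labels, x$k),
    volume = x$params$d,
    shape_ratio = apply(x$params$shape, 2L, function(g) max(g) / min(g)),
    tibble::as_tibble(as.data.frame(means))
  )
}

#' One-row summary of a constrained mixture fit
#'
#' @param x A [parsmix()] fit.
#' @param ... Unused.
#' @return A tibble with one row: dimensions, constraint constants, the
#'   achieved target log-likelihood, penalty and BIC, and convergence
#'   information.
#' @export
glance.parsmix_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, p = x$p, mode = x$mode,
    c_det = x$spec$c_det, c_shw = x$spec$c_shw, c_shb = x$spec$c_shb,
    rot = x$spec$rot,
    loglik = x$loglik, penalty = x$penalty, bic = x$bic,
    iterations = x$iterations, converged = x$converged,
    n_starts_ok = x$n_starts_ok,
    constraints_ok = x$constraints$satisfied
  )
}

#' Augment data with cluster assignments
#'
#' Adds the hard assignment (`.cluster`, a factor) and the assignment
#' uncertainty (`.uncertainty`, one minus the largest posterior weight) to
#' the clustered data.
#'
#' @param x A [parsmix()] fit.
#' @param data Data to augment; defaults to the data the model was fitted
#'   on.
#' @param ... Unused.
#' @return A tibble.
#' @export
augment.parsmix_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    data <- x$data
    tau <- x$tau
    labels <- x$labels
  } else {
    es <- e_step(data, x$params, mode = x$mode)
    tau <- es$tau
    labels <- es$labels
    data <- tibble::as_tibble(data)
  }
  data$.cluster <- factor(labels, levels = seq_len(x$k))
  data$.uncertainty <- 1 - apply(tau, 1L, max)
  data
}

#' Tidy the BIC table of a model search
#'
#' @param x A [parsmix_select()] result.
#' @param ... Unused.
#' @return The full configuration table: one row per evaluated
#'   `(k, c_det, c_shw, c_shb, rot)` with log-likelihood, penalty and BIC.
#' @export
tidy.parsmix_select <- function(x, ...) x$table

#' One-row summary of a model search
#'
#' @param x A [parsmix_select()] result.
#' @param ... Unused.
#' @return A tibble with the selected configuration and its scores.
#' @export
glance.parsmix_select <- function(x, ...) {
  g <- glance(x$fit)
  g$k_max <- x$k_max
  g$c_levels <- x$c_levels
  g$n_configs <- nrow(x$table)
  g
}
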