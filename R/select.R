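#' Complexity penalty of the constrained BIC criterion
#'
#' Evaluates the penalty `v` that replaces the free-parameter count in the
#' BIC for constrained parsimonious mixtures:
#' \deqn{v = kp + (k-1) + [(k-1)(1 - c_{det}^{-1/p}) + 1] +
#'   (p-1)(1 - 1/c_{shw})[(k-1)(1 - 1/c_{shb}) + 1] +
#'   k(rot) p(p-1)/2,}
#' with `k(rot) = 0, 1, k` for the `I`, `E`, `V` rotation regimes. Larger
#' constants allow more varied covariance matrices and are penalised more;
#' at the limit configurations (constants 1 or `Inf`) the penalty equals
#' the classical free-parameter count of the corresponding parsimonious
#' model exactly.
#'
#' @param k Number of components.
#' @param p Data dimension.
#' @param spec A [constraint_spec()].
#' @return A single number.
#' @examples
#' penalty_terms(3, 2, constraint_spec(1, 1, 1, rot = "I")) # EII: 9
#' penalty_terms(3, 2, constraint_spec(Inf, Inf, Inf, rot = "V")) # VVV: 17
#' @export
penalty_terms <- function(k, p, spec) {
  det_term <- if (is.infinite(spec$c_det)) 1 else 1 - spec$c_det^(-1 / p)
  shw_term <- if (is.infinite(spec$c_shw)) 1 else 1 - 1 / spec$c_shw
  shb_term <- if (is.infinite(spec$c_shb)) 1 else 1 - 1 / spec$c_shb
  k_rot <- switch(spec$rot, I = 0, E = 1, V = k)
  k * p + (k - 1) +
    ((k - 1) * det_term + 1) +
    (p - 1) * shw_term * ((k - 1) * shb_term + 1) +
    k_rot * p * (p - 1) / 2
}

#' BIC score of a constrained fit
#'
#' `-2 L + v log(n)` with `L` the achieved target log-likelihood and `v`
#' the constrained complexity penalty of [penalty_terms()]. Smaller is
#' better.
#'
#' @param loglik Achieved target log-likelihood.
#' @inheritParams penalty_terms
#' @param n Number of observations.
#' @return A single number.
#' @export
bic_score <- function(loglik, k, p, n, spec) {
  stopifnot(is.finite(loglik))
  -2 * loglik + penalty_terms(k, p, spec) * log(n)
}

#' Two-phase BIC search over components and constraint constants
#'
#' Selects the number of components, the rotation regime and the three
#' constraint constants by minimising the constrained BIC in two phases.
#' Phase 1 fits, for every `k` in `1..k_max`, the 14 parsimonious limit
#' patterns with `Inf` replaced by the mildly-constraining upper bound
#' `2^(c_levels - 1)`; the BIC-best configuration fixes `k`, the rotation
#' and any constant equal to 1. Phase 2 refines the remaining constants
#' over the powers of two `2^0 .. 2^(c_levels - 1)` (capped by the phase-1
#' values and by the between/within feasibility bound), warm-started from
#' the phase-1 winner.
#'
#' @inheritParams parsmix
#' @param k_max Upper bound for the number of components.
#' @param c_levels Number of power-of-two levels: constants range over
#'   `2^0 .. 2^(c_levels - 1)`.
#' @return An object of class `parsmix_select` with the full BIC `table`
#'   (one row per evaluated configuration), the selected `fit`
#'   (a [parsmix()] fit), the phase-1 pick and the final configuration.
#'   Methods: [tidy()], [glance()], [autoplot()], `print()`.
#' @examples
#' \donttest{
#' data <- sim_design_a(seed = 1)
#' sel <- parsmix_select(data[1:3], k_max = 4, c_levels = 6,
#'                       control = parsmix_control(nstart = 10), seed = 1)
#' glance(sel)
#' }
#' @export
parsmix_select <- function(data, k_max = 4, c_levels = 6,
                           mode = c("em", "cem"),
                           control = parsmix_control(), seed = NULL) {
  mode <- match.arg(mode)
  X <- data_matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(k_max >= 1, c_levels >= 1)
  c_hi <- 2^(c_levels - 1)
  if (!is.null(seed)) set.seed(seed)

  fit_one <- function(k, c_det, c_shw, c_shb, rot, extra_inits = NULL) {
    tryCatch(
      suppressWarnings(parsmix(
        X, k, spec = constraint_spec(c_det, c_shw, c_shb, rot, p = p),
        mode = mode, control = control, extra_inits = extra_inits
      )),
      error = function(e) {
        warning("fit failed for k = ", k, " (", c_det, ", ", c_shw, ", ",
                c_shb, ", ", rot, "): ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
  }
  row_of <- function(fit, k, c_det, c_shw, c_shb, rot, phase, model = NA) {
    tibble::tibble(
      phase = phase, model = as.character(model), k = k,
      c_det = c_det, c_shw = c_shw, c_shb = c_shb, rot = rot,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      penalty = penalty_terms(k, p, constraint_spec(c_det, c_shw, c_shb, rot)),
      bic = if (is.null(fit)) NA_real_ else {
        -2 * fit$loglik + penalty_terms(
          k, p, constraint_spec(c_det, c_shw, c_shb, rot)) * log(n)
      },
      converged = if (is.null(fit)) NA else fit$converged
    )
  }

  # ---- phase 1: k x 14 slightly-constrained limit patterns -----------------
  patterns <- limit_models()
  sub <- function(v) ifelse(is.infinite(v), c_hi, v)
  rows <- list()
  fits <- list()
  for (k in seq_len(k_max)) {
    # for k = 1 the determinant and between-shape constants are vacuous, so
    # several of the 14 patterns share one fit; fit each unique configuration
    # once but keep all 14 rows in the table
    cache <- list()
    for (i in seq_len(nrow(patterns))) {
      cd <- sub(patterns$c_det[i]); cw <- sub(patterns$c_shw[i])
      cb <- min(sub(patterns$c_shb[i]), shb_bound(cw, p))
      key <- if (k == 1L) paste(cw, patterns$rot[i]) else paste(cd, cw, cb, patterns$rot[i])
      if (is.null(cache[[key]])) {
        cache[[key]] <- list(fit_one(k, cd, cw, cb, patterns$rot[i]))
      }
      fit <- cache[[key]][[1]]
      rows[[length(rows) + 1L]] <-
        row_of(fit, k, cd, cw, cb, patterns$rot[i], 1L, patterns$code[i])
      fits[[length(fits) + 1L]] <- fit
    }
  }
  tab1 <- dplyr::bind_rows(rows)
  if (all(is.na(tab1$bic))) stop("every phase-1 fit failed", call. = FALSE)
  best1 <- pick_best(tab1)
  star <- tab1[best1, ]
  fit1 <- fits[[best1]]

  # ---- phase 2: refine the constants over powers of two --------------------
  axis <- function(c_star) 2^(0:(c_levels - 1))[2^(0:(c_levels - 1)) <=
                                                  min(c_star, c_hi)]
  grid <- tidyr::expand_grid(
    c_det = axis(star$c_det), c_shw = axis(star$c_shw),
    c_shb = axis(min(star$c_shb, shb_bound(star$c_shw, p)))
  )
  feasible <- mapply(function(cw, cb) cb <= shb_bound(cw, p) * (1 + 1e-12),
                     grid$c_shw, grid$c_shb)
  grid <- grid[feasible, , drop = FALSE]
  rows2 <- list()
  fits2 <- list()
  for (i in seq_len(nrow(grid))) {
    cd <- grid$c_det[i]; cw <- grid$c_shw[i]; cb <- grid$c_shb[i]
    if (cd == star$c_det && cw == star$c_shw && cb == star$c_shb) {
      fit <- fit1 # identical configuration: reuse the phase-1 fit
    } else {
      fit <- fit_one(star$k, cd, cw, cb, star$rot,
                     extra_inits = list(fit1$params))
    }
    rows2[[length(rows2) + 1L]] <- row_of(fit, star$k, cd, cw, cb, star$rot, 2L)
    fits2[[length(fits2) + 1L]] <- fit
  }
  tab2 <- dplyr::bind_rows(rows2)
  best2 <- pick_best(tab2)
  final_fit <- fits2[[best2]]
  final <- tab2[best2, ]

  structure(
    list(
      table = dplyr::bind_rows(tab1, tab2),
      fit = final_fit,
      k = final$k,
      spec = final_fit$spec,
      phase1 = list(k = star$k, c_det = star$c_det, c_shw = star$c_shw,
                    c_shb = star$c_shb, rot = star$rot, model = star$model),
      k_max = k_max, c_levels = c_levels, mode = mode, n = n, p = p
    ),
    class = "parsmix_select"
  )
}

# BIC-minimising row; ties broken toward the smaller penalty, then smaller k
pick_best <- function(tab) {
  ok <- which(!is.na(tab$bic))
  ord <- order(tab$bic[ok], tab$penalty[ok], tab$k[ok])
  ok[ord[1L]]
}

#' @export
print.parsmix_select <- function(x, ...) {
  cat("<parsmix_select> evaluated ", nrow(x$table), " configurations ",
      "(k_max = ", x$k_max, ", levels = ", x$c_levels, ")\n", sep = "")
  cat("  selected k = ", x$k, " with ", sep = "")
  print(x$spec)
  cat("  BIC = ", format(min(x$table$bic, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}
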