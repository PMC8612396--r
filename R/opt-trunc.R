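#' Weighted optimal truncation
#'
#' Clamps a set of non-negative values into an interval `[t, c * t]` whose
#' ratio of endpoints is the constraint constant `c`, choosing the
#' threshold `t` that minimises the weighted likelihood-derived objective
#' `f(t) = sum_j w_j * (log m_t(v_j) + v_j / m_t(v_j))` with
#' `m_t(v) = min(max(v, t), c * t)`. This operator is the workhorse used to
#' impose all three covariance constraints inside the M-step: on shape
#' elements within a component (unit weights), on shape elements across
#' components (component masses as weights) and on volume parameters.
#'
#' The minimiser is found exactly: `t*` lies either at a point where the
#' clamping pattern changes (some `v_j` or `v_j / c`) or at the stationary
#' value of `f` inside an interval with a fixed pattern, and all candidates
#' are evaluated. Values already satisfying `max/min <= c` are returned
#' unchanged, as is everything when `c = Inf`. Entries with zero weight do
#' not influence `t*` but are still clamped. At `c = 1` the result is the
#' weighted mean of the values in every coordinate.
#'
#' @param values Non-negative numeric vector; at least one entry carrying
#'   positive weight must be strictly positive (otherwise the component is
#'   degenerate and an error is thrown).
#' @param weights Non-negative weights, same length as `values`; default
#'   unit weights.
#' @param c Constraint constant, `>= 1` or `Inf`.
#' @return Numeric vector of the same length, with
#'   `max(out) / min(out) <= c`.
#' @examples
#' opt_trunc(c(1, 3), c = 1) # both become the mean, 2
#' opt_trunc(c(1, 4, 9), c = 4)
#' opt_trunc(c(1, 2), c = 3) # already feasible: unchanged
#' @export
opt_trunc <- function(values, weights = rep(1, length(values)), c = Inf) {
  stopifnot(is.numeric(values), is.numeric(weights),
            length(weights) == length(values))
  if (any(weights < 0)) stop("`weights` must be non-negative", call. = FALSE)
  as.numeric(cpp_opt_trunc(values, weights, c))
}

#' Objective of the optimal-truncation operator
#'
#' Evaluates `f(t) = sum_j w_j * (log m_t(v_j) + v_j / m_t(v_j))`, the
#' function minimised by [opt_trunc()]. Exposed mainly so the solution can
#' be verified against grid search.
#'
#' @inheritParams opt_trunc
#' @param t Threshold, a positive number.
#' @return A single number.
#' @examples
#' trunc_objective(1, t = 1, c = Inf) # log(1) + 1
#' @export
trunc_objective <- function(values, weights = rep(1, length(values)), t,
                            c = Inf) {
  stopifnot(is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  cpp_trunc_objective(values, weights, t, c)
}
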