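#' Constraint specification for a constrained parsimonious mixture
#'
#' Bundles the three constraint constants and the rotation regime that
#' define the feasible set of component covariance matrices. Each constant
#' must be at least 1 (`Inf` disables the corresponding constraint):
#' `c_det` caps the ratio of the largest to the smallest covariance
#' determinant across components, `c_shw` caps the ratio of the largest to
#' the smallest shape element within each component (1 forces spherical
#' components), and `c_shb` caps, coordinate by coordinate, the ratio of
#' shape elements between components (1 forces a common shape).
#'
#' Two coherence rules are applied. `c_shw = 1` forces all shape elements
#' to 1, so the effective `c_shb` is also 1. And whenever the dimension `p`
#' is known, `c_shb` is capped at `c_shw^((p-1)/p)` (see [shb_bound()]):
#' values above the cap cannot be attained by any unit-determinant shape
#' set already satisfying the within constraint, so a larger value is
#' pointless and is reduced with a warning.
#'
#' @param c_det,c_shw,c_shb Constraint constants, each a number `>= 1` or
#'   `Inf`. The numeric surrogate `1e10` used to mean "practically
#'   unconstrained" is accepted as is.
#' @param rot Rotation regime: `"V"` (free rotations), `"E"` (equal
#'   rotations) or `"I"` (axis-aligned components).
#' @param p Optional data dimension; when supplied the feasibility cap on
#'   `c_shb` is applied immediately.
#'
#' @return An object of class `parsmix_spec`: a list with elements
#'   `c_det`, `c_shw`, `c_shb` and `rot`.
#' @examples
#' constraint_spec(c_det = 4, c_shw = 16, c_shb = 4, rot = "V")
#' constraint_spec(1, 1, 1, rot = "I") # spherical equal-volume components
#' @export
constraint_spec <- function(c_det = Inf, c_shw = Inf, c_shb = Inf,
                            rot = c("V", "E", "I"), p = NULL) {
  rot <- match.arg(rot)
  for (nm in c("c_det", "c_shw", "c_shb")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop("`", nm, "` must be a single number >= 1 (or Inf)", call. = FALSE)
    }
  }
  if (c_shw == 1 && c_shb > 1) {
    warning("`c_shw` = 1 forces unit shapes; effective `c_shb` set to 1",
            call. = FALSE)
    c_shb <- 1
  }
  spec <- structure(
    list(c_det = c_det, c_shw = c_shw, c_shb = c_shb, rot = rot),
    class = "parsmix_spec"
  )
  if (!is.null(p)) spec <- spec_effective(spec, p)
  spec
}

#' @export
print.parsmix_spec <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else format(v)
  cat("<parsmix_spec> c_det = ", fmt(x$c_det), ", c_shw = ", fmt(x$c_shw),
      ", c_shb = ", fmt(x$c_shb), ", rot = ", x$rot, "\n", sep = "")
  invisible(x)
}

# apply the dimension-dependent feasibility cap on c_shb (with a warning,
# since larger values are provably unattainable)
spec_effective <- function(spec, p) {
  cap <- shb_bound(spec$c_shw, p)
  if (spec$c_shb > cap * (1 + 1e-12)) {
    warning("`c_shb` = ", format(spec$c_shb),
            " exceeds the attainable bound c_shw^((p-1)/p) = ",
            format(cap), "; capped", call. = FALSE)
    spec$c_shb <- cap
  }
  spec
}

#' Feasibility bound linking the two shape constraints
#'
#' For unit-determinant shape matrices whose within-component ratio of
#' largest to smallest element is at most `c_shw`, the ratio of shape
#' elements between any two components, at any fixed coordinate, can never
#' exceed `c_shw^((p-1)/p)`. A between-shape constant above this bound is
#' therefore never active.
#'
#' @param c_shw Within-component shape constant, `>= 1` or `Inf`.
#' @param p Data dimension, a positive integer.
#' @return The bound `c_shw^((p-1)/p)` (with `Inf` mapped to `Inf`).
#' @examples
#' shb_bound(4, p = 2) # 2: c_shb <= sqrt(c_shw) in dimension 2
#' shb_bound(8, p = 3) # 4
#' @export
shb_bound <- function(c_shw, p) {
  stopifnot(is.numeric(c_shw), length(c_shw) == 1L, c_shw >= 1,
            is.numeric(p), length(p) == 1L, p >= 1)
  if (is.infinite(c_shw)) return(Inf)
  c_shw^((p - 1) / p)
}

#' The 14 parsimonious limit models
#'
#' Enumerates the limit configurations obtained when each constraint
#' constant is pushed to 1 or infinity. Of the `2^3 x 3 = 24` raw
#' combinations, those with `c_shw = 1` but `c_shb = Inf` are infeasible
#' (the feasibility bound forces `c_shb = 1` under sphericity), and under
#' `c_shw = 1` the rotation regime is immaterial, so the rotation-equivalent
#' spherical combinations collapse. Exactly the 14 classical
#' three-letter parsimonious models remain.
#'
#' @param raw If `TRUE`, return the 24 unfiltered combinations instead
#'   (no codes, no collapsing); mainly useful for inspection.
#' @return A tibble with columns `code`, `c_det`, `c_shw`, `c_shb`, `rot`
#'   (14 rows), or the 24 raw combinations without `code` when `raw = TRUE`.
#' @examples
#' limit_models()
#' nrow(limit_models(raw = TRUE)) # 24
#' @export
limit_models <- function(raw = FALSE) {
  grid <- tidyr::expand_grid(
    c_det = c(1, Inf), c_shw = c(1, Inf), c_shb = c(1, Inf),
    rot = c("I", "E", "V")
  )
  if (raw) return(grid)
  grid <- dplyr::filter(grid, !(.data$c_shw == 1 & .data$c_shb == Inf))
  # sphericity makes the rotation immaterial: collapse to rot = "I"
  grid <- dplyr::filter(grid, !(.data$c_shw == 1 & .data$rot != "I"))
  code <- purrr::pmap_chr(grid, function(c_det, c_shw, c_shb, rot) {
    first <- if (c_det == 1) "E" else "V"
    if (c_shw == 1) return(paste0(first, "II"))
    second <- if (c_shb == 1) "E" else "V"
    paste0(first, second, rot)
  })
  dplyr::arrange(
    tibble::tibble(code = code, grid),
    .data$c_det, .data$c_shw, .data$c_shb, .data$rot
  )
}
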