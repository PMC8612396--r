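#' Control parameters for the nested ECM algorithm
#'
#' Collects the iteration limits and convergence tolerances of the fitting
#' algorithm. `nstart` random initialisations are run independently and the
#' best target value is kept. The outer loop (E-step plus full M-step) runs
#' up to `iter_max` times or until the maximal relative parameter change
#' drops below `tol`; the nested covariance update cycles shape, volume and
#' rotation improvements (`iter_max_ddr` / `tol_ddr`), with inner loops for
#' the shape truncations (`iter_max_shape` / `tol_shape`) and, under the
#' equal-rotation regime, for the common-rotation majorisation
#' (`iter_max_rot` / `tol_rot`).
#'
#' @param nstart Number of random initialisations (default 50; large
#'   simulation studies typically use more).
#' @param iter_max Maximum outer ECM iterations per start.
#' @param iter_max_ddr,iter_max_shape,iter_max_rot Maximum iterations of
#'   the nested covariance, shape and rotation loops.
#' @param tol,tol_ddr,tol_shape,tol_rot Convergence tolerances (relative
#'   changes) for the corresponding loops.
#' @return A list of class `parsmix_control`.
#' @export
parsmix_control <- function(nstart = 50, iter_max = 100,
                            iter_max_ddr = 20, iter_max_shape = 20,
                            iter_max_rot = 20,
                            tol = 1e-6, tol_ddr = 1e-6,
                            tol_shape = 1e-6, tol_rot = 1e-6) {
  ctrl <- list(
    nstart = as.integer(nstart), iter_max = as.integer(iter_max),
    iter_max_ddr = as.integer(iter_max_ddr),
    iter_max_shape = as.integer(iter_max_shape),
    iter_max_rot = as.integer(iter_max_rot),
    tol = tol, tol_ddr = tol_ddr, tol_shape = tol_shape, tol_rot = tol_rot
  )
  counts <- unlist(ctrl[1:5])
  tols <- unlist(ctrl[6:9])
  if (any(counts < 1L)) stop("iteration counts must be >= 1", call. = FALSE)
  if (any(tols <= 0)) stop("tolerances must be positive", call. = FALSE)
  structure(ctrl, class = "parsmix_control")
}

rot_code <- function(rot) c(I = 0L, E = 1L, V = 2L)[[rot]]
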