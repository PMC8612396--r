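#' Compose a covariance matrix from its volume/shape/rotation parts
#'
#' Builds `d * R %*% D %*% t(R)` from a volume `d > 0`, a unit-determinant
#' diagonal shape matrix `D` and an orthogonal rotation `R`. This is the
#' decomposition on which all three covariance constraints operate: `d^p`
#' is the determinant, the diagonal of `D` holds the relative axis lengths,
#' and the columns of `R` are the principal axes.
#'
#' @param d Volume parameter, a positive number.
#' @param D Shape matrix: a diagonal matrix (or its diagonal as a vector)
#'   with positive entries and determinant 1 (within `tol`).
#' @param R Orthogonal rotation matrix.
#' @param tol Relative tolerance for validating `D` and `R`.
#' @return A symmetric positive-definite matrix.
#' @examples
#' compose_scatter(4, diag(2), diag(2)) # 4 * I
#' compose_scatter(sqrt(3), diag(c(sqrt(3), 1 / sqrt(3))), diag(2))
#' @export
compose_scatter <- function(d, D, R, tol = 1e-8) {
  if (is.vector(D)) D <- diag(D, nrow = length(D))
  p <- nrow(D)
  stopifnot(is.numeric(d), length(d) == 1L, d > 0, nrow(R) == p, ncol(R) == p)
  dd <- diag(D)
  if (any(dd <= 0) || abs(prod(dd) - 1) > tol * max(1, p)) {
    stop("`D` must be diagonal with positive entries and unit determinant",
         call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(p))) > tol) {
    stop("`R` must be orthogonal", call. = FALSE)
  }
  S <- d * R %*% (dd * t(R))
  (S + t(S)) / 2
}

#' Decompose a covariance matrix into volume, shape and rotation
#'
#' Inverts [compose_scatter()]: `d = det(Sigma)^(1/p)`, the shape is the
#' unit-determinant diagonal matrix of scaled eigenvalues, and the rotation
#' collects the eigenvectors. Under the free-rotation regime (`rot = "V"`)
#' the shape elements are returned in non-increasing order -- the ordering
#' that makes the decomposition identifiable when rotations are
#' unconstrained. Eigenvectors are sign-canonicalised (first entry of
#' non-negligible magnitude made positive) so the decomposition is
#' deterministic; for a diagonal matrix under `rot = "I"` or `"E"` the
#' identity rotation and the natural coordinate order are returned.
#'
#' @param Sigma Symmetric positive-definite matrix.
#' @param rot Rotation regime; only affects the ordering convention.
#' @param tol Relative tolerance below which eigenvalues are treated as
#'   non-positive (an error).
#' @return A list with elements `d` (volume), `shape` (vector of shape
#'   elements, the diagonal of `D`) and `R` (rotation matrix).
#' @examples
#' decompose_scatter(4 * diag(2))
#' decompose_scatter(diag(c(1, 3)), rot = "V")$shape # decreasing
#' @export
decompose_scatter <- function(Sigma, rot = c("V", "E", "I"), tol = 1e-12) {
  rot <- match.arg(rot)
  Sigma <- as.matrix(Sigma)
  p <- nrow(Sigma)
  if (max(abs(Sigma - t(Sigma))) > tol * max(1, max(abs(Sigma)))) {
    stop("`Sigma` must be symmetric", call. = FALSE)
  }
  if (rot != "V" && p > 1 && max(abs(Sigma[upper.tri(Sigma)])) <=
      tol * max(abs(diag(Sigma)))) {
    vals <- diag(Sigma)
    if (any(vals <= 0)) stop("`Sigma` is not positive definite", call. = FALSE)
    d <- exp(mean(log(vals)))
    return(list(d = d, shape = vals / d, R = diag(p)))
  }
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (any(e$values <= tol * max(abs(e$values)))) {
    stop("`Sigma` is not positive definite", call. = FALSE)
  }
  vals <- e$values # eigen() returns them in decreasing order
  vecs <- e$vectors
  for (j in seq_len(p)) { # deterministic sign convention
    i <- which(abs(vecs[, j]) > 1e-12)[1]
    if (!is.na(i) && vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  d <- exp(mean(log(vals)))
  list(d = d, shape = vals / d, R = vecs)
}

#' Gaussian mixture parameters with their constrained decomposition
#'
#' Container for the parameters of a `k`-component Gaussian mixture:
#' weights, mean vectors and covariance matrices, together with the
#' volume/shape/rotation decomposition of each covariance on which the
#' constraints are expressed.
#'
#' @param weights Positive mixture weights summing to 1 (length `k`).
#' @param means `k x p` matrix (or data frame) of component means.
#' @param sigmas List of `k` symmetric positive-definite `p x p` matrices
#'   (or a `p x p x k` array).
#' @param rot Rotation regime used for the decomposition ordering.
#' @return An object of class `parsmix_params`: a list with elements `k`,
#'   `p`, `weights`, `means`, `sigmas`, `d` (volumes), `shape` (`p x k`
#'   matrix of shape elements) and `R` (list of rotation matrices).
#' @examples
#' mixture_params(
#'   weights = c(.5, .5),
#'   means = rbind(c(0, 0), c(3, 3)),
#'   sigmas = list(diag(2), diag(c(2, 1)))
#' )
#' @export
mixture_params <- function(weights, means, sigmas, rot = c("V", "E", "I")) {
  rot <- match.arg(rot)
  means <- as.matrix(means)
  if (is.array(sigmas) && length(dim(sigmas)) == 3L) {
    sigmas <- lapply(seq_len(dim(sigmas)[3]), function(j) sigmas[, , j])
  }
  k <- length(weights)
  p <- ncol(means)
  stopifnot(nrow(means) == k, length(sigmas) == k)
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be positive and sum to 1", call. = FALSE)
  }
  dec <- lapply(sigmas, decompose_scatter, rot = rot)
  structure(
    list(
      k = k, p = p, weights = as.numeric(weights), means = means,
      sigmas = lapply(sigmas, function(S) (as.matrix(S) + t(as.matrix(S))) / 2),
      d = vapply(dec, `[[`, numeric(1), "d"),
      shape = matrix(vapply(dec, `[[`, numeric(p), "shape"), nrow = p),
      R = lapply(dec, `[[`, "R"),
      rot = rot
    ),
    class = "parsmix_params"
  )
}

#' @export
print.parsmix_params <- function(x, ...) {
  cat("<parsmix_params> k = ", x$k, ", p = ", x$p,
      ", weights = ", paste(signif(x$weights, 3), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# internal: shape vector -> p x k matrix even when p = 1
as_shape_matrix <- function(shape, p, k) {
  matrix(shape, nrow = p, ncol = k)
}

# internal: coerce user data (tibble/data.frame/matrix) to a numeric matrix
data_matrix <- function(data) {
  if (is.data.frame(data)) {
    num <- vapply(data, is.numeric, logical(1))
    if (!all(num)) {
      stop("non-numeric columns in `data`: ",
           paste(names(data)[!num], collapse = ", "), call. = FALSE)
    }
    data <- as.matrix(data)
  }
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 1L, all))
    stop("non-finite entries in `data` (rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(X) < 1L || ncol(X) < 1L) stop("`data` is empty", call. = FALSE)
  X
}

# internal: list of matrices -> arma cube (p x p x k array)
sigma_array <- function(sigmas, p) {
  array(unlist(sigmas), dim = c(p, p, length(sigmas)))
}

# internal: build parsmix_params from the C++ fit output
params_from_cpp <- function(res, rot, var_names = NULL) {
  k <- length(res$pi)
  p <- ncol(res$mu)
  sig <- lapply(seq_len(k), function(j) res$Sigma[, , j, drop = TRUE])
  if (p == 1L) sig <- lapply(sig, function(s) matrix(s, 1, 1))
  means <- res$mu
  if (!is.null(var_names)) colnames(means) <- var_names
  mixture_params(weights = as.numeric(res$pi), means = means,
                 sigmas = sig, rot = rot)
}
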