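#' Read a numeric data matrix from delimited text
#'
#' Reads a CSV/TSV file of observations by features. The delimiter is
#' taken from the file extension unless given, and a header row is
#' auto-detected (a first line with any non-numeric field is treated as a
#' header). Ragged rows and non-numeric or non-finite entries are
#' rejected with the offending line in the error message.
#'
#' @param path File path.
#' @param delim Field delimiter; default `","` for `.csv`, `"\t"`
#'   otherwise.
#' @param header `TRUE`, `FALSE` or `NA` (auto-detect).
#' @return A tibble of numeric columns.
#' @export
read_matrix <- function(path, delim = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (is.na(header)) {
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  tb <- readr::read_delim(path, delim = delim, col_names = header,
                          show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    stop("malformed matrix file ", path, " (line ", probs$row[1] + header,
         ": ", probs$expected[1], " expected, got ", probs$actual[1], ")",
         call. = FALSE)
  }
  if (!header) names(tb) <- paste0("x", seq_along(tb))
  num <- vapply(tb, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(tb)[!num], collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(tb) |
                 !apply(as.matrix(tb), 1L, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop("non-finite entries in ", path, " (data row ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  tb
}

# infinity-safe scalar for JSON (serialised as the string "inf")
json_num <- function(v) if (is.infinite(v)) "inf" else v
json_unnum <- function(v) if (identical(v, "inf")) Inf else as.numeric(v)

params_to_list <- function(params, spec = NULL, loglik = NULL, bic = NULL) {
  out <- list(
    k = params$k, p = params$p,
    weights = params$weights,
    means = params$means,
    scatters = lapply(params$sigmas, function(S) as.numeric(t(S))), # row-major
    decomposition = list(
      d = params$d,
      shape = lapply(seq_len(params$k), function(j) params$shape[, j]),
      R = lapply(params$R, function(R) as.numeric(t(R)))
    ),
    var_names = colnames(params$means)
  )
  if (!is.null(spec)) {
    out$spec <- list(c_det = json_num(spec$c_det), c_shw = json_num(spec$c_shw),
                     c_shb = json_num(spec$c_shb), rot = spec$rot)
  }
  if (!is.null(loglik)) out$loglik <- loglik
  if (!is.null(bic) && !is.na(bic)) out$bic <- bic
  out
}

#' Write mixture parameters (or a fit) to JSON
#'
#' Serialises weights, means, covariance matrices (row-major), the
#' volume/shape/rotation decomposition and, for a fit, the constraint
#' specification and achieved log-likelihood/BIC. Infinite constants are
#' written as the string `"inf"`. Full double precision is kept so a
#' round trip reproduces likelihood values exactly.
#'
#' @param x A [mixture_params()] or [parsmix()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path) {
  if (inherits(x, "parsmix_fit")) {
    lst <- params_to_list(x$params, x$spec, x$loglik, x$bic)
  } else {
    lst <- params_to_list(x)
  }
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read mixture parameters back from JSON
#'
#' @param path A file written by [write_params()].
#' @return A [mixture_params()] object; the spec (if present) is attached
#'   as attribute `"spec"`, the log-likelihood as `"loglik"`.
#' @export
read_params <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lst$p
  k <- lst$k
  sc <- lst$scatters # k row-major vectors (simplified to a matrix when k > 1)
  if (is.matrix(sc)) sc <- lapply(seq_len(nrow(sc)), function(j) sc[j, ])
  sig <- lapply(sc, function(v) matrix(as.numeric(v), p, p, byrow = TRUE))
  means <- matrix(as.numeric(unlist(lst$means)), k, p)
  if (!is.null(lst$var_names)) colnames(means) <- lst$var_names
  rot <- if (!is.null(lst$spec)) lst$spec$rot else "V"
  out <- mixture_params(as.numeric(lst$weights), means, sig, rot = rot)
  if (!is.null(lst$spec)) {
    attr(out, "spec") <- constraint_spec(
      json_unnum(lst$spec$c_det), json_unnum(lst$spec$c_shw),
      json_unnum(lst$spec$c_shb), lst$spec$rot
    )
  }
  if (!is.null(lst$loglik)) attr(out, "loglik") <- lst$loglik
  out
}

#' Write fit results to files
#'
#' Writes `<prefix>_labels.csv` (one 1-based label per row, no header)
#' and `<prefix>_params.json` (see [write_params()]).
#'
#' @param fit A [parsmix()] fit.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_fit <- function(fit, prefix) {
  paths <- c(
    labels = paste0(prefix, "_labels.csv"),
    params = paste0(prefix, "_params.json")
  )
  writeLines(as.character(fit$labels), paths[["labels"]])
  write_params(fit, paths[["params"]])
  invisible(paths)
}

#' Write model-search results to files
#'
#' Writes `<prefix>_bic.csv` (the full configuration table),
#' `<prefix>_selection.json` (the chosen configuration) and the label and
#' parameter files of the selected fit (see [write_fit()]).
#'
#' @param sel A [parsmix_select()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_selection <- function(sel, prefix) {
  bic_path <- paste0(prefix, "_bic.csv")
  sel_path <- paste0(prefix, "_selection.json")
  readr::write_csv(sel$table, bic_path)
  g <- glance(sel)
  jsonlite::write_json(
    list(k = g$k, c_det = json_num(g$c_det), c_shw = json_num(g$c_shw),
         c_shb = json_num(g$c_shb), rot = g$rot, loglik = g$loglik,
         penalty = g$penalty, bic = g$bic, n_configs = g$n_configs),
    sel_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(bic = bic_path, selection = sel_path,
              write_fit(sel$fit, prefix)))
}
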