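#' Plot a clustered dataset
#'
#' Scatter plot of two features with points coloured by hard assignment
#' and component means marked.
#'
#' @param object A [parsmix()] fit.
#' @param vars Which two features to plot (names or indices); defaults to
#'   the first two.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parsmix_fit <- function(object, vars = NULL, ...) {
  if (is.null(vars)) vars <- object$var_names[1:2]
  if (is.numeric(vars)) vars <- object$var_names[vars]
  stopifnot(length(vars) == 2L)
  df <- augment(object)
  centers <- tibble::as_tibble(as.data.frame(object$params$means))
  names(centers) <- object$var_names
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[vars[1]]],
                                   y = .data[[vars[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.cluster),
                        alpha = 0.8) +
    ggplot2::geom_point(data = centers, shape = 3, size = 4,
                        stroke = 1.2) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot the BIC surface of a model search
#'
#' Phase-1 BIC profiles against the number of components, one line per
#' limit-model pattern, with the selected configuration marked.
#'
#' @param object A [parsmix_select()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parsmix_select <- function(object, ...) {
  tab <- dplyr::filter(object$table, .data$phase == 1L, !is.na(.data$bic))
  sel <- glance(object$fit)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data$bic,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = sel$bic, linetype = 2) +
    ggplot2::labs(x = "number of components k", y = "BIC",
                  colour = "pattern",
                  subtitle = paste0("selected k = ", sel$k, ", rot = ",
                                    sel$rot)) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise-overlap matrix
#'
#' Heatmap of the directed misclassification probabilities `w[j|l]`.
#'
#' @param object A [pairwise_overlap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parsmix_overlap <- function(object, ...) {
  k <- nrow(object$w)
  df <- tidyr::expand_grid(j = seq_len(k), l = seq_len(k))
  df$w <- as.numeric(object$w[cbind(df$j, df$l)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l, y = .data$j,
                                   fill = .data$w)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(k)) +
    ggplot2::scale_x_continuous(breaks = seq_len(k)) +
    ggplot2::labs(x = "generating component l", y = "competing component j",
                  fill = "w[j|l]") +
    ggplot2::theme_minimal()
}
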