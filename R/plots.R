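# ggplot2 visualizations for the main result types.

#' Heat map of a LOO-CV grid search
#'
#' @param object A `grid_search_map` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot: hyperparameter on x, number of PCs on y, LOO-CV
#'   accuracy as fill, the chosen cell outlined.
#' @method autoplot grid_search_map
#' @export
autoplot.grid_search_map <- function(object, ...) {
  df <- tidy(object)
  df$hyper <- factor(df$hyper, levels = as.character(object$hyper_grid))
  chosen <- tibble::tibble(hyper = factor(as.character(object$chosen$hyper),
                                          levels = levels(df$hyper)),
                           n_pcs = object$chosen$n_pcs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hyper, y = .data$n_pcs,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = chosen, fill = NA, colour = "red",
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "LOO-CV\naccuracy") +
    ggplot2::labs(x = "hyperparameter", y = "number of PCs",
                  title = sprintf("%s%s grid search", toupper(object$algorithm),
                                  if (is.na(object$band)) ""
                                  else paste0(" (", object$band, ")"))) +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA model
#'
#' @param object A `libs_pca` from [fit_pca()].
#' @param n_components Components to display.
#' @param ... Unused.
#' @return A ggplot of explained-variance ratios.
#' @method autoplot libs_pca
#' @export
autoplot.libs_pca <- function(object, n_components = 10, ...) {
  df <- head(tidy(object), n_components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained_variance_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "principal component", y = "explained variance") +
    ggplot2::theme_minimal()
}

#' Overall-desirability bar chart of a factorial design
#'
#' @param object A `doe_result` from [doe_results()].
#' @param ... Unused.
#' @return A ggplot of OD per experiment, the best experiment highlighted.
#' @method autoplot doe_result
#' @export
autoplot.doe_result <- function(object, ...) {
  df <- object$od
  df$best <- df$experiment == select_best(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$experiment), y = .data$od,
                                   fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "experiment", y = "overall desirability") +
    ggplot2::theme_minimal()
}

#' Plot averaged spectra colored by vigor class
#'
#' @param averaged An `averaged_spectra` object.
#' @param band Band to plot.
#' @param samples Optional subset of sample ids.
#' @return A ggplot of averaged SNV intensity vs wavelength.
#' @export
plot_spectra <- function(averaged, band, samples = NULL) {
  df <- tidy(averaged)
  df <- df[df$band == band, ]
  if (!is.null(samples)) df <- df[df$sample_id %in% samples, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$intensity,
                                   group = .data$sample_id,
                                   colour = .data$vigor)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "averaged SNV intensity",
                  colour = "vigor") +
    ggplot2::theme_minimal()
}
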