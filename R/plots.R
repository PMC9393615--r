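#' Plot group-mean leaf spectra
#'
#' Mean reflectance curve per group (optionally faceted by sampling day /
#' experiment), the standard first look at the generator output or at
#' extracted leaf spectra.
#'
#' @param data Wide spectra tibble with a `group` column.
#' @param facet_by Optional column name to facet on (e.g. `"dat"`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, facet_by = NULL) {
  long <- tidyr::pivot_longer(data, dplyr::all_of(wl_cols(data)),
                              names_to = "wavelength",
                              names_prefix = "wl_",
                              names_transform = as.numeric,
                              values_to = "reflectance")
  keys <- c("group", "wavelength", facet_by)
  means <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarize(reflectance = mean(.data$reflectance), .groups = "drop")
  p <- ggplot2::ggplot(means,
                       ggplot2::aes(.data$wavelength, .data$reflectance,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "mean reflectance",
                  colour = "group") +
    ggplot2::theme_minimal()
  if (!is.null(facet_by)) {
    p <- p + ggplot2::facet_wrap(facet_by, labeller = ggplot2::label_both)
  }
  p
}

#' Plot transfer-task results by variant
#'
#' Mean of one metric per (sampling day, variant) across tasks and seeds.
#'
#' @param results Long results tibble from [run_transfer_tasks()].
#' @param metric Metric column to plot (default `"accuracy"`).
#' @return A ggplot object.
#' @export
plot_transfer_results <- function(results, metric = "accuracy") {
  means <- summarize_metrics(results, .data$dat, .data$variant,
                             metric_names = metric)
  ggplot2::ggplot(means,
                  ggplot2::aes(factor(.data$dat), .data[[metric]],
                               fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "days after treatment",
                  y = sprintf("mean target-domain %s", metric),
                  fill = "variant") +
    ggplot2::theme_minimal()
}

#' Scree plot of a TCA model
#'
#' @param object A `tca_model`.
#' @param ... Unused.
#' @return A ggplot object of the retained eigenvalues.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.tca_model <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "transfer component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}
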