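# ggplot2 methods for the main result types. These are diagnostic plots,
# not publication figures.

#' Plot an annual masting index series
#'
#' @param object A `mast_index` tibble from [compute_m_index()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mast_index
#' @export
autoplot.mast_index <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$m)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Year", y = "Masting index (NC45 - NC12)") +
    ggplot2::theme_minimal()
}

#' Plot a raw/low/high frequency decomposition
#'
#' @param object A `freq_components` tibble from [split_frequencies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot freq_components
#' @export
autoplot.freq_components <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("raw", "low", "high"),
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component, levels = c("raw", "low", "high"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Index value") +
    ggplot2::theme_minimal()
}

#' Plot a wavelet coherence field
#'
#' Coherence as a filled raster over time and period (log2 axis), with the
#' significance contour at `alpha` (when Monte Carlo p-values are present)
#' and the cone of influence.
#'
#' @param object A `mast_coherence` object.
#' @param alpha Contour level for pointwise significance (default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mast_coherence
#' @export
autoplot.mast_coherence <- function(object, alpha = 0.1, ...) {
  df <- tidy(object)
  coi_df <- tibble(year = object$years, coi = object$coi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$r2)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "coherence") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::geom_line(data = coi_df,
                       ggplot2::aes(x = .data$year, y = .data$coi),
                       colour = "white") +
    ggplot2::labs(x = "Year", y = "Period (years)") +
    ggplot2::theme_minimal()
  if (!is.null(object$pointwise_p)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$pointwise_p), breaks = alpha, colour = "black")
  }
  p
}

#' Plot observed against fitted values of a beta regression
#'
#' @param object A `beta_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_fit
#' @export
autoplot.beta_fit <- function(object, ...) {
  df <- tibble(
    year = object$years %||% seq_along(object$response),
    observed = object$response, fitted = object$fitted_mean
  )
  long <- tidyr::pivot_longer(df, c("observed", "fitted"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Unit-scale masting index", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot out-of-sample LOOCV predictions against observations
#'
#' @param object A `beta_loocv` object from [loocv_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_loocv
#' @export
autoplot.beta_loocv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed", y = "LOOCV prediction") +
    ggplot2::theme_minimal()
}

#' Plot a Spearman correlation map
#'
#' @param object Output tibble of [spearman_map()].
#' @param ... Unused.
#' @return A ggplot object with significant cells dotted.
#' @export
plot_spearman_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$rho)) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman rho") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$significant),
                        size = 0.4) +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}
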