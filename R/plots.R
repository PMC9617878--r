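# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot treatment-effect estimates
#'
#' Posterior means with thick 80% and thin 95% highest-density interval
#' bars, per post-activation year and aggregated, around a zero reference.
#'
#' @param object An `ate_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ate_estimate <- function(object, ...) {
  unit_lab <- if (object$unit[1] == "ha") "ha" else "m²"
  df <- dplyr::mutate(object, year = factor(.data$year,
                                            levels = unique(.data$year)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hpd95_lo,
                                         ymax = .data$hpd95_hi),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hpd80_lo,
                                         ymax = .data$hpd80_hi),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "year since activation",
                  y = paste0("difference in canopy lost (", unit_lab,
                             " per pixel-year)"),
                  title = "Treatment effect: treated minus matched control") +
    ggplot2::theme_minimal()
}

#' Covariate-balance (love) plot
#'
#' Absolute standardised mean differences before and after matching, with
#' the conventional 0.1 reference line.
#'
#' @param object A `balance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("smd_before", "smd_after"),
                            names_to = "stage", values_to = "smd") |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("smd_before", "smd_after"),
                                 labels = c("before", "after")))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$smd), y = .data$variable,
                                   colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "|standardised mean difference|", y = NULL,
                  colour = NULL, title = "Covariate balance") +
    ggplot2::theme_minimal()
}

#' Residual variogram plot with permutation envelope
#'
#' @param object A `variogram_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variogram_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dist / 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$gamma,
                                     colour = .data$outside)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 na.value = "grey60") +
    ggplot2::labs(x = "distance (km)", y = "semivariance",
                  colour = "outside envelope",
                  title = "Residual variogram") +
    ggplot2::theme_minimal()
}

#' Uniform QQ plot of simulated quantile residuals
#'
#' @param object A `residual_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residual_set <- function(object, ...) {
  n <- nrow(object)
  df <- tibble::tibble(theoretical = (seq_len(n) - 0.5) / n,
                       observed = sort(object$residual))
  ggplot2::ggplot(df, ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Uniform(0,1) quantiles", y = "quantile residuals",
                  title = "Simulated quantile residuals") +
    ggplot2::theme_minimal()
}

#' Map a yearly canopy-loss surface
#'
#' @param grid A `canopy_loss_grid`.
#' @param year Year to map.
#' @return A ggplot object (tile map, ha per pixel).
#' @export
plot_canopy_loss <- function(grid, year = 1) {
  col <- paste0("canopy_loss_Y", year)
  stopifnot(col %in% names(grid))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                     fill = .data[[col]] / 1e4)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km", fill = "ha lost",
                  title = paste("Canopy area lost, year", year)) +
    ggplot2::theme_minimal()
}
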