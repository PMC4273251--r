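#' Plot a calibration fit
#'
#' Variance-versus-mean-intensity scatter of the flat-field ladder with the
#' fitted linear noise model overlaid.
#'
#' @param object A `pg_calibration` from [calibrate_alpha()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pg_calibration <- function(object, ...) {
  ggplot2::ggplot(object$levels, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$var_est), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$var_model), colour = "red") +
    ggplot2::labs(
      x = "mean intensity (counts)",
      y = expression(hat(sigma)[eta]^2),
      title = sprintf("Poisson-Gaussian noise calibration: alpha = %.3g, R² = %.4f",
                      object$alpha, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot evaluation curves
#'
#' Metric-versus-noise curves in the style of the quantitative evaluation:
#' absolute MSE / MS-SSIM / sharpness-index values per mode against
#' `1 / alpha` (smaller means noisier), one facet per metric, averaged over
#' phantoms with per-phantom traces.
#'
#' @param object A `bm3d_eval` from [evaluate_curves()].
#' @param metric One of `"mse"`, `"ms_ssim"`, `"si"`, or `"all"` (facets).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bm3d_eval <- function(object, metric = c("all", "mse", "ms_ssim", "si"),
                               ...) {
  metric <- match.arg(metric)
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("mse", "ms_ssim", "si"),
                        names_to = "metric", values_to = "value")
  if (metric != "all") long <- dplyr::filter(long, .data$metric == !!metric)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = 1 / .data$alpha, y = .data$value,
                               colour = .data$mode,
                               group = interaction(.data$mode, .data$phantom_id))) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$mode), fun = mean,
                          geom = "line", linewidth = 1.1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(1 / alpha ~ "(lower = noisier)"),
                  y = NULL, colour = "mode") +
    ggplot2::theme_minimal()
}

#' @export
plot.pg_calibration <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.bm3d_eval <- function(x, ...) print(autoplot(x, ...))
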