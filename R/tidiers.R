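#' Tidy a Poisson-Gaussian calibration fit
#'
#' @param x A `pg_calibration` from [calibrate_alpha()].
#' @param ... Unused.
#' @return One row per flat-field level: mean intensity, estimated and
#'   model-predicted variance, and the fit residual.
#' @export
tidy.pg_calibration <- function(x, ...) {
  dplyr::mutate(x$levels, residual = .data$var_est - .data$var_model)
}

#' @rdname tidy.pg_calibration
#' @return `glance()`: a one-row tibble with `alpha`, `mu_g`, `sigma_g`,
#'   `r_squared` and the number of levels.
#' @export
glance.pg_calibration <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, mu_g = x$params$mu_g,
                 sigma_g = x$params$sigma_g, r_squared = x$r_squared,
                 n_levels = nrow(x$levels))
}

#' Tidy an evaluation table
#'
#' `bm3d_eval` results are already tibbles; `tidy()` strips the class and
#' `glance()` summarises the modified-versus-original comparison.
#'
#' @param x A `bm3d_eval` from [evaluate_curves()].
#' @param ... Unused.
#' @export
tidy.bm3d_eval <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.bm3d_eval
#' @export
glance.bm3d_eval <- function(x, ...) {
  rel <- relative_curves(x)
  tibble::tibble(
    n_runs = nrow(rel),
    frac_mse_improved = mean(rel$mse_ratio <= 1),
    frac_ms_ssim_improved = mean(rel$ms_ssim_ratio >= 1),
    frac_si_improved = mean(rel$si_pct_diff >= 0),
    median_mse_ratio = stats::median(rel$mse_ratio),
    median_ms_ssim_ratio = stats::median(rel$ms_ssim_ratio))
}
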