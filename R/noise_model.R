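#' Poisson-Gaussian noise model parameters
#'
#' The measured pixel value is modelled as
#' \deqn{z(x) = \alpha\,\eta_p(x) + \eta_G(x), \qquad
#'       \eta_p(x) \sim \mathrm{Pois}(y(x)), \quad
#'       \eta_G(x) \sim N(\mu_G, \sigma_G^2),}
#' where \eqn{y(x) \ge 0} is the noise-free ground-truth intensity (expected
#' photon count), `alpha > 0` a detector gain, and the Gaussian term collects
#' signal-independent read-out noise and offset. The first two moments are
#' \eqn{E[z] = \alpha y + \mu_G} and
#' \eqn{\mathrm{Var}[z] = \alpha^2 y + \sigma_G^2}: the variance grows
#' linearly with the signal (heteroscedastic noise).
#'
#' @param alpha Positive gain (detector counts per photon).
#' @param mu_g Gaussian offset, in detector counts.
#' @param sigma_g Gaussian standard deviation, in detector counts
#'   (non-negative).
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(1.2, mu_g = 8, sigma_g = 3)
#' @export
noise_params <- function(alpha, mu_g = 0, sigma_g = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    abort("`alpha` must be a single positive number", class = "pgbm3d_input_error")
  if (!is.numeric(sigma_g) || length(sigma_g) != 1L || sigma_g < 0)
    abort("`sigma_g` must be a single non-negative number", class = "pgbm3d_input_error")
  if (!is.numeric(mu_g) || length(mu_g) != 1L || !is.finite(mu_g))
    abort("`mu_g` must be a single finite number", class = "pgbm3d_input_error")
  structure(list(alpha = alpha, mu_g = mu_g, sigma_g = sigma_g),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> alpha = %g, mu_G = %g, sigma_G = %g\n",
              x$alpha, x$mu_g, x$sigma_g))
  invisible(x)
}

#' Simulate mixed Poisson-Gaussian noise
#'
#' Draws `z(x) = alpha * Pois(y(x)) + N(mu_G, sigma_G^2)` independently per
#' pixel. The Poisson rate is the (possibly non-integer) ground-truth
#' intensity.
#'
#' @param ground_truth Non-negative numeric matrix of ground-truth
#'   intensities `y(x)`.
#' @param params A [noise_params()] object.
#' @param seed Integer seed; the draw is deterministic given `seed` and does
#'   not disturb the caller's RNG state.
#' @return A matrix of the same shape as `ground_truth`.
#' @examples
#' y <- matrix(100, 8, 8)
#' z <- simulate_pg_noise(y, noise_params(2, 0, 3), seed = 1)
#' @export
simulate_pg_noise <- function(ground_truth, params, seed) {
  assert_image(ground_truth, "ground_truth")
  stopifnot(inherits(params, "noise_params"))
  neg <- which(ground_truth < 0)
  if (length(neg)) {
    ij <- arrayInd(neg[1L], dim(ground_truth))
    abort(sprintf("ground truth must be non-negative; first negative pixel at (row %d, col %d)",
                  ij[1L], ij[2L]),
          class = "pgbm3d_input_error")
  }
  n <- length(ground_truth)
  z <- withr::with_seed(as.integer(seed), {
    params$alpha * rpois(n, lambda = as.vector(ground_truth)) +
      rnorm(n, mean = params$mu_g, sd = params$sigma_g)
  })
  matrix(z, nrow(ground_truth), ncol(ground_truth))
}

#' Population variance of a flat-field image
#'
#' Estimates the noise variance of an image of a homogeneous sample by
#' subtracting the mean intensity from the measured values:
#' \eqn{\hat\sigma_\eta^2 = |X|^{-1} \sum_x (z(x) - \bar z)^2}, with the
#' population normalization `1/|X|`.
#'
#' @param flat_field Numeric matrix.
#' @return Single non-negative number.
#' @export
estimate_noise_variance <- function(flat_field) {
  assert_image(flat_field, "flat_field")
  mean((flat_field - mean(flat_field))^2)
}

#' Estimate the Gaussian noise component from dark frames
#'
#' Dark frames are recorded at zero excitation power, so the Poisson term
#' vanishes and the pixel statistics are those of the Gaussian component
#' alone. Statistics are pooled over the concatenation of all pixels of all
#' frames.
#'
#' @param dark_images A single matrix or a list of matrices.
#' @return A list with elements `mu_g` (pooled mean) and `sigma_g` (pooled
#'   population standard deviation).
#' @export
estimate_gaussian_params <- function(dark_images) {
  if (is.matrix(dark_images)) dark_images <- list(dark_images)
  if (!is.list(dark_images) || length(dark_images) == 0L)
    abort("at least one dark image is required", class = "pgbm3d_input_error")
  purrr::walk(dark_images, assert_image, arg = "dark image")
  px <- unlist(lapply(dark_images, as.vector), use.names = FALSE)
  mu <- mean(px)
  list(mu_g = mu, sigma_g = sqrt(mean((px - mu)^2)))
}

#' Bundle a noise-calibration series
#'
#' @param flat_fields List of flat-field images (homogeneous sample recorded
#'   at increasing excitation power).
#' @param levels Optional numeric vector of excitation levels, parallel to
#'   `flat_fields` (informational; the fit uses measured mean intensities).
#' @param darks List of dark frames (zero excitation).
#' @return Object of class `calibration_series`.
#' @export
calibration_series <- function(flat_fields, levels = NULL, darks = list()) {
  if (is.matrix(flat_fields)) flat_fields <- list(flat_fields)
  purrr::walk(flat_fields, assert_image, arg = "flat field")
  if (is.matrix(darks)) darks <- list(darks)
  if (!is.null(levels) && length(levels) != length(flat_fields))
    abort("`levels` must be parallel to `flat_fields`", class = "pgbm3d_input_error")
  structure(list(flat_fields = flat_fields, levels = levels, darks = darks),
            class = "calibration_series")
}

#' Calibrate the gain alpha from a flat-field ladder
#'
#' Per-level mean intensity and variance are computed from each flat field,
#' and the variance law `Var = alpha * (mean - mu_G) + sigma_G^2` is fitted
#' by unweighted least squares for the slope `alpha` (the Gaussian intercept
#' being fixed by the dark-frame calibration). The coefficient of
#' determination is reported against the per-level variance estimates.
#'
#' @param series A [calibration_series()].
#' @param gaussian List with `mu_g`, `sigma_g`, e.g. from
#'   [estimate_gaussian_params()].
#' @return Object of class `pg_calibration`: fields `alpha`, `r_squared`,
#'   `params` (a [noise_params()]) and `levels` (a tibble with one row per
#'   flat-field level). Supports [tidy()], [glance()] and [autoplot()].
#' @export
calibrate_alpha <- function(series, gaussian) {
  stopifnot(inherits(series, "calibration_series"))
  if (length(series$flat_fields) < 2L)
    abort("at least 2 flat-field levels are required to fit alpha",
          class = "pgbm3d_input_error")
  m <- vapply(series$flat_fields, mean, numeric(1))
  v <- vapply(series$flat_fields, estimate_noise_variance, numeric(1))
  if (max(m) - min(m) < sqrt(.Machine$double.eps) * max(1, abs(max(m))))
    abort("all flat-field mean intensities are identical; the fit is degenerate",
          class = "pgbm3d_input_error")
  x <- m - gaussian$mu_g
  y <- v - gaussian$sigma_g^2
  alpha <- sum(x * y) / sum(x * x)
  pred <- alpha * x + gaussian$sigma_g^2
  ss_res <- sum((v - pred)^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    alpha = alpha,
    r_squared = r2,
    params = noise_params(alpha, gaussian$mu_g, gaussian$sigma_g),
    levels = tibble::tibble(mean = m, var_est = v, var_model = pred)
  ), class = "pg_calibration")
}

#' @export
print.pg_calibration <- function(x, ...) {
  cat(sprintf("<pg_calibration> alpha = %.4g (R^2 = %.4f) over %d flat-field levels\n",
              x$alpha, x$r_squared, nrow(x$levels)))
  invisible(x)
}

#' Variance-versus-intensity curve of a calibration series
#'
#' One row per flat-field level: the measured mean intensity, the estimated
#' noise variance, and the variance predicted by the calibrated model
#' `alpha * (mean - mu_G) + sigma_G^2`.
#'
#' @param series A [calibration_series()].
#' @param params Calibrated [noise_params()], or a `pg_calibration` object.
#' @return A tibble with columns `mean`, `var_est`, `var_model`.
#' @export
variance_vs_intensity_curve <- function(series, params) {
  stopifnot(inherits(series, "calibration_series"))
  if (inherits(params, "pg_calibration")) params <- params$params
  stopifnot(inherits(params, "noise_params"))
  if (length(series$flat_fields) == 0L)
    return(tibble::tibble(mean = numeric(), var_est = numeric(), var_model = numeric()))
  m <- vapply(series$flat_fields, mean, numeric(1))
  v <- vapply(series$flat_fields, estimate_noise_variance, numeric(1))
  tibble::tibble(
    mean = m,
    var_est = v,
    var_model = params$alpha * (m - params$mu_g) + params$sigma_g^2
  )
}
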