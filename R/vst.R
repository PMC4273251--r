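#' Generalized Anscombe variance-stabilizing transform
#'
#' Applies
#' \deqn{f(z) = \frac{2}{\alpha}\sqrt{\alpha z + \tfrac{3}{8}\alpha^2 +
#'   \sigma_G^2 - \alpha\mu_G}}
#' pixel-wise, with the radicand clamped at zero. Under the Poisson-Gaussian
#' model the transformed noise is approximately additive white Gaussian with
#' unit variance, which is the regime the BM3D filter assumes.
#'
#' @param z Numeric matrix of raw detector counts.
#' @param params A [noise_params()] object.
#' @return Matrix of stabilized values.
#' @examples
#' generalized_anscombe(matrix(0), noise_params(1)) # 2 * sqrt(3/8)
#' @export
generalized_anscombe <- function(z, params) {
  assert_image(z, "z")
  stopifnot(inherits(params, "noise_params"))
  a <- params$alpha
  rad <- a * z + 0.375 * a^2 + params$sigma_g^2 - a * params$mu_g
  (2 / a) * sqrt(pmax(rad, 0))
}

# Forward transform of a scalar/vector in the z domain (shared internal).
ga_forward <- function(z, params) {
  a <- params$alpha
  (2 / a) * sqrt(pmax(a * z + 0.375 * a^2 + params$sigma_g^2 - a * params$mu_g, 0))
}

#' Build the exact unbiased inverse table of the generalized Anscombe VST
#'
#' The exact unbiased inverse maps a denoised stabilized value `D` back to the
#' intensity `y` solving `E[f(z) | y] = D`, where the expectation runs over
#' the Poisson-Gaussian law. This function tabulates `E[f(z) | y]` on a grid
#' of intensities: the Poisson sum is truncated where its tail mass falls
#' below `1e-12` and the Gaussian component is integrated by Gauss-Hermite
#' quadrature. The resulting table is checked for strict monotonicity.
#'
#' @param params A [noise_params()] object.
#' @param y_grid Increasing non-negative intensities at which to tabulate.
#'   Defaults to 512 log-spaced values spanning `[0, 1.5 * y_max]`.
#' @param y_max Upper end of the working intensity range (used only when
#'   `y_grid` is `NULL`).
#' @param n_quad Number of Gauss-Hermite nodes for the Gaussian integral.
#' @return Object of class `vst_spec` holding `params`, the grid and the
#'   tabulated expected forward values.
#' @export
build_exact_inverse_table <- function(params, y_grid = NULL, y_max = 4095,
                                      n_quad = 31) {
  stopifnot(inherits(params, "noise_params"))
  if (is.null(y_grid)) {
    hi <- 1.5 * y_max
    y_grid <- c(0, exp(seq(log(1e-2), log(hi), length.out = 511)))
  }
  if (is.unsorted(y_grid, strictly = TRUE) || any(y_grid < 0))
    abort("`y_grid` must be strictly increasing and non-negative",
          class = "pgbm3d_input_error")
  gh <- if (params$sigma_g > 0) pracma::gaussHermite(n_quad) else NULL
  ef <- vapply(y_grid, function(y) ga_expectation(y, params, gh), numeric(1))
  if (is.unsorted(ef, strictly = TRUE)) {
    bad <- which(diff(ef) <= 0)[1L]
    abort(sprintf(
      "tabulated E[f(z)|y] is not strictly increasing near y = %.6g (entries %g, %g); refine the grid",
      y_grid[bad], ef[bad], ef[bad + 1L]), class = "pgbm3d_numeric_error")
  }
  structure(list(params = params, y_grid = y_grid, e_forward = ef),
            class = "vst_spec")
}

# E[f(z) | y] for one intensity; Poisson tail truncated at 1e-12 mass,
# Gaussian handled by Gauss-Hermite nodes (or exactly when sigma_G = 0).
ga_expectation <- function(y, params, gh) {
  if (y == 0) {
    k <- 0L
    w <- 1
  } else {
    k <- seq(qpois(1e-12, y), qpois(1 - 1e-12, y))
    w <- dpois(k, y)
  }
  zk <- params$alpha * k + params$mu_g
  if (is.null(gh)) {
    fe <- ga_forward(zk, params)
  } else {
    # z = alpha k + mu_G + sqrt(2) sigma_G t, t the Hermite nodes
    zg <- outer(zk, sqrt(2) * params$sigma_g * gh$x, `+`)
    fe <- as.vector(ga_forward(zg, params) %*% gh$w) / sqrt(pi)
  }
  sum(w * fe) / sum(w)
}

#' @export
print.vst_spec <- function(x, ...) {
  cat(sprintf("<vst_spec> alpha = %g, mu_G = %g, sigma_G = %g; %d grid points over y in [%g, %g]\n",
              x$params$alpha, x$params$mu_g, x$params$sigma_g,
              length(x$y_grid), min(x$y_grid), max(x$y_grid)))
  invisible(x)
}

#' Exact unbiased inverse of the generalized Anscombe transform
#'
#' Inverts the tabulated map `y -> E[f(z)|y]` by monotone piecewise-cubic
#' interpolation. Stabilized values below the table minimum map to 0;
#' values above the maximum continue with the asymptotic inverse.
#'
#' @param stabilized Matrix of denoised stabilized values.
#' @param spec A `vst_spec` from [build_exact_inverse_table()].
#' @param params Optional [noise_params()]; when supplied it must match the
#'   parameters the table was built with.
#' @return Matrix of intensities (the `y` domain), non-negative.
#' @export
exact_unbiased_inverse <- function(stabilized, spec, params = NULL) {
  assert_image(stabilized, "stabilized")
  stopifnot(inherits(spec, "vst_spec"))
  if (!is.null(params)) {
    p <- spec$params
    if (!isTRUE(all.equal(unclass(p), unclass(params))))
      abort("`params` does not match the parameters `spec` was built with",
            class = "pgbm3d_input_error")
  }
  inv <- splinefun(spec$e_forward, spec$y_grid, method = "hyman")
  d <- as.vector(stabilized)
  out <- numeric(length(d))
  lo <- d <= spec$e_forward[1L]
  hi <- d >= spec$e_forward[length(spec$e_forward)]
  mid <- !lo & !hi
  out[lo] <- 0
  out[mid] <- pmax(inv(d[mid]), 0)
  if (any(hi)) {
    cont <- asymptotic_inverse(matrix(d[hi], nrow = 1L), spec$params)
    out[hi] <- as.vector(cont)
  }
  matrix(out, nrow(stabilized), ncol(stabilized))
}

#' Algebraic and asymptotically unbiased inverses of the generalized Anscombe
#' transform
#'
#' Closed-form baselines for comparison with the exact unbiased inverse. The
#' algebraic inverse solves `f(z) = D` for the clean measurement and converts
#' it to the intensity domain: `y = ((alpha D / 2)^2 - (3/8) alpha^2 -
#' sigma_G^2) / alpha^2`, clamped at 0. The asymptotically unbiased inverse
#' adds the classical `+1/4` correction in the intensity domain (reducing to
#' `(D/2)^2 - 1/8` for pure Poisson noise at `alpha = 1`).
#'
#' @param stabilized Matrix of stabilized values.
#' @param params A [noise_params()] object.
#' @return Matrix of intensities, clamped at 0.
#' @export
algebraic_inverse <- function(stabilized, params) {
  assert_image(stabilized, "stabilized")
  stopifnot(inherits(params, "noise_params"))
  a <- params$alpha
  pmax(((a * stabilized / 2)^2 - 0.375 * a^2 - params$sigma_g^2) / a^2, 0)
}

#' @rdname algebraic_inverse
#' @export
asymptotic_inverse <- function(stabilized, params) {
  assert_image(stabilized, "stabilized")
  stopifnot(inherits(params, "noise_params"))
  a <- params$alpha
  pmax(((a * stabilized / 2)^2 - 0.375 * a^2 - params$sigma_g^2) / a^2 + 0.25, 0)
}

#' Robust noise-level estimate for (approximately) AWGN images
#'
#' Median-absolute-deviation estimator on the finest diagonal Haar details
#' (`(z11 - z12 - z21 + z22) / 2` over disjoint 2 x 2 cells), the standard
#' robust sigma estimate for white noise. Used to measure the effective
#' noise standard deviation of a stabilized image: the generalized Anscombe
#' transform promises unit variance, but under-stabilizes below a few
#' photons per pixel, and the matching and shrinkage thresholds adapt to
#' the measured value.
#'
#' @param img Numeric matrix (at least 2 x 2).
#' @return Estimated noise standard deviation.
#' @export
estimate_awgn_sigma <- function(img) {
  assert_image(img, "img")
  n <- 2L * (nrow(img) %/% 2L); m <- 2L * (ncol(img) %/% 2L)
  if (n < 2L || m < 2L)
    abort("image too small for a noise estimate", class = "pgbm3d_input_error")
  x <- img[seq_len(n), seq_len(m), drop = FALSE]
  hh <- (x[seq(1, n, 2), seq(1, m, 2)] - x[seq(1, n, 2), seq(2, m, 2)] -
           x[seq(2, n, 2), seq(1, m, 2)] + x[seq(2, n, 2), seq(2, m, 2)]) / 2
  stats::median(abs(hh)) / 0.6744898
}

#' Serialize / restore a VST specification as JSON
#'
#' Runs are bit-reproducible when the inverse table is carried alongside the
#' result; these helpers write and read the table (parameters + grid) as
#' plain JSON.
#'
#' @param spec A `vst_spec`.
#' @param path File path.
#' @return `read_vst_spec()` returns the restored `vst_spec`;
#'   `write_vst_spec()` returns `path` invisibly.
#' @export
write_vst_spec <- function(spec, path) {
  stopifnot(inherits(spec, "vst_spec"))
  jsonlite::write_json(
    list(params = unclass(spec$params), y_grid = spec$y_grid,
         e_forward = spec$e_forward),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vst_spec
#' @export
read_vst_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    params = noise_params(x$params$alpha, x$params$mu_g, x$params$sigma_g),
    y_grid = as.numeric(x$y_grid),
    e_forward = as.numeric(x$e_forward)
  ), class = "vst_spec")
}
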