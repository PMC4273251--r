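#' Mean squared error between two images
#' @param a,b Numeric matrices of equal shape.
#' @return Non-negative scalar; 0 iff the images are identical.
#' @export
mse <- function(a, b) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b)))
    abort("images must have identical shapes", class = "pgbm3d_input_error")
  mean((a - b)^2)
}

#' Multiscale structural similarity (MS-SSIM)
#'
#' The multiscale SSIM of Wang, Simoncelli and Bovik: contrast/structure
#' terms are computed at `scales` dyadic scales (2 x 2 average-pool
#' downsampling between scales) and combined with the luminance term at the
#' coarsest scale using the published exponent weights. An 11 x 11 Gaussian
#' window (sd 1.5) with "valid" support and stability constants
#' `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` are used, where `L` is the dynamic
#' range.
#'
#' @param a,b Numeric matrices of equal shape, at least
#'   `window * 2^(scales - 1)` pixels per side.
#' @param dynamic_range Intensity range `L` of the data (positive). Defaults
#'   to the range of `a`.
#' @param scales Number of dyadic scales (default 5).
#' @param weights Per-scale exponents (default the published five).
#' @param window,window_sigma Gaussian window size and sd.
#' @param k1,k2 Stability constants.
#' @return A number in (-1, 1]; exactly 1 when `a` equals `b`.
#' @export
ms_ssim <- function(a, b, dynamic_range = NULL, scales = 5,
                    weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                    window = 11, window_sigma = 1.5,
                    k1 = 0.01, k2 = 0.03) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b)))
    abort("images must have identical shapes", class = "pgbm3d_input_error")
  stopifnot(length(weights) == scales)
  min_side <- window * 2^(scales - 1)
  if (min(dim(a)) < min_side)
    abort(sprintf("images must be at least %d pixels per side for %d scales",
                  min_side, scales), class = "pgbm3d_input_error")
  L <- dynamic_range %||% diff(range(a))
  if (is.null(L) || L <= 0) L <- 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  kern <- gaussian_kernel(window_sigma, radius = (window - 1) / 2)

  mcs <- numeric(scales)
  msim <- NA_real_
  for (s in seq_len(scales)) {
    st <- ssim_terms(a, b, kern, c1, c2)
    mcs[s] <- st$cs
    if (s == scales) msim <- st$ssim
    if (s < scales) {
      a <- downsample2(a)
      b <- downsample2(b)
    }
  }
  # sign-preserving powers keep rare negative means well-defined
  spow <- function(v, w) sign(v) * abs(v)^w
  prod(spow(mcs[-scales], weights[-scales])) * spow(msim, weights[scales])
}

ssim_terms <- function(a, b, kern, c1, c2) {
  Tr <- conv_matrix(nrow(a), kern, "valid")
  Tc <- conv_matrix(ncol(a), kern, "valid")
  f <- function(x) Tr %*% x %*% t(Tc)
  mu1 <- f(a); mu2 <- f(b)
  s11 <- f(a * a) - mu1^2
  s22 <- f(b * b) - mu2^2
  s12 <- f(a * b) - mu1 * mu2
  cs_map <- (2 * s12 + c2) / (s11 + s22 + c2)
  l_map <- (2 * mu1 * mu2 + c1) / (mu1^2 + mu2^2 + c1)
  list(cs = mean(cs_map), ssim = mean(l_map * cs_map))
}

downsample2 <- function(x) {
  n <- 2L * (nrow(x) %/% 2L); m <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(n), seq_len(m), drop = FALSE]
  (x[seq(1, n, 2), seq(1, m, 2)] + x[seq(2, n, 2), seq(1, m, 2)] +
     x[seq(1, n, 2), seq(2, m, 2)] + x[seq(2, n, 2), seq(2, m, 2)]) / 4
}

#' Gradient-energy sharpness index
#'
#' Mean squared gradient magnitude obtained with 3 x 3 Sobel operators,
#' normalized by the mean squared intensity so the measure is invariant to
#' multiplying the image by a positive constant. This is the gradient-energy
#' autofocus measure commonly used for automated focusing of light
#' microscopes; higher values indicate sharper images. It is intended for
#' comparative use (same scene, different reconstructions).
#'
#' @param img Numeric matrix.
#' @return Non-negative scalar; 0 for a constant image.
#' @export
sharpness_index <- function(img) {
  assert_image(img, "img")
  if (nrow(img) < 3L || ncol(img) < 3L || mean(img^2) == 0) return(0)
  smooth <- c(1, 2, 1) / 4
  diffk <- c(1, 0, -1) / 2
  Sr <- conv_matrix(nrow(img), smooth, "valid")
  Dr <- conv_matrix(nrow(img), diffk, "valid")
  Sc <- conv_matrix(ncol(img), smooth, "valid")
  Dc <- conv_matrix(ncol(img), diffk, "valid")
  gx <- Sr %*% img %*% t(Dc)  # horizontal gradient
  gy <- Dr %*% img %*% t(Sc)  # vertical gradient
  mean(gx^2 + gy^2) / mean(img^2)
}

#' Relative modified-versus-original curves
#'
#' Pairs the two modes of an [evaluate_curves()] table per phantom and gain
#' and derives the relative quantities plotted in the evaluation figures:
#' MSE and MS-SSIM ratios (modified / original) and the percent difference
#' of the sharpness index.
#'
#' @param results A `bm3d_eval` tibble (or any tibble with columns
#'   `phantom_id`, `alpha`, `mode`, `mse`, `ms_ssim`, `si`).
#' @return Tibble with one row per phantom x alpha and columns `mse_ratio`,
#'   `ms_ssim_ratio`, `si_pct_diff`.
#' @export
relative_curves <- function(results) {
  need <- c("phantom_id", "alpha", "mode", "mse", "ms_ssim", "si")
  if (!all(need %in% names(results)))
    abort("`results` must carry phantom_id/alpha/mode/mse/ms_ssim/si columns",
          class = "pgbm3d_input_error")
  wide <- results |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "mode",
                       values_from = c("mse", "ms_ssim", "si"))
  need_wide <- c("mse_modified", "mse_original", "ms_ssim_modified",
                 "ms_ssim_original", "si_modified", "si_original")
  if (!all(need_wide %in% names(wide)) ||
      anyNA(wide[need_wide]))
    abort("every (phantom_id, alpha) must have exactly one row per mode",
          class = "pgbm3d_input_error")
  wide |>
    dplyr::transmute(
      .data$phantom_id, .data$alpha,
      mse_ratio = .data$mse_modified / .data$mse_original,
      ms_ssim_ratio = .data$ms_ssim_modified / .data$ms_ssim_original,
      si_pct_diff = 100 * (.data$si_modified - .data$si_original) /
        .data$si_original)
}
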