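#' Data-adaptive Bayes threshold for one wavelet subband
#'
#' Following the BayesShrink estimator, the clean-signal standard deviation
#' of a subband is estimated from the noisy coefficients as
#' \eqn{\hat\sigma_y = \sqrt{\max(\hat\sigma_z^2 - \sigma^2, 0)}} with
#' \eqn{\hat\sigma_z^2} the mean squared coefficient, and the threshold is
#' \deqn{Th_\mathrm{Bayes} = \sigma^2 / \hat\sigma_y.}
#' A subband indistinguishable from pure noise (\eqn{\hat\sigma_y = 0})
#' returns `Inf` and is zeroed entirely. Unlike the original BayesShrink use
#' with soft thresholding, the denoiser applies this value as a hard
#' threshold.
#'
#' @param coefficients Numeric vector (or array) of the subband's
#'   coefficients.
#' @param sigma Noise standard deviation per coefficient (positive; the
#'   transforms are orthonormal so the pixel-domain value carries over).
#' @return The threshold (possibly `Inf`).
#' @examples
#' bayes_threshold(c(sqrt(2), -sqrt(2)), 1) # sigma_y = 1 -> threshold 1
#' @export
bayes_threshold <- function(coefficients, sigma) {
  if (length(coefficients) == 0L)
    abort("subband is empty", class = "pgbm3d_input_error")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    abort("`sigma` must be a single positive number", class = "pgbm3d_input_error")
  ms <- mean(coefficients^2)
  sy2 <- ms - sigma^2
  if (sy2 <= 0) Inf else sigma^2 / sqrt(sy2)
}

#' Hard-threshold a transformed block stack
#'
#' Sets to zero every coefficient whose magnitude is strictly below its
#' subband's threshold (equality survives). In `"bayes"` mode the threshold
#' is computed per subband by [bayes_threshold()]; in `"fixed"` mode (the
#' original-BM3D baseline) a single threshold `lambda * sigma` applies to
#' all detail coefficients. The protected DC subband is never thresholded in
#' either mode.
#'
#' @param coefficients 3D coefficient array matching `map`.
#' @param map A [subband_partition()].
#' @param sigma Noise standard deviation per coefficient.
#' @param mode `"bayes"` or `"fixed"`.
#' @param lambda Multiplier for the fixed threshold (default 2.7, the
#'   published BM3D hard-thresholding value).
#' @return List with `coefficients` (thresholded array) and
#'   `retained_count` (number of surviving coefficient positions).
#' @export
hard_threshold_stack <- function(coefficients, map, sigma,
                                 mode = c("bayes", "fixed"), lambda = 2.7) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "subband_map"))
  if (!identical(dim(coefficients), dim(map$labels)))
    abort("`coefficients` shape does not match `map`", class = "pgbm3d_input_error")
  labs <- map$labels
  th <- if (mode == "bayes") {
    vapply(seq_len(nrow(map$subbands)), function(s)
      bayes_threshold(coefficients[labs == s], max(sigma, .Machine$double.xmin)),
      numeric(1))
  } else {
    rep(lambda * sigma, nrow(map$subbands))
  }
  th[map$subbands$protected] <- -Inf
  kill <- abs(coefficients) < th[labs]
  out <- coefficients
  out[kill] <- 0
  list(coefficients = out, retained_count = sum(!kill))
}

#' Empirical Wiener filtering of a transformed stack against a pilot
#'
#' Per-coefficient shrinkage `W = P^2 / (P^2 + sigma^2)` where `P` is the
#' pilot (basic-estimate) coefficient; the output coefficient is `W` times
#' the noisy coefficient. The accumulated `sum(W^2)` is the Wiener energy
#' used for aggregation weighting.
#'
#' @param noisy,pilot Coefficient arrays of identical shape.
#' @param sigma Noise standard deviation per coefficient (positive).
#' @return List with `coefficients` and `wiener_energy`.
#' @export
wiener_filter_stack <- function(noisy, pilot, sigma) {
  if (!identical(dim(noisy), dim(pilot)))
    abort("`noisy` and `pilot` must have identical shapes", class = "pgbm3d_input_error")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    abort("`sigma` must be a single positive number", class = "pgbm3d_input_error")
  p2 <- pilot^2
  w <- p2 / (p2 + sigma^2)
  list(coefficients = w * noisy, wiener_energy = sum(w^2))
}

#' Aggregate overlapping filtered block groups into an image
#'
#' Accumulates a per-pixel numerator and weight buffer over all filtered
#' blocks and divides; each group contributes with one scalar weight
#' (`1 / retained_count` after hard thresholding, `1 / wiener_energy` after
#' Wiener filtering). Pixels never covered by any block are copied from
#' `input` when given, else set to 0.
#'
#' @param groups List of groups; each a list with `stack` (pixel-domain
#'   `b x b x n` array), `coords` (n x 2 matrix of 1-based top-left
#'   corners) and `weight` (positive scalar).
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param input Optional matrix supplying uncovered pixels.
#' @return Matrix of dimension `image_shape`.
#' @export
aggregate_blocks <- function(groups, image_shape, input = NULL) {
  num <- matrix(0, image_shape[1L], image_shape[2L])
  den <- matrix(0, image_shape[1L], image_shape[2L])
  for (g in groups) {
    b <- dim(g$stack)[1L]
    for (k in seq_len(dim(g$stack)[3L])) {
      r <- g$coords[k, 1L]; c <- g$coords[k, 2L]
      if (r < 1L || c < 1L || r + b - 1L > image_shape[1L] ||
          c + b - 1L > image_shape[2L])
        abort("block out of image bounds during aggregation",
              class = "pgbm3d_input_error")
      rows <- r:(r + b - 1L); cols <- c:(c + b - 1L)
      num[rows, cols] <- num[rows, cols] + g$weight * g$stack[, , k]
      den[rows, cols] <- den[rows, cols] + g$weight
    }
  }
  out <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  if (!is.null(input)) out[den == 0] <- input[den == 0]
  out
}
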