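#' Block-matching geometry
#'
#' @param block_size Pixels per block side (square blocks).
#' @param step Sliding stride of the reference-block lattice, in pixels. The
#'   lattice always includes the last valid row/column so that image borders
#'   are covered.
#' @param search_radius Half-width of the square search window around the
#'   reference block, in pixels.
#' @param max_group Maximum number of blocks per group; must be a power of
#'   two so the 1D transform across the stack stays dyadic.
#' @return Object of class `block_spec`.
#' @export
block_spec <- function(block_size = 8, step = 3, search_radius = 19,
                       max_group = 16) {
  if (block_size < 2) abort("`block_size` must be >= 2", class = "pgbm3d_input_error")
  if (step < 1 || step > block_size)
    abort("`step` must satisfy 1 <= step <= block_size", class = "pgbm3d_input_error")
  if (!is_power_of_two(max_group))
    abort("`max_group` must be a power of two >= 1", class = "pgbm3d_input_error")
  if (search_radius < 0) abort("`search_radius` must be >= 0", class = "pgbm3d_input_error")
  structure(list(block_size = as.integer(block_size), step = as.integer(step),
                 search_radius = as.integer(search_radius),
                 max_group = as.integer(max_group)),
            class = "block_spec")
}

#' Noise-adaptive block-matching thresholds
#'
#' For two noisy blocks sharing the same ground truth, the variance of their
#' pixel difference is `2 * sigma_eta^2` (Bienaymé). Allowing in addition a
#' bounded ground-truth dissimilarity `Th_offset` gives the level-1 matching
#' threshold
#' \deqn{Th_{BM} = 2\sigma_\eta^2 + Th_\mathrm{offset}.}
#' At level 2 matching runs on the basic estimate, in which the residual
#' noise variance has dropped to a fraction `reduction` (about 30\%) of the
#' input's, so the noise term is scaled accordingly:
#' \deqn{Th_{BM} = 2\,\mathrm{reduction}\,\sigma_\eta^2 + Th_\mathrm{offset}.}
#'
#' @param sigma_eta_sq Noise variance of the signal being matched
#'   (stabilized units squared).
#' @param th_offset Upper limit for the ground-truth mean squared pixel
#'   difference between blocks still considered similar. Default 900.
#' @param reduction Fraction of the noise variance remaining in the basic
#'   estimate (level 2 only), default 0.3.
#' @return The matching threshold, commensurable with [block_distance()].
#' @examples
#' th_bm_level1(0, 900)   # 900
#' th_bm_level2(100, 900) # 960
#' @export
th_bm_level1 <- function(sigma_eta_sq, th_offset = 900) {
  if (sigma_eta_sq < 0 || th_offset < 0)
    abort("threshold inputs must be non-negative", class = "pgbm3d_input_error")
  2 * sigma_eta_sq + th_offset
}

#' @rdname th_bm_level1
#' @export
th_bm_level2 <- function(sigma_eta_sq, th_offset = 900, reduction = 0.3) {
  if (sigma_eta_sq < 0 || th_offset < 0)
    abort("threshold inputs must be non-negative", class = "pgbm3d_input_error")
  if (reduction <= 0 || reduction > 1)
    abort("`reduction` must lie in (0, 1]", class = "pgbm3d_input_error")
  2 * reduction * sigma_eta_sq + th_offset
}

#' Matching-threshold bundle
#'
#' Convenience container pairing the noise variance, offset and level, with
#' the resulting threshold value precomputed.
#'
#' @inheritParams th_bm_level1
#' @param level 1 or 2.
#' @inheritParams th_bm_level2
#' @export
match_threshold <- function(sigma_eta_sq = 1, th_offset = 900, level = 1,
                            reduction = 0.3) {
  stopifnot(level %in% c(1, 2))
  th <- if (level == 1) th_bm_level1(sigma_eta_sq, th_offset)
        else th_bm_level2(sigma_eta_sq, th_offset, reduction)
  structure(list(sigma_eta_sq = sigma_eta_sq, th_offset = th_offset,
                 level = level, reduction = reduction, th = th),
            class = "match_threshold")
}

#' Per-pixel mean squared difference between two blocks
#'
#' `mean((b1 - b2)^2)`, the normalization that makes distances commensurable
#' with the matching thresholds (which are variances of the pixel
#' difference).
#'
#' @param b1,b2 Numeric matrices of equal shape.
#' @export
block_distance <- function(b1, b2) {
  assert_image(b1, "b1"); assert_image(b2, "b2")
  if (!all(dim(b1) == dim(b2)))
    abort("blocks must have identical shapes", class = "pgbm3d_input_error")
  mean((b1 - b2)^2)
}

as_threshold_value <- function(threshold) {
  if (inherits(threshold, "match_threshold")) threshold$th
  else if (is.numeric(threshold) && length(threshold) == 1L) threshold
  else abort("`threshold` must be a number or a match_threshold object",
             class = "pgbm3d_input_error")
}

#' Find blocks similar to a reference block
#'
#' Scans all candidate positions on the step lattice inside the search
#' window (clipped to the image, with the last row/column appended so
#' borders are covered), keeps candidates whose [block_distance()] to the
#' reference is at most the threshold, sorts them by increasing distance
#' (ties broken by raster order), and truncates the group to the largest
#' power of two not exceeding `max_group`. The reference block is always the
#' first member.
#'
#' @param image Numeric matrix.
#' @param ref Integer vector `c(row, col)`: 1-based top-left corner of the
#'   reference block.
#' @param spec A [block_spec()].
#' @param threshold A [match_threshold()] or a plain numeric threshold.
#' @return Object of class `block_group`: `coords` (n x 2 matrix, 1-based
#'   top-left corners, reference first), `dist` (non-decreasing distances),
#'   `stack` (`block_size x block_size x n` array) and `reference_index`
#'   (always 1).
#' @export
find_similar_blocks <- function(image, ref, spec, threshold) {
  assert_image(image)
  stopifnot(inherits(spec, "block_spec"))
  b <- spec$block_size
  ref <- as.integer(ref)
  if (length(ref) != 2L || any(ref < 1L) ||
      ref[1L] + b - 1L > nrow(image) || ref[2L] + b - 1L > ncol(image))
    abort("reference block is out of image bounds", class = "pgbm3d_input_error")
  m <- cpp_find_matches(image, ref[1L] - 1L, ref[2L] - 1L, b, spec$step,
                        spec$search_radius, spec$max_group,
                        as_threshold_value(threshold))
  new_block_group(image, m$coords + 1L, m$dist, b)
}

new_block_group <- function(image, coords, dist, b) {
  n <- nrow(coords)
  stack <- array(0, dim = c(b, b, n))
  for (k in seq_len(n))
    stack[, , k] <- image[coords[k, 1L]:(coords[k, 1L] + b - 1L),
                          coords[k, 2L]:(coords[k, 2L] + b - 1L)]
  structure(list(coords = coords, dist = dist, stack = stack,
                 reference_index = 1L),
            class = "block_group")
}

#' @export
print.block_group <- function(x, ...) {
  cat(sprintf("<block_group> %d block(s) of %d x %d, reference at (%d, %d)\n",
              dim(x$stack)[3L], dim(x$stack)[1L], dim(x$stack)[2L],
              x$coords[1L, 1L], x$coords[1L, 2L]))
  invisible(x)
}

#' Dual-stack block matching against a pilot image
#'
#' Matching decisions are computed on the pilot (the cleaner basic estimate)
#' only; the selected coordinates then extract one stack from the noisy
#' image and one from the pilot, as level 2 of the denoiser requires.
#'
#' @param noisy,pilot Numeric matrices of identical shape.
#' @inheritParams find_similar_blocks
#' @return List with elements `noisy` and `pilot`, two [find_similar_blocks()]
#'   style groups sharing identical `coords`.
#' @export
find_similar_blocks_pilot <- function(noisy, pilot, ref, spec, threshold) {
  assert_image(noisy, "noisy"); assert_image(pilot, "pilot")
  if (!all(dim(noisy) == dim(pilot)))
    abort("`noisy` and `pilot` must have identical shapes", class = "pgbm3d_input_error")
  g <- find_similar_blocks(pilot, ref, spec, threshold)
  list(noisy = new_block_group(noisy, g$coords, g$dist, spec$block_size),
       pilot = g)
}
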