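# Sparse-domain transforms: non-standard 2D Haar analysis of blocks, 1D Haar
# across the stack, and the subband bookkeeping used by the adaptive
# thresholding. All transforms are orthonormal, so unit pixel-domain noise
# variance carries over to unit variance per coefficient.

# Dyadic band of a 0-based coordinate under full-depth analysis of length n:
# 0 = scaling position, l >= 1 = detail level (1 = finest).
dyadic_band <- function(i, n) {
  out <- integer(length(i))
  l <- 1L
  hi <- n
  repeat {
    lo <- hi / 2
    out[i >= lo & i < hi & out == 0L & i > 0L] <- l
    if (lo <= 1) break
    hi <- lo
    l <- l + 1L
  }
  out
}

#' Subband partition of a transformed block stack
#'
#' Labels every coefficient of a `block_size x block_size x n_blocks`
#' transform array with its subband. The 2D part follows the non-standard
#' (Mallat quadrant) decomposition at full depth: on an 8 x 8 block this
#' yields 3 levels x 3 orientations (LH, HL, HH) plus one scaling (LL)
#' subband. `stack_pooling` sets how the stack axis combines with the 2D
#' subbands:
#'
#' * `"position"` (default) - one subband per 2D subband per stack
#'   position, i.e. the subbands of the individual wavelet-transformed
#'   blocks. This keeps the contribution of a single deviating layer (a
#'   nanoparticle grouped with background blocks, say) concentrated in its
#'   own subbands instead of diluting it across the group;
#' * `"scale"` - the (2D subband) x (1D stack scale) cross product;
#' * `"group"` - one subband per 2D subband pooled over every stack layer
#'   (maximal sample size for the variance estimate).
#'
#' The single coefficient combining the deepest LL subband with the stack
#' scaling layer is the group's DC: it forms its own `protected` class, is
#' excluded from the pooled variance estimate (it has a large non-zero
#' mean), and is never thresholded.
#'
#' @param block_size Side of the (square, power-of-two) block.
#' @param n_blocks Number of blocks in the stack (power of two).
#' @param stack_pooling `"position"`, `"scale"` or `"group"` (see above).
#' @return Object of class `subband_map`: integer `labels` array of
#'   dimension `c(block_size, block_size, n_blocks)`, a `subbands` tibble
#'   (id, level, orientation, stack class, size, protected flag), and the
#'   call parameters.
#' @examples
#' subband_partition(8, 1)$subbands
#' @export
subband_partition <- function(block_size, n_blocks = 1,
                              stack_pooling = c("position", "scale", "group")) {
  stack_pooling <- match.arg(stack_pooling)
  if (!is_power_of_two(block_size) || !is_power_of_two(n_blocks))
    abort("`block_size` and `n_blocks` must be powers of two",
          class = "pgbm3d_input_error")
  b <- as.integer(block_size); K <- as.integer(n_blocks)

  i <- rep(0:(b - 1L), times = b)
  j <- rep(0:(b - 1L), each = b)
  bi <- dyadic_band(i, b)
  bj <- dyadic_band(j, b)
  depth <- log2(b)
  lvl <- pmin(ifelse(bi == 0L, depth + 1L, bi), ifelse(bj == 0L, depth + 1L, bj))
  h <- b / 2^lvl
  ori <- ifelse(bi == 0L & bj == 0L, "LL",
         ifelse(i >= h & j >= h, "HH", ifelse(i >= h, "HL", "LH")))
  lvl[ori == "LL"] <- depth
  band2d <- paste0(ori, ifelse(ori == "LL", depth, lvl))

  bk <- dyadic_band(0:(K - 1L), K)
  stack_class <- switch(stack_pooling,
    position = paste0("k", seq_len(K) - 1L),
    scale = ifelse(bk == 0L, "s", paste0("d", bk)),
    group = rep("all", K))
  lab_chr <- as.vector(outer(band2d, stack_class, paste, sep = ":"))
  # the DC coefficient (deepest LL x stack scaling) is split off so it
  # neither enters a zero-mean variance estimate nor gets thresholded
  dc <- rep(band2d == paste0("LL", depth), K) & rep(bk, each = b * b) == 0L
  lab_chr[dc] <- "DC:s"
  ids <- unique(lab_chr)
  labels <- array(match(lab_chr, ids), dim = c(b, b, K))

  parts <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  sub2d <- parts[, 1L]
  is_dc <- sub2d == "DC" | (sub2d == paste0("LL", depth) & parts[, 2L] == "s")
  subbands <- tibble::tibble(
    id = seq_along(ids),
    subband = ids,
    orientation = ifelse(is_dc, "LL", sub("[0-9]+$", "", sub2d)),
    level = ifelse(is_dc, depth, suppressWarnings(as.integer(sub("^[A-Z]+", "", sub2d)))),
    stack = parts[, 2L],
    size = as.integer(tabulate(labels, nbins = length(ids))),
    protected = is_dc
  )
  structure(list(labels = labels, subbands = subbands, block_size = b,
                 n_blocks = K, stack_pooling = stack_pooling),
            class = "subband_map")
}

#' @export
print.subband_map <- function(x, ...) {
  cat(sprintf("<subband_map> %d x %d block, stack depth %d: %d subbands\n",
              x$block_size, x$block_size, x$n_blocks, nrow(x$subbands)))
  print(x$subbands)
  invisible(x)
}

check_dyadic_block <- function(block) {
  assert_image(block, "block")
  if (nrow(block) != ncol(block) || !is_power_of_two(nrow(block)))
    abort("block must be square with a power-of-two side",
          class = "pgbm3d_input_error")
  invisible(block)
}

#' Non-standard 2D Haar decomposition of a block
#'
#' Orthonormal full-depth Haar analysis alternating one row step and one
#' column step per level (the non-standard scheme), recursing on the
#' low-pass quadrant. Produces quadrant-layout coefficients whose subbands
#' are larger than those of the standard (all-rows-then-all-columns) tensor
#' decomposition, which is what makes per-subband statistics estimable.
#'
#' @param block Square numeric matrix with power-of-two side.
#' @return `haar2d_nonstandard_forward()`: list with `coefficients` (matrix
#'   in quadrant layout) and `map` (the [subband_partition()] for a single
#'   block). `haar2d_nonstandard_inverse()`: the reconstructed block.
#' @export
haar2d_nonstandard_forward <- function(block) {
  check_dyadic_block(block)
  list(coefficients = cpp_haar2d_ns_fwd(block),
       map = subband_partition(nrow(block), 1L))
}

#' @rdname haar2d_nonstandard_forward
#' @param coefficients Coefficient matrix from the forward transform.
#' @export
haar2d_nonstandard_inverse <- function(coefficients) {
  check_dyadic_block(coefficients)
  cpp_haar2d_ns_inv(coefficients)
}

#' 1D Haar transform along the stack axis
#'
#' Orthonormal full-depth Haar analysis applied along the third dimension of
#' a `b x b x K` array (after each layer has been 2D transformed). Depth 1
#' is the identity.
#'
#' @param stack Numeric 3D array with power-of-two depth.
#' @return Array of the same shape.
#' @export
haar1d_stack_forward <- function(stack) {
  d <- check_stack(stack)
  out <- cpp_haar1d_stack_fwd(as.vector(stack), d[1L] * d[2L], d[3L])
  array(out, dim = d)
}

#' @rdname haar1d_stack_forward
#' @export
haar1d_stack_inverse <- function(stack) {
  d <- check_stack(stack)
  out <- cpp_haar1d_stack_inv(as.vector(stack), d[1L] * d[2L], d[3L])
  array(out, dim = d)
}

check_stack <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L || !is.numeric(stack))
    abort("`stack` must be a numeric 3D array", class = "pgbm3d_input_error")
  d <- dim(stack)
  if (!is_power_of_two(d[3L]))
    abort("stack depth must be a power of two", class = "pgbm3d_input_error")
  d
}
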