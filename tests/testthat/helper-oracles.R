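# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast paths.

# Exhaustive block matcher: every lattice position, plain R arithmetic.
oracle_find_blocks <- function(image, ref, block_size, step, radius,
                               max_group, th) {
  lat <- function(n) unique(c(seq(1, n - block_size + 1, step),
                              n - block_size + 1))
  get_block <- function(r, c)
    image[r:(r + block_size - 1), c:(c + block_size - 1)]
  bref <- get_block(ref[1], ref[2])
  cand <- expand.grid(r = lat(nrow(image)), c = lat(ncol(image)))
  cand <- cand[abs(cand$r - ref[1]) <= radius & abs(cand$c - ref[2]) <= radius, ]
  cand <- cand[!(cand$r == ref[1] & cand$c == ref[2]), ]
  d <- mapply(function(r, c) mean((get_block(r, c) - bref)^2), cand$r, cand$c)
  keep <- d <= th
  cand <- cand[keep, , drop = FALSE]; d <- d[keep]
  ord <- order(d, cand$r, cand$c)
  cand <- cand[ord, , drop = FALSE]; d <- d[ord]
  n <- 1
  while (2 * n <= min(max_group, nrow(cand) + 1)) n <- 2 * n
  list(coords = rbind(c(ref[1], ref[2]),
                      as.matrix(cand[seq_len(n - 1), , drop = FALSE])),
       dist = c(0, d[seq_len(n - 1)]))
}

# Hand-rolled aggregation accumulator (double loop over pixels).
oracle_aggregate <- function(groups, shape, input = NULL) {
  num <- matrix(0, shape[1], shape[2]); den <- matrix(0, shape[1], shape[2])
  for (g in groups) {
    b <- dim(g$stack)[1]
    for (k in seq_len(dim(g$stack)[3])) {
      for (i in 0:(b - 1)) for (j in 0:(b - 1)) {
        r <- g$coords[k, 1] + i; c <- g$coords[k, 2] + j
        num[r, c] <- num[r, c] + g$weight * g$stack[i + 1, j + 1, k]
        den[r, c] <- den[r, c] + g$weight
      }
    }
  }
  out <- matrix(0, shape[1], shape[2])
  cov <- den > 0
  out[cov] <- num[cov] / den[cov]
  if (!is.null(input)) out[!cov] <- input[!cov]
  out
}

# Full 3D forward/inverse transform via the exported primitives.
transform3d <- function(stack) {
  d <- dim(stack)
  co2 <- array(apply(stack, 3,
                     function(m) haar2d_nonstandard_forward(m)$coefficients), d)
  haar1d_stack_forward(co2)
}

inverse3d <- function(coeff) {
  d <- dim(coeff)
  st <- haar1d_stack_inverse(coeff)
  array(apply(st, 3, haar2d_nonstandard_inverse), d)
}

# R composition of level 1 from the exported module operations; mirrors the
# fused pipeline and serves as its oracle on small images.
reference_level1 <- function(image, cfg) {
  b <- cfg$block$block_size
  sig <- cfg$sigma %||% estimate_awgn_sigma(image)
  th <- if (cfg$mode == "modified") th_bm_level1(sig^2, cfg$th_offset)
        else cfg$tau_match / 255^2 * diff(range(image))^2
  lat <- function(n) unique(c(seq(1, n - b + 1, cfg$block$step), n - b + 1))
  groups <- list()
  for (r0 in lat(nrow(image))) for (c0 in lat(ncol(image))) {
    g <- find_similar_blocks(image, c(r0, c0), cfg$block, th)
    K <- dim(g$stack)[3]
    co <- transform3d(g$stack)
    map <- subband_partition(b, K, cfg$stack_pooling)
    ht <- hard_threshold_stack(co, map, sig,
                               if (cfg$mode == "modified") "bayes" else "fixed",
                               cfg$lambda)
    groups[[length(groups) + 1]] <- list(
      stack = inverse3d(ht$coefficients), coords = g$coords,
      weight = 1 / max(ht$retained_count, 1))
  }
  aggregate_blocks(groups, dim(image), input = image)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subband sizes of the standard (tensor, rows-then-columns) decomposition at
# full depth, for comparison with the non-standard scheme.
standard_subband_sizes <- function(b) {
  band_sizes <- c(1, 2^(0:(log2(b) - 1)))  # scaling + detail band widths
  as.vector(outer(band_sizes, band_sizes))
}

# Separable Gaussian blur for metric degradation tests (plain R, independent
# of package internals).
blur_for_test <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  Tr <- matrix(0, n, n); Tc <- matrix(0, m, m)
  for (i in seq_len(n)) {
    lo <- max(1, i - r); hi <- min(n, i + r)
    kk <- k[(lo - i + r + 1):(hi - i + r + 1)]
    Tr[i, lo:hi] <- kk / sum(kk)
  }
  for (i in seq_len(m)) {
    lo <- max(1, i - r); hi <- min(m, i + r)
    kk <- k[(lo - i + r + 1):(hi - i + r + 1)]
    Tc[i, lo:hi] <- kk / sum(kk)
  }
  Tr %*% img %*% t(Tc)
}
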