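# Internal helpers shared across modules.

assert_image <- function(x, arg = "image", allow_empty = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    rlang::abort(sprintf("`%s` must be a numeric matrix", arg), class = "pgbm3d_input_error")
  if (!allow_empty && (nrow(x) == 0L || ncol(x) == 0L))
    rlang::abort(sprintf("`%s` must be non-empty", arg), class = "pgbm3d_input_error")
  invisible(x)
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

largest_pow2_leq <- function(n) {
  p <- 1L
  while (2L * p <= n) p <- 2L * p
  p
}

# Truncated, renormalized 1D Gaussian kernel.
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution by banded matrices; mode "same" renormalizes the
# kernel at the borders, mode "valid" crops them.
conv_matrix <- function(n, kernel, mode = c("same", "valid")) {
  mode <- match.arg(mode)
  r <- (length(kernel) - 1L) / 2L
  if (mode == "valid") {
    m <- n - 2L * r
    stopifnot(m >= 1L)
    T <- matrix(0, m, n)
    for (i in seq_len(m)) T[i, i:(i + 2L * r)] <- kernel
    return(T)
  }
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - r)
    hi <- min(n, i + r)
    k <- kernel[(lo - i + r + 1L):(hi - i + r + 1L)]
    T[i, lo:hi] <- k / sum(k)
  }
  T
}

blur_separable <- function(img, kernel, mode = c("same", "valid")) {
  mode <- match.arg(mode)
  Tr <- conv_matrix(nrow(img), kernel, mode)
  Tc <- conv_matrix(ncol(img), kernel, mode)
  Tr %*% img %*% t(Tc)
}

blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blur_separable(img, gaussian_kernel(sigma), "same")
}
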