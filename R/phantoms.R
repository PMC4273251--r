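#' Synthetic ground-truth phantoms for 2-photon-microscopy-like scenes
#'
#' Seeded, pure generators for the image classes the evaluation harness
#' needs:
#'
#' * `"cells"` - a Voronoi-like mosaic of epithelial-cell bodies with dark
#'   membranes and fine multiplicative granularity (mitochondria-like
#'   texture), under a mild illumination gradient;
#' * `"particles"` - a low, slowly varying background with `k` isolated 1-2
#'   pixel bright spots (nanoparticle-like), 5-10x the local background;
#' * `"flatfield"` - constant at the intensity ceiling (homogeneous
#'   fluorescent-slide surrogate);
#' * `"dark"` - all zeros (zero-excitation frame);
#' * `"edges"` - bar and step patterns for sharpness checks.
#'
#' All generators are deterministic functions of their arguments; the
#' caller's RNG state is untouched.
#'
#' @param kind One of `"cells"`, `"particles"`, `"flatfield"`, `"dark"`,
#'   `"edges"`.
#' @param size Image side in pixels (at least 64 for cells/particles).
#' @param intensity_ceiling Upper intensity bound; default 4095
#'   (12-bit-like detector counts).
#' @param seed Integer seed.
#' @param k Number of seeded spots (particles only).
#' @return A `size x size` non-negative matrix. Particle phantoms carry a
#'   `spots` attribute (tibble with row, col, peak and size of each spot).
#' @examples
#' p <- make_phantom("particles", 128, seed = 7)
#' nrow(attr(p, "spots"))
#' @export
make_phantom <- function(kind = c("cells", "particles", "flatfield", "dark",
                                  "edges"),
                         size = 256, intensity_ceiling = 4095, seed = 1,
                         k = 12) {
  kind <- match.arg(kind)
  stopifnot(size >= 8, intensity_ceiling > 0)
  if (kind %in% c("cells", "particles") && size < 64)
    abort("cells/particles phantoms need `size` >= 64", class = "pgbm3d_input_error")
  withr::with_seed(as.integer(seed), switch(kind,
    flatfield = matrix(intensity_ceiling, size, size),
    dark = matrix(0, size, size),
    cells = phantom_cells(size, intensity_ceiling),
    particles = phantom_particles(size, intensity_ceiling, k),
    edges = phantom_edges(size, intensity_ceiling)
  ))
}

phantom_cells <- function(n, ceiling) {
  k <- max(8L, round((n / 64)^2))
  cr <- runif(k, 1, n)
  cc <- runif(k, 1, n)
  amp <- runif(k, 0.25, 0.85) * ceiling
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- vapply(seq_len(k),
              function(s) sqrt((rows - cr[s])^2 + (cols - cc[s])^2),
              matrix(0, n, n))
  d <- matrix(d, n * n, k)
  ord1 <- max.col(-d)                       # nearest seed
  d1 <- d[cbind(seq_len(n * n), ord1)]
  d[cbind(seq_len(n * n), ord1)] <- Inf
  d2 <- d[cbind(seq_len(n * n), max.col(-d))]
  base <- amp[ord1]
  # membranes: darken where the two nearest seeds are nearly equidistant
  w <- pmin((d2 - d1) / 3, 1)
  img <- matrix(base * (0.08 + 0.92 * w * w * (3 - 2 * w)), n, n)
  # dark elliptical nuclei, one per cell seed
  nr <- runif(k, 0.06, 0.12) * n
  for (s in seq_len(k)) {
    dn <- sqrt(((rows - cr[s]) / 1.3)^2 + (cols - cc[s])^2)
    img[dn < nr[s]] <- img[dn < nr[s]] * 0.35
  }
  # mitochondria-like granularity: ~3 px features (0.5-1 um at 0.29 um/px)
  tex <- blur_gaussian(matrix(rnorm(n * n), n, n), 1.8)
  img <- img * (1 + 0.10 * tex / sd(tex))
  ramp <- matrix(seq(0.85, 1.15, length.out = n), n, n, byrow = TRUE)
  img <- blur_gaussian(img * ramp, 0.6)
  pmin(pmax(img, 0.01 * ceiling), ceiling)
}

phantom_particles <- function(n, ceiling, k) {
  # low, nearly flat background: lumen/mucus autofluorescence is faint and
  # structure-free, so only a mild (5%) slowly varying modulation is applied
  bg0 <- 0.05 * ceiling
  bg <- blur_gaussian(matrix(rnorm(n * n), n, n), 4)
  bg <- bg0 * (1 + 0.05 * bg / max(abs(bg)))
  margin <- 8L
  pos <- matrix(0L, 0L, 2L)
  guard <- 0L
  while (nrow(pos) < k && guard < 10000L) {
    guard <- guard + 1L
    p <- sample(seq(margin, n - margin), 2L, replace = TRUE)
    if (nrow(pos) == 0L ||
        min(pmax(abs(pos[, 1L] - p[1L]), abs(pos[, 2L] - p[2L]))) >= 6L)
      pos <- rbind(pos, p)
  }
  img <- bg
  amp <- runif(k, 5, 10)
  sz <- sample(1:2, k, replace = TRUE)
  for (s in seq_len(k)) {
    r <- pos[s, 1L]; c <- pos[s, 2L]
    peak <- amp[s] * bg[r, c]
    img[r, c] <- peak
    if (sz[s] == 2L) img[r, c + 1L] <- 0.7 * peak  # companion pixel
  }
  img <- pmin(img, ceiling)
  attr(img, "spots") <- tibble::tibble(row = pos[, 1L], col = pos[, 2L],
                                       peak = amp * bg[pos], size = sz)
  img
}

phantom_edges <- function(n, ceiling) {
  img <- matrix(0.1 * ceiling, n, n)
  lo <- 0.1 * ceiling; hi <- 0.9 * ceiling
  widths <- sample(c(2L, 4L, 8L, 16L))  # seeded bar order varies per phantom
  c0 <- 1L
  w_i <- 1L
  state <- FALSE
  while (c0 <= n %/% 2L) {
    w <- widths[w_i]
    img[, c0:min(n %/% 2L, c0 + w - 1L)] <- if (state) hi else lo
    c0 <- c0 + w
    state <- !state
    w_i <- w_i %% length(widths) + 1L
  }
  # right half: intensity staircase
  steps <- 8L
  edges_at <- round(seq(n %/% 2L + 1L, n + 1L, length.out = steps + 1L))
  for (s in seq_len(steps)) {
    cols <- edges_at[s]:(edges_at[s + 1L] - 1L)
    img[, cols] <- lo + (hi - lo) * (s - 1) / (steps - 1)
  }
  img
}

#' Default evaluation phantom suite
#'
#' Ten phantoms (4 cells, 3 particles, 2 edges, 1 flatfield) at the given
#' size - a desk-scale surrogate for a set of high-quality ground-truth
#' acquisitions.
#'
#' @param size Side length in pixels (default 256).
#' @param intensity_ceiling Intensity ceiling (default 4095).
#' @param seed Base seed; each phantom derives its own.
#' @return Named list of matrices.
#' @export
phantom_suite <- function(size = 256, intensity_ceiling = 4095, seed = 1) {
  s <- as.integer(seed)
  out <- c(
    purrr::map(1:4, ~ make_phantom("cells", size, intensity_ceiling, seed = s + .x)),
    purrr::map(1:3, ~ make_phantom("particles", size, intensity_ceiling, seed = s + 10L + .x)),
    purrr::map(1:2, ~ make_phantom("edges", size, intensity_ceiling, seed = s + 20L + .x)),
    list(make_phantom("flatfield", size, intensity_ceiling, seed = s))
  )
  names(out) <- c(paste0("cells", 1:4), paste0("particles", 1:3),
                  paste0("edges", 1:2), "flatfield")
  out
}
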