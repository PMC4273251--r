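test_that("matching thresholds implement the Bienaymé parameterization", {
  expect_identical(th_bm_level1(0, 900), 900)
  expect_identical(th_bm_level1(50, 900), 1000)
  expect_identical(th_bm_level1(1, 0), 2)
  expect_identical(th_bm_level2(0, 900), 900)
  expect_identical(th_bm_level2(100, 900, 0.3), 960)
  # reduction = 1 reproduces the level-1 threshold
  expect_identical(th_bm_level2(37, 123, 1), th_bm_level1(37, 123))
  expect_error(th_bm_level1(-1, 900), class = "pgbm3d_input_error")
  expect_error(th_bm_level2(1, 900, reduction = 0), class = "pgbm3d_input_error")
  expect_error(th_bm_level2(1, 900, reduction = 1.5), class = "pgbm3d_input_error")
  mt <- match_threshold(1, 900, level = 2)
  expect_equal(mt$th, 900.6)
})

test_that("block distance is the per-pixel mean squared difference", {
  b <- matrix(rnorm(16), 4, 4)
  expect_equal(block_distance(b, b), 0)
  expect_equal(block_distance(matrix(0, 2, 2), matrix(3, 2, 2)), 9)
  expect_error(block_distance(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "pgbm3d_input_error")
  # Bienaymé: expected distance between independent noise blocks is 2 sigma^2
  d <- withr::with_seed(4, replicate(2000, {
    block_distance(matrix(rnorm(64, sd = 3), 8), matrix(rnorm(64, sd = 3), 8))
  }))
  expect_lt(abs(mean(d) - 18) / 18, 0.05)
})

test_that("matcher agrees with the exhaustive brute-force oracle", {
  img <- matrix(withr::with_seed(11, rnorm(32 * 32, sd = 5)), 32)
  spec <- block_spec(block_size = 8, step = 3, search_radius = 12,
                     max_group = 8)
  for (ref in list(c(1, 1), c(9, 13), c(25, 25))) {
    for (th in c(10, 40, 1e6)) {
      got <- find_similar_blocks(img, ref, spec, th)
      want <- oracle_find_blocks(img, ref, 8, 3, 12, 8, th)
      expect_equal(unname(got$coords), unname(want$coords))
      expect_equal(got$dist, want$dist, tolerance = 1e-12)
    }
  }
  expect_error(find_similar_blocks(img, c(30, 30), spec, 10),
               class = "pgbm3d_input_error")
})

test_that("matcher satisfies its structural invariants", {
  img <- matrix(withr::with_seed(2, rnorm(48 * 48)), 48)
  spec <- block_spec()
  g <- find_similar_blocks(img, c(13, 13), spec, 1e6)
  # group size is a power of two, reference first with distance zero
  expect_true(log2(dim(g$stack)[3]) %% 1 == 0)
  expect_equal(g$coords[1, ], c(13, 13))
  expect_equal(g$dist[1], 0)
  expect_true(all(diff(g$dist) >= 0))
  expect_equal(g$reference_index, 1L)

  # raising th_offset never shrinks the group
  sizes <- vapply(c(0, 1, 5, 1e6), function(off)
    dim(find_similar_blocks(img, c(13, 13), spec,
                            th_bm_level1(0, off))$stack)[3], numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # constant image: every in-window candidate matches
  cst <- matrix(4, 48, 48)
  gc <- find_similar_blocks(cst, c(21, 21), spec, th_bm_level1(1, 900))
  expect_equal(dim(gc$stack)[3], spec$max_group)
  expect_true(all(gc$dist == 0))
})

test_that("noise-free matching with zero offset finds exactly the replicates", {
  img <- matrix(withr::with_seed(3, runif(32 * 32, 0, 10)), 32)
  patch <- matrix(withr::with_seed(4, rnorm(64, 50, 5)), 8)
  img[1:8, 1:8] <- patch
  img[1:8, 13:20] <- patch  # both on the step-3 lattice
  g <- find_similar_blocks(img, c(1, 1), block_spec(), th_bm_level1(0, 0))
  expect_equal(unname(g$coords), rbind(c(1, 1), c(1, 13)))
})

test_that("pilot matching decides on the pilot and extracts dual stacks", {
  noisy <- matrix(withr::with_seed(5, rnorm(32 * 32)), 32)
  spec <- block_spec(search_radius = 10)
  both <- find_similar_blocks_pilot(noisy, noisy, c(9, 9), spec,
                                    th_bm_level2(1, 900))
  direct <- find_similar_blocks(noisy, c(9, 9), spec, th_bm_level2(1, 900))
  expect_equal(both$pilot$coords, direct$coords)
  expect_equal(both$noisy$coords, both$pilot$coords)
  expect_error(find_similar_blocks_pilot(noisy, matrix(0, 16, 16), c(1, 1),
                                         spec, 1),
               class = "pgbm3d_input_error")
})

test_that("pilot-side matching recovers more true replicates than noisy-side", {
  # 6 identical patches at known lattice positions + strong noise
  base <- matrix(withr::with_seed(6, runif(64 * 64, 0, 4)), 64)
  patch <- matrix(withr::with_seed(7, rnorm(64, 10, 3)), 8)
  pos <- rbind(c(1, 1), c(1, 16), c(1, 31), c(16, 1), c(31, 16), c(16, 31))
  clean <- base
  for (i in seq_len(nrow(pos)))
    clean[pos[i, 1]:(pos[i, 1] + 7), pos[i, 2]:(pos[i, 2] + 7)] <- patch
  hits <- function(coords) sum(apply(pos, 1, function(p)
    any(coords[, 1] == p[1] & coords[, 2] == p[2])))
  n1 <- n2 <- 0
  for (s in 1:5) {
    noisy <- clean + matrix(withr::with_seed(s, rnorm(64 * 64, sd = 2)), 64)
    spec <- block_spec(search_radius = 40)
    g1 <- find_similar_blocks(noisy, c(1, 1), spec, th_bm_level1(4, 4))
    g2 <- find_similar_blocks_pilot(noisy, clean, c(1, 1), spec,
                                    th_bm_level2(4, 4))
    n1 <- n1 + hits(g1$coords)
    n2 <- n2 + hits(g2$pilot$coords)
  }
  expect_gte(n2, n1)
})
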