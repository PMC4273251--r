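test_that("generalized Anscombe transform evaluates the closed form", {
  p <- noise_params(1, 0, 0)
  expect_equal(generalized_anscombe(matrix(0), p)[1], 2 * sqrt(3 / 8),
               tolerance = 1e-10)
  expect_equal(generalized_anscombe(matrix(1), p)[1], 2 * sqrt(11 / 8),
               tolerance = 1e-10)
  # radicand clamp keeps low pixels finite
  pneg <- noise_params(1, 10, 0)
  expect_equal(generalized_anscombe(matrix(0), pneg)[1], 0)
  # strictly increasing above the clamp point
  z <- matrix(seq(0, 500, length.out = 100), 1)
  expect_true(all(diff(as.vector(generalized_anscombe(z, p))) > 0))
})

test_that("transform stabilizes simulated Poisson-Gaussian noise", {
  p <- noise_params(1, 0, 2)
  for (y in c(20, 50, 100, 200)) {
    z <- simulate_pg_noise(matrix(y, 500, 500), p, seed = y)
    v <- var(as.vector(generalized_anscombe(z, p)))
    expect_gte(v, 0.9)
    expect_lte(v, 1.1)
  }
})

test_that("exact-inverse table matches degenerate and Monte-Carlo oracles", {
  # degenerate: y = 0 with no Gaussian part is f(0) exactly
  p0 <- noise_params(1, 0, 0)
  tab0 <- build_exact_inverse_table(p0, y_grid = c(0, 1, 5, 20))
  expect_equal(tab0$e_forward[1], 2 * sqrt(3 / 8), tolerance = 1e-10)

  # Monte-Carlo oracle for E[f(z) | y] at y = 100
  p <- noise_params(1, 0, 0.5)
  tab <- build_exact_inverse_table(p, y_grid = c(0, 50, 100, 200))
  z <- simulate_pg_noise(matrix(100, 1000, 1000), p, seed = 5)
  fz <- generalized_anscombe(z, p)
  se <- sd(as.vector(fz)) / 1000
  expect_lt(abs(tab$e_forward[3] - mean(fz)), 3 * se)

  # strict monotonicity over a default grid
  tabd <- build_exact_inverse_table(noise_params(1.2, 8, 3), y_max = 2000)
  expect_true(all(diff(tabd$e_forward) > 0))
})

test_that("exact unbiased inverse round-trips and is monotone", {
  p <- noise_params(1, 0, 2)
  tab <- build_exact_inverse_table(p, y_max = 300)
  i100 <- which.min(abs(tab$y_grid - 100))
  D <- matrix(tab$e_forward[i100])
  expect_lt(abs(exact_unbiased_inverse(D, tab)[1] - tab$y_grid[i100]), 0.5)

  # identity on the grid within interpolation tolerance
  mid <- tab$y_grid > 1 & tab$y_grid < 290
  back <- exact_unbiased_inverse(matrix(tab$e_forward[mid], 1), tab)
  expect_lt(max(abs(back - tab$y_grid[mid])), 1e-3)

  # monotone non-decreasing; below-table values map to 0
  d <- matrix(seq(0, max(tab$e_forward) * 1.2, length.out = 200), 1)
  out <- exact_unbiased_inverse(d, tab)
  expect_true(all(diff(as.vector(out)) >= -1e-9))
  expect_equal(exact_unbiased_inverse(matrix(0), tab)[1], 0)

  # constant in, constant out
  cst <- exact_unbiased_inverse(matrix(5, 3, 3), tab)
  expect_equal(max(cst) - min(cst), 0)

  # parameter mismatch is rejected
  expect_error(exact_unbiased_inverse(D, tab, params = noise_params(2, 0, 2)),
               class = "pgbm3d_input_error")
})

test_that("algebraic and asymptotic inverses hold their closed-form identities", {
  # algebraic inverse undoes the forward map (y domain)
  p <- noise_params(1, 0, 0)
  z <- matrix(seq(1, 400, length.out = 50), 1)
  expect_equal(algebraic_inverse(generalized_anscombe(z, p), p), z,
               tolerance = 1e-10)
  pg <- noise_params(2, 5, 3)
  zg <- matrix(seq(50, 800, length.out = 50), 1)
  expect_equal(algebraic_inverse(generalized_anscombe(zg, pg), pg),
               (zg - 5) / 2, tolerance = 1e-8)
  # asymptotic = algebraic + 1/4 away from the clamp
  expect_equal(asymptotic_inverse(generalized_anscombe(zg, pg), pg),
               (zg - 5) / 2 + 0.25, tolerance = 1e-8)
  # constant in, constant out
  cst <- algebraic_inverse(matrix(4, 2, 2), pg)
  expect_equal(max(cst) - min(cst), 0)
})

test_that("exact inverse reconstructs E-estimates better than the algebraic one", {
  p <- noise_params(1, 0, 1)
  tab <- build_exact_inverse_table(p, y_max = 50)
  z <- matrix(simulate_pg_noise(matrix(5, 1, 2e5), p, seed = 2), 1)
  D <- matrix(mean(generalized_anscombe(z, p)))  # denoised-value surrogate
  err_exact <- abs(exact_unbiased_inverse(D, tab)[1] - 5)
  err_alg <- abs(algebraic_inverse(D, p)[1] - 5)
  expect_lt(err_exact, err_alg)
})

test_that("VST specification survives a JSON round trip", {
  p <- noise_params(1.3, 4, 2)
  tab <- build_exact_inverse_table(p, y_max = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_vst_spec(tab, path)
  back <- read_vst_spec(path)
  expect_equal(back$params, p)
  expect_equal(back$y_grid, tab$y_grid)
  expect_equal(back$e_forward, tab$e_forward)
})

test_that("robust sigma estimate recovers the noise level of AWGN", {
  img <- matrix(withr::with_seed(1, rnorm(256 * 256, sd = 2.5)), 256)
  expect_lt(abs(estimate_awgn_sigma(img) - 2.5) / 2.5, 0.05)
})
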