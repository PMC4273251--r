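test_that("parameter container enforces the model's invariants", {
  p <- noise_params(1.2, 8, 3)
  expect_s3_class(p, "noise_params")
  expect_error(noise_params(0), class = "pgbm3d_input_error")
  expect_error(noise_params(-1), class = "pgbm3d_input_error")
  expect_error(noise_params(1, sigma_g = -0.1), class = "pgbm3d_input_error")
})

test_that("simulator matches the Poisson-Gaussian moment law", {
  # zero signal, zero-variance Gaussian: deterministic offset
  z <- simulate_pg_noise(matrix(0, 4, 4), noise_params(1, 5, 0), seed = 1)
  expect_equal(z, matrix(5, 4, 4))

  # Monte Carlo vs closed-form moments at 10^6 pixels
  z <- simulate_pg_noise(matrix(100, 1000, 1000), noise_params(2, 0, 3),
                         seed = 7)
  expect_lt(abs(mean(z) - 200), 0.5)
  expect_lt(abs(var(as.vector(z)) - 409), 3)

  # dark frames recover the Gaussian component
  d <- simulate_pg_noise(matrix(0, 1000, 1000), noise_params(1.5, 10, 4),
                         seed = 8)
  expect_lt(abs(mean(d) - 10), 0.05)
  expect_lt(abs(sd(as.vector(d)) - 4), 0.05)
})

test_that("simulator is deterministic given a seed and validates input", {
  y <- matrix(runif(64, 0, 50), 8, 8)  # non-integer rates allowed
  z1 <- simulate_pg_noise(y, noise_params(1, 0, 1), seed = 42)
  z2 <- simulate_pg_noise(y, noise_params(1, 0, 1), seed = 42)
  expect_identical(z1, z2)
  bad <- y; bad[3, 5] <- -1
  expect_error(simulate_pg_noise(bad, noise_params(1), seed = 1),
               "row 3, col 5")
})

test_that("flat-field variance uses the population normalization", {
  expect_equal(estimate_noise_variance(matrix(7, 5, 5)), 0)
  expect_equal(estimate_noise_variance(matrix(c(0, 0, 2, 2), 2, 2)), 1)
  # Monte Carlo vs alpha^2 y + sigma^2
  z <- simulate_pg_noise(matrix(50, 512, 512), noise_params(1.5, 0, 2),
                         seed = 3)
  expect_lt(abs(estimate_noise_variance(z) - 116.5), 2)
})

test_that("dark frames give pooled Gaussian estimates", {
  expect_equal(estimate_gaussian_params(matrix(7, 3, 3)),
               list(mu_g = 7, sigma_g = 0))
  two <- estimate_gaussian_params(list(matrix(1, 1, 2), matrix(3, 1, 2)))
  expect_equal(two$mu_g, 2)
  expect_equal(two$sigma_g, 1)
  expect_error(estimate_gaussian_params(list()), class = "pgbm3d_input_error")
})

test_that("alpha regression is exact on noiseless points and rejects degeneracy", {
  means <- c(10, 20, 40, 80)
  flats <- lapply(means, function(m) {
    v <- 2 * (m - 5) + 9  # alpha = 2, mu_G = 5, sigma_G^2 = 9
    matrix(c(m - sqrt(v), m + sqrt(v)), 1, 2)  # mean m, population var v
  })
  fit <- calibrate_alpha(calibration_series(flats),
                         list(mu_g = 5, sigma_g = 3))
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  expect_error(calibrate_alpha(calibration_series(flats[1]),
                               list(mu_g = 5, sigma_g = 3)),
               class = "pgbm3d_input_error")
  same <- calibration_series(list(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_error(calibrate_alpha(same, list(mu_g = 0, sigma_g = 0)),
               class = "pgbm3d_input_error")
})

test_that("round-trip calibration recovers the generating parameters", {
  true <- noise_params(1.2, 8, 3)
  darks <- lapply(1:3, function(i)
    simulate_pg_noise(matrix(0, 256, 256), true, seed = 100 + i))
  gauss <- estimate_gaussian_params(darks)
  expect_lt(abs(gauss$mu_g - 8), 0.05)
  expect_lt(abs(gauss$sigma_g - 3), 0.05)

  levels <- seq(50, 1500, length.out = 24)
  flats <- lapply(seq_along(levels), function(i)
    simulate_pg_noise(matrix(levels[i], 256, 256), true, seed = 200 + i))
  series <- calibration_series(flats, levels = levels, darks = darks)
  fit <- calibrate_alpha(series, gauss)
  expect_lt(abs(fit$alpha - 1.2) / 1.2, 0.05)
  expect_gte(fit$r_squared, 0.99)

  # heteroscedasticity: variance strictly increasing along the ladder
  curve <- variance_vs_intensity_curve(series, fit)
  expect_true(all(diff(curve$var_est) > 0))
  expect_equal(curve$var_model,
               fit$alpha * (curve$mean - gauss$mu_g) + gauss$sigma_g^2)

  tid <- tidy(fit)
  expect_equal(nrow(tid), 24)
  gl <- glance(fit)
  expect_equal(gl$n_levels, 24)
  expect_equal(gl$alpha, fit$alpha)
})

test_that("variance curve handles empty and noiseless series", {
  empty <- variance_vs_intensity_curve(calibration_series(list()),
                                       noise_params(1))
  expect_equal(nrow(empty), 0)
  flats <- lapply(c(10, 20), function(m) {
    s <- sqrt(m - 9)  # on the line var = (m - 9) for alpha = 1, mu_G = 9
    matrix(c(m - s, m + s), 1, 2)
  })
  cv <- variance_vs_intensity_curve(calibration_series(flats),
                                    noise_params(1, 9, 0))
  expect_equal(cv$var_est, cv$var_model, tolerance = 1e-12)
})
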