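test_that("Bayes threshold follows the BayesShrink estimator", {
  expect_equal(bayes_threshold(c(sqrt(2), -sqrt(2)), 1), 1)
  expect_equal(bayes_threshold(rep(sqrt(13), 4), 2), 4 / 3)
  expect_identical(bayes_threshold(c(0.5, -0.5), 1), Inf)
  expect_error(bayes_threshold(numeric(0), 1), class = "pgbm3d_input_error")
  expect_error(bayes_threshold(1:4, 0), class = "pgbm3d_input_error")
})

test_that("hard thresholding respects mode, protection and the equality rule", {
  K <- 4
  map <- subband_partition(8, K)
  co <- array(withr::with_seed(1, rnorm(64 * K)), c(8, 8, K))

  # fixed mode with sigma = 0 is the identity
  ht0 <- hard_threshold_stack(co, map, 0, "fixed")
  expect_equal(ht0$coefficients, co)
  expect_equal(ht0$retained_count, length(co))

  # all details below threshold: only the protected DC survives
  tiny <- co * 1e-6
  tiny[map$labels == map$subbands$id[map$subbands$protected]] <- 100
  ht <- hard_threshold_stack(tiny, map, 1, "fixed", lambda = 2.7)
  expect_equal(ht$retained_count, sum(map$subbands$size[map$subbands$protected]))
  expect_true(all(ht$coefficients[map$labels != map$subbands$id[map$subbands$protected]] == 0))

  # equality survives: a coefficient exactly at lambda * sigma is kept
  eq <- array(0, c(8, 8, K))
  eq[8, 8, 2] <- 2.7
  hte <- hard_threshold_stack(eq, map, 1, "fixed", lambda = 2.7)
  expect_equal(hte$coefficients[8, 8, 2], 2.7)

  # output non-zeros are a subset of input non-zeros plus the protected band
  htb <- hard_threshold_stack(co, map, 1, "bayes")
  changed <- htb$coefficients != 0 & co == 0
  expect_false(any(changed))
  expect_error(hard_threshold_stack(co, map, 1, "nonsense"))
})

test_that("Bayes mode preserves dense shared texture better than the fixed threshold", {
  # grouped blocks that are similar but not identical, with moderate-contrast
  # texture: the regime where a fixed 2.7 sigma threshold flattens signal
  set.seed(10)
  K <- 8
  map <- subband_partition(8, K)
  mb <- mf <- numeric(40)
  for (i in 1:40) {
    common <- matrix(rnorm(64, sd = 1.5), 8, 8)
    truth <- array(0, c(8, 8, K))
    for (k in seq_len(K)) truth[, , k] <- common + matrix(rnorm(64, sd = 1.5), 8)
    co <- transform3d(truth + array(rnorm(64 * K), c(8, 8, K)))
    rec_b <- inverse3d(hard_threshold_stack(co, map, 1, "bayes")$coefficients)
    rec_f <- inverse3d(hard_threshold_stack(co, map, 1, "fixed")$coefficients)
    mb[i] <- mean((rec_b - truth)^2)
    mf[i] <- mean((rec_f - truth)^2)
  }
  expect_lt(mean(mb), mean(mf))
})

test_that("empirical Wiener shrinkage follows the pilot", {
  K <- 2
  noisy <- array(withr::with_seed(2, rnorm(64 * K)), c(8, 8, K))
  zero <- array(0, c(8, 8, K))
  w0 <- wiener_filter_stack(noisy, zero, 1)
  expect_equal(w0$coefficients, zero)
  expect_equal(w0$wiener_energy, 0)

  half <- wiener_filter_stack(array(1, c(8, 8, K)), array(2, c(8, 8, K)), 2)
  expect_equal(half$coefficients, array(0.5, c(8, 8, K)))  # P = sigma -> 1/2
  expect_equal(half$wiener_energy, 0.25 * 64 * K)

  big <- wiener_filter_stack(noisy, noisy * 1e6, 1)
  expect_equal(big$coefficients, noisy, tolerance = 1e-9)

  expect_error(wiener_filter_stack(noisy, array(0, c(4, 4, 2)), 1),
               class = "pgbm3d_input_error")
})

test_that("aggregation equals the hand-rolled accumulator", {
  # single group: block copied verbatim
  blk <- array(matrix(1:4, 2, 2), c(2, 2, 1))
  one <- aggregate_blocks(list(list(stack = blk, coords = rbind(c(2, 2)),
                                    weight = 0.7)), c(4, 4))
  expect_equal(one[2:3, 2:3], matrix(1:4, 2, 2))

  # two overlapping constant blocks of equal value
  g2 <- list(list(stack = array(5, c(2, 2, 1)), coords = rbind(c(1, 1)),
                  weight = 1),
             list(stack = array(5, c(2, 2, 1)), coords = rbind(c(2, 2)),
                  weight = 9))
  out2 <- aggregate_blocks(g2, c(3, 3))
  expect_equal(out2[2, 2], 5)

  # random overlapping case vs the double-loop oracle on a 4 x 4 image
  set.seed(3)
  groups <- lapply(1:4, function(i) list(
    stack = array(rnorm(8), c(2, 2, 2)),
    coords = rbind(c(sample(1:3, 1), sample(1:3, 1)),
                   c(sample(1:3, 1), sample(1:3, 1))),
    weight = runif(1, 0.1, 3)))
  input <- matrix(rnorm(16), 4, 4)
  expect_equal(aggregate_blocks(groups, c(4, 4), input),
               oracle_aggregate(groups, c(4, 4), input), tolerance = 1e-12)

  # constants are conserved, uncovered pixels come from the input
  cval <- aggregate_blocks(list(list(stack = array(2, c(2, 2, 3)),
                                     coords = rbind(c(1, 1), c(1, 1), c(3, 3)),
                                     weight = 0.5)),
                           c(6, 6), input = matrix(2, 6, 6))
  expect_equal(cval, matrix(2, 6, 6))

  expect_error(aggregate_blocks(list(list(stack = array(0, c(2, 2, 1)),
                                          coords = rbind(c(4, 4)),
                                          weight = 1)), c(4, 4)),
               class = "pgbm3d_input_error")
})
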