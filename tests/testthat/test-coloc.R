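test_that("PDM matches hand-computed values and errors on bad input", {
  expect_equal(compute_pdm(c(1, 2, 3), c(1, 2, 3))$values, c(1, 0, 1))
  expect_equal(compute_pdm(c(1, 2, 3), c(3, 2, 1))$values, c(-1, 0, -1))
  expect_error(compute_pdm(1:4, 1:5), "same shape")
  expect_error(compute_pdm(1:4, 1:4, mask = c(TRUE, FALSE, FALSE, FALSE)),
               "at least 2")
  # means are computed over the mask only
  p <- compute_pdm(c(1, 2, 3, 100), c(1, 2, 3, -50),
                   mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(p$mean_a, 2)
  expect_equal(p$values, c(1, 0, 1))
})

test_that("mean PDM equals the population covariance", {
  set.seed(42)
  for (rep in 1:5) {
    a <- matrix(runif(64 * 64, 0, 1000), 64)
    b <- 0.3 * a + matrix(runif(64 * 64, 0, 700), 64)
    p <- compute_pdm(a, b)
    cov_pop <- mean(a * b) - mean(a) * mean(b)   # independent oracle
    expect_equal(mean(p$values), cov_pop, tolerance = 1e-10)
  }
})

test_that("ICQ hits its bounds for perfectly dependent channels", {
  set.seed(7)
  x <- matrix(runif(128 * 128, 0, 1000), 128)
  expect_identical(compute_icq(compute_pdm(x, x))$icq, 0.5)
  expect_identical(compute_icq(compute_pdm(x, 2000 - x))$icq, -0.5)
  # all-constant channel: every PDM is 0, counted non-positive
  expect_identical(compute_icq(compute_pdm(rep(1, 10), rep(1, 10)))$icq, -0.5)
})

test_that("ICQ of independent channels is near zero", {
  set.seed(11)
  r <- compute_icq(compute_pdm(runif(1e5), runif(1e5)))
  expect_lt(abs(r$icq), 0.01)
})

test_that("ICQ is bounded, symmetric, and affine invariant", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(10:400, 1)
    a <- runif(n, 0, 1000)
    b <- if (i %% 3 == 0) 0.5 * a + runif(n, 0, 500) else runif(n, 0, 1000)
    q1 <- compute_icq(compute_pdm(a, b))$icq
    expect_gte(q1, -0.5); expect_lte(q1, 0.5)
    expect_identical(q1, compute_icq(compute_pdm(b, a))$icq)
    q2 <- compute_icq(compute_pdm(3.7 * a + 12, b))$icq
    q3 <- compute_icq(compute_pdm(a, 0.2 * b + 900))$icq
    expect_identical(q1, q2)
    expect_identical(q1, q3)
  }
})

test_that("sign-test p-values match analytic and enumerated values", {
  expect_equal(icq_significance(100, 100), 2 * 0.5^100)
  expect_equal(icq_significance(0, 100), 2 * 0.5^100)
  expect_equal(icq_significance(50, 100), 1)
  # independent oracle: direct enumeration of the binomial tail
  tail_ge_60 <- sum(dbinom(60:100, 100, 0.5))
  expect_equal(icq_significance(60, 100), 2 * tail_ge_60, tolerance = 1e-12)
  expect_equal(round(icq_significance(60, 100), 4), 0.0569)
  # agrees with the built-in exact binomial test (symmetric null)
  for (k in c(40, 55, 60, 75)) {
    expect_equal(icq_significance(k, 100),
                 binom.test(k, 100, 0.5)$p.value, tolerance = 1e-12)
  }
  expect_error(icq_significance(5, 0), "positive count")
  expect_error(icq_significance(11, 10))
})

test_that("sign test holds its nominal type-I error on null channels", {
  set.seed(2024)
  n_sim <- 200
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    r <- compute_icq(compute_pdm(runif(1e4), runif(1e4)))
    rej[i] <- r$p_value < 0.05
  }
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("coloc_mask implements the threshold/ratio rule", {
  expect_true(coloc_mask(100, 100)$mask)
  expect_false(coloc_mask(100, 50)$mask)       # ratio 50 < 97
  expect_false(coloc_mask(100, 40)$mask)       # below threshold too
  expect_false(coloc_mask(49, 49)$mask)        # both below threshold 50
  expect_true(coloc_mask(60, 60, coloc_params(ratio = 90))$mask)
  # both zero skips the ratio test but fails the threshold
  expect_false(coloc_mask(0, 0)$mask)
  expect_true(coloc_mask(0, 0, coloc_params(ratio = 97, 0, 0))$mask)
  expect_error(coloc_mask(1:3, 1:4), "same shape")
  expect_error(coloc_params(ratio = 101), "0, 100")
})

test_that("coloc_mask count equals the brute-force oracle on small grids", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(sample(0:120, 64, replace = TRUE), 8)
    b <- matrix(sample(0:120, 64, replace = TRUE), 8)
    if (i > 5) b <- a + matrix(sample(-3:3, 64, replace = TRUE), 8)
    p <- coloc_params(ratio = sample(c(80, 97, 100), 1),
                      threshold_a = 50, threshold_b = 50)
    expect_identical(coloc_mask(a, b, p)$n_colocalized,
                     brute_coloc_count(a, b, p$ratio, p$threshold_a,
                                       p$threshold_b))
  }
})

test_that("ICA plot data is normalized and skews positive when co-dependent", {
  d <- ica_plot_data(c(0, 10), c(5, 7))
  expect_equal(d$channel_a$intensity, c(0, 1))
  # constant channel: all PDM exactly zero
  d2 <- ica_plot_data(rep(4, 6), runif(6, 1, 10))
  expect_true(all(d2$channel_a$pdm == 0))
  expect_error(ica_plot_data(rep(0, 6), runif(6)), "all zero")
  # strongly co-dependent synthetic pair: most points in the positive half
  out <- gen_coloc_stack(coloc_spec(128, 128, 2, w = 0.8, seed = 21))
  d3 <- ica_plot_data(get_channel(out$stack, "a", drop = FALSE),
                      get_channel(out$stack, "b", drop = FALSE))
  expect_gte(mean(d3$channel_a$pdm > 0), 0.6)
  expect_gte(mean(d3$channel_b$pdm > 0), 0.6)
})

test_that("icq() wrapper accepts stacks, arrays and masks", {
  out <- gen_coloc_stack(coloc_spec(32, 32, 2, w = 1, noise_sd = 0, seed = 1))
  expect_identical(icq(out$stack)$icq, 0.5)
  x <- matrix(runif(100, 0, 100), 10)
  expect_identical(icq(x, b = x)$icq, 0.5)
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  r <- icq(x, b = x, mask = m)
  expect_identical(r$n_pixels, 50L)
})
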