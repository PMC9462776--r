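params <- preset_t1()

test_that("the exact product form matches closed forms and a brute-force
           Monte-Carlo oracle", {
  # constant path: 1 - Phi(z)^T
  p <- blink_prob_path(rep(48, 25), sigma = 3, y_b = 53.3)$probability
  expect_equal(p, 1 - pnorm((53.3 - 48) / 3)^25, tolerance = 1e-12)

  # 3-sample path against dense Monte Carlo at 1e6 draws
  d <- c(47, 50.5, 44)
  exact <- blink_prob_path(d, sigma = 3.2, y_b = 53.3)$probability
  mc <- withr::with_seed(99, {
    z <- matrix(rnorm(3 * 1e6, sd = 3.2), nrow = 3)
    mean(pmax(z[1, ] + d[1], z[2, ] + d[2], z[3, ] + d[3]) >= 53.3)
  })
  se <- sqrt(exact * (1 - exact) / 1e6)
  expect_lt(abs(exact - mc), 3 * se)

  # vanishing noise with a sub-threshold path
  expect_equal(blink_prob_path(c(40, 45), sigma = 1e-9,
                               y_b = 53.3)$probability, 0)
  expect_error(blink_prob_path(c(40), sigma = 0, y_b = 53.3),
               class = "ab_invalid_parameter")
})

test_that("Monte-Carlo and exact estimates agree within sampling error", {
  for (lag in c(2L, 3L)) {
    exact <- blink_prob(params, lag, method = "exact")$probability
    mc <- blink_prob(params, lag, method = "monte_carlo", n_reps = 2000,
                     seed = 30 + lag)
    expect_lt(abs(mc$probability - exact), 3 * mc$std_error)
    expect_false(is.na(mc$std_error))
  }
  expect_true(is.na(blink_prob(params, 3, method = "exact")$std_error))
})

test_that("the Gumbel approximation tracks the exact law and is monotone in
           the threshold", {
  flat <- rep(44, 400)
  e <- blink_prob_path(flat, 3.2, 53.3, method = "exact")$probability
  g <- blink_prob_path(flat, 3.2, 53.3, method = "gumbel")$probability
  expect_lt(abs(e - g), 0.05)

  thresholds <- seq(52, 64, by = 2)
  probs <- vapply(thresholds, function(yb) {
    blink_prob_path(flat, 3.2, yb, method = "gumbel")$probability
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("blink probability is monotone in the noise and threshold
           parameters", {
  base <- preset_t1()
  p_at <- function(mu = base$mu, sigma = base$sigma, y_b = base$y_b) {
    blink_prob(model_params(mu = mu, sigma = sigma, y_b = y_b, g2 = base$g2),
               lag = 3, method = "exact")$probability
  }
  # non-decreasing in mu
  p_mu <- vapply(seq(14, 20, by = 1.5), function(m) p_at(mu = m), numeric(1))
  expect_true(all(diff(p_mu) >= 0))
  # non-decreasing in sigma while the deterministic peak is sub-threshold
  p_sd <- vapply(seq(2, 5, by = 0.75), function(s) p_at(sigma = s), numeric(1))
  expect_true(all(diff(p_sd) >= 0))
  # non-increasing in the threshold
  p_yb <- vapply(seq(45, 65, by = 5), function(y) p_at(y_b = y), numeric(1))
  expect_true(all(diff(p_yb) <= 0))
})

test_that("detection curves invert blink probabilities and respect the
           requested estimator", {
  cv <- detection_curve(params, lags = 1:6, method = "exact")
  expect_s3_class(cv, "ab_curve")
  expect_equal(cv$detection, 1 - cv$blink_prob)
  expect_equal(nrow(cv), 6L)
  expect_identical(
    detection_curve(params, 2:3, method = "monte_carlo", n_reps = 200,
                    seed = 4),
    detection_curve(params, 2:3, method = "monte_carlo", n_reps = 200,
                    seed = 4)
  )
  # vanishing-noise parameters with sub-threshold peaks detect everywhere
  quiet <- model_params(sigma = 1e-6, g2 = params$g2)
  expect_equal(detection_curve(quiet, 1:8, method = "exact")$detection,
               rep(1, 8))
  expect_error(detection_curve(params, integer(0)), class = "ab_invalid_lag")
})
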