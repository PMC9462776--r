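params <- preset_t1()

test_that("the calibrated stage-2 gain hits the behavioural reference point
           and is cached deterministically", {
  g2 <- calibrate_gain(params)
  expect_equal(g2, params$g2)
  expect_equal(1 - blink_prob(params, 3, method = "exact")$probability, 0.6,
               tolerance = 1e-7)
  expect_identical(calibrate_gain(params), g2)
})

test_that("synthetic curves are seeded binomial draws around the exact
           detection probabilities", {
  cv <- generate_synthetic_curve(params, 2000, lags = 1:8, seed = 10)
  expect_identical(cv, generate_synthetic_curve(params, 2000, lags = 1:8,
                                                seed = 10))
  expect_true(all(cv$detection_rate >= 0 & cv$detection_rate <= 1))
  expect_equal(cv$n_trials, rep(2000L, 8))
  # lag-1 sparing and U shape survive the sampling noise at this n
  expect_gt(cv$detection_rate[1], cv$detection_rate[2])
  expect_gt(cv$detection_rate[8], cv$detection_rate[2])
  # large n converges on the exact curve
  big <- generate_synthetic_curve(params, 1e5, lags = 3, seed = 11)
  p_exact <- 1 - blink_prob(params, 3, method = "exact")$probability
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(big$detection_rate - p_exact), 3 * se)
})

test_that("least-squares fitting recovers generating noise parameters", {
  cv <- generate_synthetic_curve(params, 2000, lags = 1:8, seed = 20)
  fit <- fit_params(cv, free = c("mu", "sigma"),
                    params_init = model_params(mu = 15.5, sigma = 4,
                                               g2 = params$g2))
  expect_s3_class(fit, "ab_fit")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$mu - 17.4) / 17.4, 0.05)
  expect_lt(abs(fit$params$sigma - 3.2) / 3.2, 0.10)
  # the optimiser never returns something worse than its start
  objective_of <- function(p) {
    pred <- vapply(cv$lag, function(l) {
      1 - blink_prob(p, l, method = "exact")$probability
    }, numeric(1))
    sum((pred - cv$detection_rate)^2)
  }
  expect_lte(fit$objective_value,
             objective_of(model_params(mu = 15.5, sigma = 4,
                                       g2 = params$g2)))
  # deterministic objective: refitting reproduces the estimates exactly
  refit <- fit_params(cv, free = c("mu", "sigma"),
                      params_init = model_params(mu = 15.5, sigma = 4,
                                                 g2 = params$g2))
  expect_equal(fit$estimates, refit$estimates)
})

test_that("a saturated target curve drives the fit towards certain detection", {
  flat <- tibble::tibble(lag = 1:8, detection_rate = rep(1, 8))
  fit <- fit_params(flat, free = c("mu", "sigma"), params_init = params)
  pred <- 1 - blink_prob(fit$params, 3, method = "exact")$probability
  expect_lt(fit$objective_value, 0.01)
  expect_gt(pred, 0.98)
})

test_that("tidy and glance summarise fits in broom style", {
  cv <- generate_synthetic_curve(params, 1000, lags = c(1:4, 6, 8), seed = 30)
  fit <- fit_params(cv, free = "mu", params_init = params)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "fixed"))
  expect_equal(td$fixed[td$term == "mu"], FALSE)
  expect_true(all(td$fixed[td$term != "mu"]))
  gl <- glance(fit)
  expect_named(gl, c("objective_value", "n_evaluations", "n_lags",
                     "converged"))
  expect_equal(gl$n_lags, 6L)
  expect_gte(gl$objective_value, 0)
})

test_that("invalid curves and bounds are rejected", {
  bad <- tibble::tibble(lag = 1:3, detection_rate = c(0.5, 1.2, 0.4))
  expect_error(fit_params(bad), class = "ab_invalid_parameter")
  cv <- generate_synthetic_curve(params, 500, lags = 1:4, seed = 2)
  expect_error(fit_params(cv, free = "mu", lower = c(mu = 20),
                          upper = c(mu = 10)),
               class = "ab_invalid_parameter")
})
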