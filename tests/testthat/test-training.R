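params <- preset_t1()

test_that("the U-shape event product is a probability and needs the right
           lags", {
  us <- ushape_product(params, method = "exact")
  expect_gte(us, 0)
  expect_lte(us, 1)
  expect_error(ushape_product(params, lags = 2:4),
               class = "ab_criterion_undefined")
  expect_error(ushape_product(params, lags = c(1, 5, 7)),
               class = "ab_criterion_undefined")
  # degenerate regimes: no blinking anywhere makes the lag-2 factor zero
  quiet <- model_params(sigma = 1e-6, g2 = params$g2)
  expect_equal(ushape_product(quiet, method = "exact"), 0)
  # Monte-Carlo and exact estimates of the product agree
  us_mc <- ushape_product(params, reps = 2000, seed = 13)
  expect_lt(abs(us_mc - us), 0.08)
})

test_that("consistency checks separate training-consistent pairs from nulls", {
  ok <- check_consistency(noise_params(17.5, 3.15), noise_params(14.5, 3.8))
  expect_true(ok$consistent)
  expect_true(all(ok$report$pass))
  expect_named(ok$report, c("condition", "value", "pass"))

  # no change between times: the detection-improvement condition must fail
  same <- check_consistency(noise_params(17.4, 3.2), noise_params(17.4, 3.2))
  expect_false(same$consistent)
  expect_false(same$report$pass[same$report$condition == "detection_time2_min"])

  # a huge time-2 baseline blinks at every lag: the U-shape condition fails
  noisy <- check_consistency(noise_params(17.4, 3.2), noise_params(30, 3.2))
  expect_false(noisy$report$pass[noisy$report$condition == "ushape_time2"])
})

test_that("the noise sweep finds a consistent region with the reported
           structure", {
  sw <- sweep_noise_grid(params, mu = seq(13, 19, by = 0.5),
                         sigma = seq(2.75, 4.25, by = 0.5))
  expect_true(all(sw$grid$detection >= 0 & sw$grid$detection <= 1))
  expect_true(all(sw$grid$ushape >= 0 & sw$grid$ushape <= 1))
  # detection is monotone non-increasing in mu at fixed sigma
  for (s in unique(sw$grid$sigma)) {
    col <- dplyr::arrange(dplyr::filter(sw$grid, sigma == s), mu)
    expect_true(all(diff(col$detection) <= 1e-12))
  }
  expect_gt(nrow(sw$pairs), 0)
  # every reported pair re-passes the full consistency check
  pick <- sw$pairs[c(1, nrow(sw$pairs)), ]
  for (i in seq_len(nrow(pick))) {
    chk <- check_consistency(noise_params(pick$mu1[i], pick$sigma1[i]),
                             noise_params(pick$mu2[i], pick$sigma2[i]),
                             params_base = params)
    expect_true(chk$consistent)
  }
  # training moves the noise towards lower baseline and larger fluctuations
  expect_true(all(sw$pairs$mu2 < sw$pairs$mu1))
  expect_gt(mean(sw$pairs$sigma_ratio), 1)
})

test_that("the training interaction design is symmetric and seeded", {
  sc <- training_scenario("practitioners")
  expect_equal(sc$time1_noise$mean, 17.5)
  expect_equal(sc$time2_noise$sd, 3.8)
  ti <- training_interaction(n_reps = 500, seed = 14)
  expect_identical(ti$cells,
                   training_interaction(n_reps = 500, seed = 14)$cells)
  expect_equal(nrow(ti$cells), 8L)
  expect_equal(100 * ti$interaction / ti$denominator, ti$interaction_pct)
  # identical scenarios in both arms cancel exactly
  same <- training_interaction(practitioners = training_scenario("novices"),
                               novices = training_scenario("novices"),
                               n_reps = 500, seed = 15)
  expect_lt(abs(same$interaction), 0.02)
})

test_that("matched-noise load traces isolate the training-induced shift", {
  tr <- load_traces_before_after(training_scenario("practitioners"),
                                 lag = 2, seed = 6)
  t1 <- dplyr::filter(tr, time == "time1")
  t2 <- dplyr::filter(tr, time == "time2")
  # deterministic baseline drops by exactly mu1 - mu2 = 3 load units
  expect_equal(unique(round(t1$det_load - t2$det_load, 10)), 3)
  expect_gt(unique(t2$sigma), unique(t1$sigma))
  # identical standard-normal draws underlie both traces
  z1 <- (t1$load - t1$det_load) / t1$sigma
  z2 <- (t2$load - t2$det_load) / t2$sigma
  expect_equal(z1, z2, tolerance = 1e-12)
})
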