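params <- preset_t1()

test_that("sensory trace is bounded, silent for silent input, and matches a
           direct-summation convolution", {
  spec <- stimulus_spec(3)
  train <- build_impulse_train(spec)
  tr <- sensory_trace(train, params)
  expect_true(all(tr$values >= 0 & tr$values <= 1))

  # silent input: zero out the train
  silent <- train
  silent$values[] <- 0L
  expect_true(all(sensory_trace(silent, params)$values == 0))

  # independent O(n m) convolution oracle
  h1 <- stage1_kernel(params)
  direct <- pmin(conv_direct(as.numeric(train$values), h1$coefficients), 1)
  expect_equal(tr$values, direct, tolerance = 1e-10)
})

test_that("a lone target stays below the clipping threshold; consecutive
           targets are clipped sub-linearly", {
  spec1 <- stimulus_spec(1)
  single <- sensory_trace(build_impulse_train(spec1, n_targets = 1), params)
  expect_lt(max(single$values), 1)
  expect_equal(single$clipped_mass, 0)

  pair <- sensory_trace(build_impulse_train(spec1), params)
  expect_gt(pair$clipped_mass, 0)
  # trace of the pair <= sum of traces of each target alone, strictly at
  # clipped samples
  u1 <- build_impulse_train(spec1, n_targets = 1)
  u2 <- u1
  u2$values <- c(integer(10), u1$values[seq_len(length(u1$values) - 10)])
  s1 <- sensory_trace(u1, params)$values
  s2 <- sensory_trace(u2, params)$values
  expect_true(all(pair$values <= s1 + s2 + 1e-12))
  expect_gt(sum((s1 + s2) - pair$values), 0)
})

test_that("clipping loss is maximal at lag 1 and non-increasing over lags 1-4", {
  loss <- vapply(1:4, function(l) clipping_loss(params, l), numeric(1))
  expect_true(all(diff(loss) <= 0))
  expect_equal(which.max(loss), 1L)
})

test_that("superposition holds exactly in the unclipped regime", {
  # small g1: no clipping anywhere, so the stimulus-driven load is additive
  lin <- model_params(g1 = 0.5, g2 = params$g2)
  lag <- 4L
  pair <- deterministic_load(lin, lag)
  expect_equal(clipping_loss(lin, lag), 0)
  single1 <- deterministic_load(lin, lag, n_targets = 1)
  # T2 response = T1 response shifted by lag x 10 samples
  shift <- lag * 10L
  n <- nrow(pair)
  t2_resp <- c(rep(0, shift), (single1$det_load - lin$mu)[1:(n - shift)])
  expect_equal(pair$det_load - lin$mu,
               (single1$det_load - lin$mu) + t2_resp,
               tolerance = 1e-10)
})

test_that("attentional load decomposes into deterministic path plus noise", {
  tr <- sensory_trace(build_impulse_train(stimulus_spec(3)), params)
  load <- attentional_load(tr, params, seed = 7)
  expect_equal(load$load, load$det_load + load$noise - params$mu)
  expect_identical(load, attentional_load(tr, params, seed = 7))
  # near-zero noise collapses the load onto mu for silent input
  quiet <- model_params(sigma = 1e-9, g2 = params$g2)
  silent <- build_impulse_train(stimulus_spec(3))
  silent$values[] <- 0L
  tr0 <- sensory_trace(silent, quiet)
  l0 <- attentional_load(tr0, quiet, seed = 1)
  expect_equal(l0$load, rep(quiet$mu, nrow(l0)), tolerance = 1e-6)
})

test_that("the realised load is unbiased around the deterministic path", {
  tr <- sensory_trace(build_impulse_train(stimulus_spec(3)), params)
  n_rep <- 4000L
  probe <- c(150L, 250L, 350L) # samples spanning baseline and peak
  loads <- vapply(seq_len(n_rep), function(i) {
    attentional_load(tr, params, seed = i)$load[probe]
  }, numeric(3))
  det <- attentional_load(tr, params, seed = 1)$det_load[probe]
  tol <- 4 * params$sigma / sqrt(n_rep)
  expect_true(all(abs(rowMeans(loads) - det) < tol))
})

test_that("well-separated targets produce two distinct load peaks", {
  det <- deterministic_load(params, lag = 15)$det_load
  # interior local maxima of the noise-free path
  d1 <- diff(det)
  turns <- which(d1[-1] < 0 & d1[-length(d1)] > 0)
  expect_gte(length(turns), 2L)
})

test_that("trial simulation is seeded, consistent, and validates parameters", {
  t1 <- simulate_trials(params, lag = 3, n_reps = 20, seed = 5)
  expect_identical(t1, simulate_trials(params, lag = 3, n_reps = 20, seed = 5))
  expect_equal(t1$blinked, t1$max_load >= params$y_b)
  expect_equal(t1$p3b, t1$rai / params$sigma)
  # single target, noise-free peak is far below threshold: no blinks
  one <- simulate_trials(params, lag = 3, n_reps = 50, seed = 2, n_targets = 1)
  expect_false(any(one$blinked))
  # a threshold at or below the noise baseline is rejected outright
  expect_error(model_params(mu = 17.4, y_b = 17), class = "ab_invalid_parameter")
})

test_that("rest-state blink probability is negligible under the reference
           parameters", {
  # with no stimulus the load is i.i.d. N(mu, sigma^2); the exact crossing
  # probability over a full analysis window must be far below 1e-6
  w <- length(blinksim:::trial_base(params, 3L)$base_win)
  p_rest <- blink_prob_path(rep(params$mu, w), params$sigma, params$y_b,
                            method = "exact")$probability
  expect_lt(p_rest, 1e-6)
})
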