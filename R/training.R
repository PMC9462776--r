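#' Behavioural consistency conditions for training effects
#'
#' The three conditions a pair of mental-noise parameter sets (time 1 = before
#' training, time 2 = after) must satisfy to be consistent with the reported
#' effects of intensive mental training:
#'
#' 1. T2 detection at `lag_for_detection` is `detection_t1_center` plus/minus
#'    `detection_t1_tol` at time 1 and at least `detection_t2_min` at time 2.
#' 2. The T1-evoked P3b amplitude drops between time 1 and time 2 by a factor
#'    in `[p3b_factor_min, p3b_factor_max]`.
#' 3. Both parameter sets reproduce the U-shaped detection profile: the
#'    product of the probabilities of no blink at lag 1, a blink at lag 2, and
#'    no blink at every lag from 5 up to `max(ushape_lags)` is at least
#'    `ushape_min_product`.
#'
#' @param lag_for_detection Lag for the detection conditions (default 3).
#' @param detection_t1_center,detection_t1_tol Time-1 detection band (0.6,
#'   0.1).
#' @param detection_t2_min Minimum time-2 detection (0.8).
#' @param p3b_factor_min,p3b_factor_max Allowed P3b reduction factor range
#'   (1.25, 2).
#' @param ushape_min_product Minimum U-shape event product (0.2).
#' @param ushape_lags Lags entering the U-shape criterion (1 to 11).
#' @param ushape_reps Monte-Carlo repetitions per lag when the criterion is
#'   estimated by simulation (2000).
#' @return A list of class `ab_consistency_conditions`.
#' @export
consistency_conditions <- function(lag_for_detection = 3L,
                                   detection_t1_center = 0.6,
                                   detection_t1_tol = 0.1,
                                   detection_t2_min = 0.8,
                                   p3b_factor_min = 1.25,
                                   p3b_factor_max = 2,
                                   ushape_min_product = 0.2,
                                   ushape_lags = 1:11,
                                   ushape_reps = 2000L) {
  stopifnot(p3b_factor_min < p3b_factor_max, detection_t1_tol > 0,
            detection_t2_min > 0, ushape_min_product > 0)
  structure(
    list(lag_for_detection = as.integer(lag_for_detection),
         detection_t1_center = detection_t1_center,
         detection_t1_tol = detection_t1_tol,
         detection_t2_min = detection_t2_min,
         p3b_factor_min = p3b_factor_min,
         p3b_factor_max = p3b_factor_max,
         ushape_min_product = ushape_min_product,
         ushape_lags = as.integer(ushape_lags),
         ushape_reps = as.integer(ushape_reps)),
    class = "ab_consistency_conditions"
  )
}

check_ushape_lags <- function(lags) {
  if (!(1L %in% lags) || !(2L %in% lags) || !any(lags >= 5L)) {
    abort_ab("U-shape criterion needs lags 1, 2 and at least one lag >= 5.",
             "ab_criterion_undefined")
  }
  invisible(lags)
}

#' U-shape event product
#'
#' Product of the probabilities of the three events that define the classic
#' U-shaped detection profile with lag-1 sparing: no blink at lag 1, a blink
#' at lag 2, and no blink at any lag from 5 up to the largest requested lag
#' (the per-lag no-blink probabilities are multiplied, treating lags as
#' independent trials). Values of at least 0.2 mark parameter sets that
#' reproduce the profile.
#'
#' @inheritParams simulate_trials
#' @param reps Monte-Carlo repetitions per lag (used when
#'   `method = "monte_carlo"`).
#' @param lags Lags to simulate; must include 1, 2 and at least one lag >= 5.
#' @param method `"monte_carlo"` (reference procedure) or `"exact"` (analytic
#'   per-lag probabilities; deterministic, used by the parameter sweep).
#' @return A scalar in `[0, 1]`.
#' @examples
#' ushape_product(ab_preset("time1"), method = "exact")
#' @export
ushape_product <- function(params, reps = 2000L, lags = 1:11, seed = NULL,
                           method = c("monte_carlo", "exact")) {
  stopifnot(inherits(params, "ab_model_params"))
  method <- match.arg(method)
  lags <- as.integer(lags)
  check_ushape_lags(lags)
  reps <- check_count(reps, "reps")
  p <- maybe_with_seed(seed, {
    vapply(lags, function(l) {
      blink_prob(params, l, method = if (method == "exact") "exact"
                 else "monte_carlo", n_reps = reps)$probability
    }, numeric(1))
  })
  names(p) <- lags
  unname((1 - p[lags == 1L]) * p[lags == 2L] * prod(1 - p[lags >= 5L]))
}

#' Mental-training scenario for a group
#'
#' Mental-noise parameters before (time 1) and after (time 2) the training
#' period. The shipped defaults follow the simulated group comparison:
#' practitioners move from (17.5, 3.15) to (14.5, 3.8); novices stay at
#' (17, 3).
#'
#' @param group `"practitioners"` or `"novices"`.
#' @param time1_noise,time2_noise Optional [noise_params()] overrides.
#' @return A list of class `ab_training_scenario`.
#' @export
training_scenario <- function(group = c("practitioners", "novices"),
                              time1_noise = NULL, time2_noise = NULL) {
  group <- match.arg(group)
  if (is.null(time1_noise)) {
    time1_noise <- if (group == "practitioners") noise_params(17.5, 3.15)
                   else noise_params(17, 3)
  }
  if (is.null(time2_noise)) {
    time2_noise <- if (group == "practitioners") noise_params(14.5, 3.8)
                   else noise_params(17, 3)
  }
  stopifnot(inherits(time1_noise, "ab_noise_params"),
            inherits(time2_noise, "ab_noise_params"))
  structure(list(group = group, time1_noise = time1_noise,
                 time2_noise = time2_noise),
            class = "ab_training_scenario")
}

#' Check a (time 1, time 2) noise pair against the consistency conditions
#'
#' Evaluates the three behavioural conditions (see
#' [consistency_conditions()]) for a pair of mental-noise parameter sets
#' sharing the structural parameters of `params_base`. Detection and U-shape
#' probabilities use the exact product-form estimator by default, making the
#' check deterministic and stable under reseeding; Monte-Carlo estimation at
#' the stated repetition counts is available via `method`. The P3b reduction
#' factor uses the noise-free deterministic RAI at the detection lag, so
#' condition 2 is a smooth function of the noise parameters.
#'
#' @param noise1,noise2 [noise_params()] for time 1 and time 2.
#' @param params_base An [model_params()] supplying filters, gains and
#'   threshold.
#' @param cond A [consistency_conditions()] object.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param seed Optional integer seed (Monte-Carlo only).
#' @return A list of class `ab_consistency` with elements `consistent`
#'   (logical) and `report` (a tibble with one row per condition: `condition`,
#'   `value`, `pass`).
#' @examples
#' check_consistency(noise_params(17.5, 3.15), noise_params(14.5, 3.8))
#' @export
check_consistency <- function(noise1, noise2,
                              params_base = model_params(),
                              cond = consistency_conditions(),
                              method = c("exact", "monte_carlo"),
                              seed = NULL) {
  stopifnot(inherits(noise1, "ab_noise_params"),
            inherits(noise2, "ab_noise_params"),
            inherits(params_base, "ab_model_params"),
            inherits(cond, "ab_consistency_conditions"))
  method <- match.arg(method)
  p1 <- with_noise(params_base, noise1)
  p2 <- with_noise(params_base, noise2)
  bp_method <- if (method == "exact") "exact" else "monte_carlo"

  maybe_with_seed(seed, {
    det1 <- 1 - blink_prob(p1, cond$lag_for_detection, method = bp_method,
                           n_reps = 1000L)$probability
    det2 <- 1 - blink_prob(p2, cond$lag_for_detection, method = bp_method,
                           n_reps = 1000L)$probability
    ratio <- (rai_deterministic(p1, cond$lag_for_detection) / p1$sigma) /
             (rai_deterministic(p2, cond$lag_for_detection) / p2$sigma)
    us1 <- ushape_product(p1, reps = cond$ushape_reps, lags = cond$ushape_lags,
                          method = method)
    us2 <- ushape_product(p2, reps = cond$ushape_reps, lags = cond$ushape_lags,
                          method = method)
    report <- tibble::tibble(
      condition = c("detection_time1_band", "detection_time2_min",
                    "p3b_reduction_factor", "ushape_time1", "ushape_time2"),
      value = c(det1, det2, ratio, us1, us2),
      pass = c(
        abs(det1 - cond$detection_t1_center) <= cond$detection_t1_tol,
        det2 >= cond$detection_t2_min,
        ratio >= cond$p3b_factor_min & ratio <= cond$p3b_factor_max,
        us1 >= cond$ushape_min_product,
        us2 >= cond$ushape_min_product
      )
    )
    structure(list(consistent = all(report$pass), report = report,
                   method = method),
              class = "ab_consistency")
  })
}

#' @export
print.ab_consistency <- function(x, ...) {
  cat(sprintf("<consistency check> %s (%s)\n",
              if (x$consistent) "PASS" else "FAIL", x$method))
  print(x$report)
  invisible(x)
}

with_noise <- function(params, noise) {
  model_params(noise = noise, y_b = params$y_b, tau1_ms = params$tau1_ms,
               l1 = params$l1, tau2_ms = params$tau2_ms, l2 = params$l2,
               dt_ms = params$dt_ms, g1 = params$g1, g2 = params$g2)
}

# Exact per-lag no-blink probabilities for a grid of (mu, sigma) points,
# re-using the cached deterministic base paths. Returns a points x lags
# matrix.
exact_noblink_grid <- function(params_base, mu, sigma, lags) {
  vapply(lags, function(l) {
    base <- trial_base(params_base, l, 2L)$base_win
    task <- params_base$g2 * base
    vapply(seq_along(mu), function(i) {
      exp(sum(stats::pnorm(params_base$y_b, mean = mu[i] + task,
                           sd = sigma[i], log.p = TRUE)))
    }, numeric(1))
  }, numeric(length(mu)))
}

#' Sweep the mental-noise parameter space
#'
#' Evaluates, on a (mu, sigma) grid, the exact T2 detection probability at the
#' condition lag, the noise-free model P3b amplitude, and the U-shape event
#' product, then enumerates all (time 1, time 2) grid-point pairs satisfying
#' the behavioural consistency conditions. All quantities use the analytic
#' product-form probabilities, so the sweep is deterministic.
#'
#' @param params_base An [model_params()] supplying structure, gains and
#'   threshold.
#' @param mu,sigma Numeric vectors of grid values (defaults: mu 12 to 20,
#'   sigma 2.5 to 4.5, step 0.25).
#' @param cond A [consistency_conditions()] object.
#' @return A list of class `ab_sweep`: `grid` (tibble with `mu`, `sigma`,
#'   `detection`, `p3b`, `ushape`), `pairs` (tibble of consistent pairs with
#'   `mu1`, `sigma1`, `mu2`, `sigma2`, `p3b_ratio`, `mu_ratio`,
#'   `sigma_ratio`), and `cond`.
#' @examples
#' sw <- sweep_noise_grid(mu = seq(13, 18, 1), sigma = seq(3, 4, 0.5))
#' nrow(sw$pairs)
#' @export
sweep_noise_grid <- function(params_base = model_params(),
                             mu = seq(12, 20, by = 0.25),
                             sigma = seq(2.5, 4.5, by = 0.25),
                             cond = consistency_conditions()) {
  stopifnot(inherits(params_base, "ab_model_params"),
            inherits(cond, "ab_consistency_conditions"))
  if (length(mu) < 1L || length(sigma) < 1L) {
    abort_ab("`mu` and `sigma` grids must be non-empty.",
             "ab_invalid_parameter")
  }
  check_ushape_lags(cond$ushape_lags)
  grid <- tidyr::expand_grid(mu = mu, sigma = sigma)
  lags <- sort(unique(c(cond$ushape_lags, cond$lag_for_detection)))
  noblink <- exact_noblink_grid(params_base, grid$mu, grid$sigma, lags)
  colnames(noblink) <- lags

  detection <- noblink[, as.character(cond$lag_for_detection)]
  ushape <- noblink[, "1"] * (1 - noblink[, "2"]) *
    apply(noblink[, as.character(cond$ushape_lags[cond$ushape_lags >= 5L]),
                  drop = FALSE], 1L, prod)
  peak <- max(trial_base(params_base, cond$lag_for_detection, 2L)$base_win) *
    params_base$g2
  p3b <- peak / ((params_base$y_b - grid$mu) * grid$sigma)

  grid <- dplyr::mutate(grid, detection = detection, p3b = p3b,
                        ushape = ushape)
  ok_shape <- grid$ushape >= cond$ushape_min_product
  t1_idx <- which(ok_shape &
    abs(grid$detection - cond$detection_t1_center) <= cond$detection_t1_tol)
  t2_idx <- which(ok_shape & grid$detection >= cond$detection_t2_min)
  pairs <- tidyr::expand_grid(i = t1_idx, j = t2_idx)
  ratio <- grid$p3b[pairs$i] / grid$p3b[pairs$j]
  keep <- ratio >= cond$p3b_factor_min & ratio <= cond$p3b_factor_max
  pairs <- tibble::tibble(
    mu1 = grid$mu[pairs$i][keep], sigma1 = grid$sigma[pairs$i][keep],
    mu2 = grid$mu[pairs$j][keep], sigma2 = grid$sigma[pairs$j][keep],
    p3b_ratio = ratio[keep]
  )
  pairs <- dplyr::mutate(pairs, mu_ratio = .data$mu2 / .data$mu1,
                         sigma_ratio = .data$sigma2 / .data$sigma1)
  structure(list(grid = grid, pairs = pairs, cond = cond,
                 params_base = params_base),
            class = "ab_sweep")
}

#' @export
print.ab_sweep <- function(x, ...) {
  cat(sprintf("<noise sweep> %d grid points, %d consistent (time1, time2) pairs\n",
              nrow(x$grid), nrow(x$pairs)))
  if (nrow(x$pairs) > 0) {
    cat(sprintf("  mean mu2/mu1 = %.3f, mean sigma2/sigma1 = %.3f\n",
                mean(x$pairs$mu_ratio), mean(x$pairs$sigma_ratio)))
  }
  invisible(x)
}

#' Training-by-condition-by-group P3b interaction
#'
#' Simulates the 2 x 2 x 2 design (group x time x blink condition) of the
#' training comparison: per-trial P3b amplitudes at the given lag, averaged
#' within each cell after splitting trials by their own blink outcome. The
#' three-way interaction contrast is the practitioners' time change in the
#' no-blink-minus-blink difference, minus the same quantity for novices,
#' reported both in P3b units and as a percentage of the practitioners'
#' time-1 no-blink mean.
#'
#' @param practitioners,novices [training_scenario()] objects.
#' @param params_base An [model_params()] supplying the structural parameters.
#' @param lag Lag at which trials are simulated (default 2, the lag with the
#'   strongest blink engagement).
#' @param n_reps Trials per cell.
#' @param seed Optional integer seed.
#' @return A list of class `ab_interaction` with `cells` (tibble: `group`,
#'   `time`, `condition`, `mean_p3b`, `n`), `interaction` (P3b units),
#'   `interaction_pct` (percent of the practitioners' time-1 no-blink mean)
#'   and `denominator`.
#' @examples
#' training_interaction(n_reps = 200, seed = 1)
#' @export
training_interaction <- function(practitioners = training_scenario("practitioners"),
                                 novices = training_scenario("novices"),
                                 params_base = model_params(),
                                 lag = 2L, n_reps = 2000L, seed = NULL) {
  stopifnot(inherits(practitioners, "ab_training_scenario"),
            inherits(novices, "ab_training_scenario"))
  n_reps <- check_count(n_reps, "n_reps")
  cells <- maybe_with_seed(seed, {
    purrr::map(list(practitioners = practitioners, novices = novices),
               function(sc) {
      purrr::map(list(time1 = sc$time1_noise, time2 = sc$time2_noise),
                 function(ns) {
        conditioned_p3b(with_noise(params_base, ns), lag = lag,
                        n_reps = n_reps)
      })
    })
  })
  cell_tbl <- purrr::imap(cells, function(times, group) {
    purrr::imap(times, function(s, time) {
      tibble::tibble(
        group = group, time = time,
        condition = c("noblink", "blink"),
        mean_p3b = c(s$mean_p3b_noblink, s$mean_p3b_blink),
        n = c(s$n_noblink, s$n_blink)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  cell <- function(group, time, condition) {
    cell_tbl$mean_p3b[cell_tbl$group == group & cell_tbl$time == time &
                        cell_tbl$condition == condition]
  }
  sel <- function(group) {
    (cell(group, "time1", "noblink") - cell(group, "time2", "noblink")) -
      (cell(group, "time1", "blink") - cell(group, "time2", "blink"))
  }
  denom <- cell("practitioners", "time1", "noblink")
  interaction <- sel("practitioners") - sel("novices")
  structure(
    list(cells = cell_tbl,
         interaction = interaction,
         interaction_pct = 100 * interaction / denom,
         denominator = denom, lag = as.integer(lag), n_reps = n_reps,
         seed = seed),
    class = "ab_interaction"
  )
}

#' @export
print.ab_interaction <- function(x, ...) {
  cat(sprintf(
    "<training interaction> lag %d, %d trials/cell\n  three-way contrast: %.4f P3b units = %.1f%% of practitioners' time-1 no-blink mean\n",
    x$lag, x$n_reps, x$interaction, x$interaction_pct))
  print(x$cells)
  invisible(x)
}

#' Matched attentional-load traces before and after training
#'
#' Generates one attentional-load trace per time point of a training scenario
#' using the same standard-normal noise realisation, so the two traces differ
#' only through the noise mean and standard deviation. Useful for visualising
#' how a lower baseline moves the load away from the blinking threshold even
#' when the fluctuations grow.
#'
#' @inheritParams training_interaction
#' @param scenario A [training_scenario()].
#' @return A tibble with columns `time` (`"time1"`/`"time2"`), `sample`,
#'   `time_ms`, `mu`, `sigma`, `det_load`, `load`, `in_window`.
#' @examples
#' load_traces_before_after(training_scenario("practitioners"), seed = 1)
#' @export
load_traces_before_after <- function(scenario, params_base = model_params(),
                                     lag = 2L, seed = NULL) {
  stopifnot(inherits(scenario, "ab_training_scenario"),
            inherits(params_base, "ab_model_params"))
  paths <- trial_base(params_base, lag, 2L)
  n <- length(paths$base_full)
  z <- maybe_with_seed(seed, stats::rnorm(n))
  purrr::imap(list(time1 = scenario$time1_noise,
                   time2 = scenario$time2_noise), function(ns, nm) {
    det <- ns$mean + params_base$g2 * paths$base_full
    tibble::tibble(
      time = nm,
      sample = seq_len(n) - 1L,
      time_ms = (seq_len(n) - 1L) * params_base$dt_ms,
      mu = ns$mean, sigma = ns$sd,
      det_load = det,
      load = det + ns$sd * z,
      in_window = seq_len(n) %in% paths$window
    )
  }) |> dplyr::bind_rows()
}
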