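#' @keywords internal
#' @noRd
default_spec <- function(params, lag, n_targets = 2L) {
  tds <- max(1L, as.integer(round(100 / params$dt_ms)))
  t1 <- params$l1
  t2_offset <- t1 + (as.integer(lag) + 1L) * tds
  stimulus_spec(
    lag = lag, n_targets = n_targets, sample_period_ms = params$dt_ms,
    target_duration_samples = tds, t1_onset_sample = t1,
    trial_length_samples = t2_offset + params$l1 + params$l2 + 50L
  )
}

# Analysis window (1-based indices): from T1 onset to the offset of the last
# target plus the full length of both impulse responses, so the whole
# stimulus-driven response is covered.
analysis_window <- function(spec, params) {
  end <- min(spec$trial_length_samples,
             spec$t2_offset_sample + params$l1 + params$l2)
  (spec$t1_onset_sample + 1L):end
}

# Deterministic per-trial paths shared by every estimator: the impulse train,
# the clipped sensory trace, and the stage-2 response computed with a
# unit-gain (unit-peak) Gamma kernel, so the noise-free load is
# mu + g2 * base. Cached per structural-parameter/lag combination because the
# sweep and fitting modules re-use the same paths thousands of times.
trial_base <- function(params, lag, n_targets = 2L, spec = NULL) {
  cacheable <- is.null(spec)
  key <- NULL
  if (cacheable) {
    key <- paste("base", lag, n_targets, params$g1, params$tau1_ms, params$l1,
                 params$tau2_ms, params$l2, params$dt_ms, sep = "|")
    cached <- .ab_env[[key]]
    if (!is.null(cached)) {
      return(cached)
    }
    spec <- default_spec(params, lag, n_targets)
  }
  train <- build_impulse_train(spec, n_targets = n_targets)
  trace <- sensory_trace(train, params)
  h2_unit <- gamma_kernel(params$tau2_ms, params$l2, params$dt_ms,
                          normalization = "unit_peak", gain = 1)
  base_full <- conv_fir(trace$values, h2_unit$coefficients)
  window <- analysis_window(spec, params)
  out <- list(spec = spec, u = train$values, trace = trace$values,
              clipped_mass = trace$clipped_mass, base_full = base_full,
              window = window, base_win = base_full[window])
  if (cacheable) {
    .ab_env[[key]] <- out
  }
  out
}

#' Stage 1: the clipped sensory trace
#'
#' Filters the impulse train with the Gaussian sensory kernel and clips the
#' result at the unit likelihood threshold. The clipping makes the response to
#' two temporally close targets sub-linear: the trace of the pair is smaller
#' than the sum of the single-target traces wherever the combined filtered
#' signal exceeds 1, which happens most strongly at lag 1.
#'
#' @param train An [build_impulse_train()] result.
#' @param params An [model_params()] object; its sampling period must match
#'   the stimulus specification.
#' @return An object of class `ab_sensory_trace`: list with `values` (in
#'   `[0, 1]`), the input `u`, the `spec`, and `clipped_mass`, the total
#'   filtered signal removed by clipping (a measure of the sub-linearity).
#' @examples
#' tr <- sensory_trace(build_impulse_train(stimulus_spec(3)), model_params())
#' max(tr$values)
#' @export
sensory_trace <- function(train, params) {
  stopifnot(inherits(train, "ab_impulse_train"),
            inherits(params, "ab_model_params"))
  spec <- train$spec
  if (!isTRUE(all.equal(spec$sample_period_ms, params$dt_ms))) {
    abort_ab("Stimulus and model sampling periods differ.", "ab_unit_mismatch")
  }
  if (spec$trial_length_samples <
      spec$t2_offset_sample + params$l1 + params$l2) {
    abort_ab(paste0(
      "Trial too short: it must contain the last target offset plus the ",
      "length of both impulse responses."
    ), "ab_trial_too_short")
  }
  h1 <- stage1_kernel(params)
  filtered <- pmax(conv_fir(as.numeric(train$values), h1$coefficients), 0)
  values <- pmin(filtered, params$clip_threshold)
  structure(
    list(values = values, u = train$values, spec = spec,
         clipped_mass = sum(pmax(filtered - params$clip_threshold, 0))),
    class = "ab_sensory_trace"
  )
}

#' @export
print.ab_sensory_trace <- function(x, ...) {
  cat(sprintf("<sensory trace> %d samples, max %.3f, clipped mass %.3f\n",
              length(x$values), max(x$values), x$clipped_mass))
  invisible(x)
}

#' Stage 2: the attentional load
#'
#' Filters the sensory trace with the Gamma attentional kernel (gain `g2`) and
#' adds stationary white Gaussian mental noise `N(mu, sigma^2)` drawn
#' independently per sample. Because the noise enters after the second filter,
#' the load samples are independent Gaussians around the deterministic path,
#' which is what makes the exact product-form blink probability available.
#'
#' @param trace An [sensory_trace()] result.
#' @param params An [model_params()] object.
#' @param seed Optional integer seed for the noise draw.
#' @return A tibble of class `ab_load` with one row per sample and columns
#'   `sample` (0-based), `time_ms`, `u`, `trace`, `det_load` (noise-free load,
#'   including the baseline `mu`), `noise` (the realised `n(t)`), and `load`.
#'   Attributes `window` (analysis-window row indices), `params` and `seed`
#'   are attached.
#' @examples
#' tr <- sensory_trace(build_impulse_train(stimulus_spec(3)), model_params())
#' load <- attentional_load(tr, model_params(), seed = 1)
#' @export
attentional_load <- function(trace, params, seed = NULL) {
  stopifnot(inherits(trace, "ab_sensory_trace"),
            inherits(params, "ab_model_params"))
  h2 <- stage2_kernel(params)
  det <- conv_fir(trace$values, h2$coefficients) + params$mu
  n <- length(det)
  noise <- maybe_with_seed(seed, stats::rnorm(n, params$mu, params$sigma))
  out <- tibble::new_tibble(
    list(
      sample = seq_len(n) - 1L,
      time_ms = (seq_len(n) - 1L) * params$dt_ms,
      u = trace$u,
      trace = trace$values,
      det_load = det,
      noise = noise,
      load = det + noise - params$mu
    ),
    nrow = n, class = "ab_load"
  )
  attr(out, "window") <- analysis_window(trace$spec, params)
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Simulate RSVP trials
#'
#' Runs the full pipeline (impulse train, clipped sensory trace, attentional
#' load with fresh noise per trial) and summarises each trial by the maximum
#' load over the analysis window, the blink event (maximum at or above the
#' blinking threshold `y_b`), the resource allocation index and the model P3b
#' amplitude.
#'
#' @param params An [model_params()] object.
#' @param lag T1-T2 lag (1-based integer).
#' @param n_reps Number of independent trials.
#' @param seed Optional integer seed.
#' @param n_targets Number of targets (1 or 2).
#' @param spec Optional [stimulus_spec()] overriding the default trial layout.
#' @return A tibble with columns `trial`, `lag`, `max_load`, `blinked`, `rai`,
#'   `p3b`; the seed is recorded in the `"seed"` attribute.
#' @examples
#' simulate_trials(ab_preset("time1"), lag = 3, n_reps = 5, seed = 1)
#' @export
simulate_trials <- function(params, lag, n_reps = 1L, seed = NULL,
                            n_targets = 2L, spec = NULL) {
  stopifnot(inherits(params, "ab_model_params"))
  n_reps <- check_count(n_reps, "n_reps")
  paths <- trial_base(params, lag, n_targets, spec = spec)
  det_win <- params$mu + params$g2 * paths$base_win
  w <- length(det_win)
  maxima <- maybe_with_seed(seed, {
    z <- matrix(stats::rnorm(w * n_reps), nrow = w)
    col_maxima(det_win + params$sigma * z)
  })
  out <- tibble::tibble(
    trial = seq_len(n_reps),
    lag = as.integer(lag),
    max_load = maxima,
    blinked = maxima >= params$y_b,
    rai = rai_value(maxima, params),
    p3b = rai_value(maxima, params) / params$sigma
  )
  attr(out, "seed") <- seed
  out
}

#' @describeIn simulate_trials Simulate a single trial (one-row tibble).
#' @export
simulate_trial <- function(params, lag, seed = NULL, n_targets = 2L,
                           spec = NULL) {
  simulate_trials(params, lag, n_reps = 1L, seed = seed,
                  n_targets = n_targets, spec = spec)
}

#' Noise-free load path of a trial
#'
#' The deterministic component of the attentional load (sensory trace filtered
#' by the attentional kernel, plus the noise baseline `mu`), as a tibble.
#' Useful for inspecting the overlap of the responses to T1 and T2 at a given
#' lag and for the noise-free resource allocation index.
#'
#' @inheritParams simulate_trials
#' @return A tibble with columns `sample`, `time_ms`, `u`, `trace`,
#'   `det_load`, and a logical `in_window` flag marking the analysis window.
#' @examples
#' deterministic_load(ab_preset("time1"), lag = 15)
#' @export
deterministic_load <- function(params, lag, n_targets = 2L, spec = NULL) {
  stopifnot(inherits(params, "ab_model_params"))
  paths <- trial_base(params, lag, n_targets, spec = spec)
  n <- length(paths$base_full)
  tibble::tibble(
    sample = seq_len(n) - 1L,
    time_ms = (seq_len(n) - 1L) * params$dt_ms,
    u = paths$u,
    trace = paths$trace,
    det_load = params$mu + params$g2 * paths$base_full,
    in_window = seq_len(n) %in% paths$window
  )
}

#' Sensory-stage clipping loss at a given lag
#'
#' Total filtered stage-1 signal removed by the unit clipping threshold on a
#' two-target trial. The loss is maximal at lag 1 (maximal overlap of the two
#' sensory responses) and non-increasing over the first few lags; it is the
#' mechanism behind lag-1 sparing.
#'
#' @inheritParams simulate_trials
#' @return A non-negative scalar (trace units x samples).
#' @examples
#' clipping_loss(model_params(), lag = 1)
#' @export
clipping_loss <- function(params, lag, n_targets = 2L) {
  trial_base(params, lag, n_targets)$clipped_mass
}
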