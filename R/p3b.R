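#' Resource allocation index and model P3b amplitude
#'
#' The resource allocation index (RAI) is the fraction of total attentional
#' capacity drawn by a trial: `(max_t y(t) - mu) / (y_b - mu)`, with the
#' maximum taken over the analysis window. It is near 0 when the attentional
#' system is idle and reaches 1 exactly at the blinking threshold; it is not
#' clamped, so blink trials have RAI >= 1 and rare noise realisations may dip
#' below 0. The model P3b amplitude is the RAI divided by the subject's
#' mental-noise standard deviation, so for a fixed attentional demand larger
#' noise fluctuations give smaller T1-evoked P3b amplitudes.
#'
#' @param load An [attentional_load()] tibble.
#' @param params An [model_params()] object.
#' @return `rai()` returns the scalar index for the trial; `rai_value()` is
#'   the same map applied to pre-computed window maxima (vectorised);
#'   `p3b_amplitude()` scales an RAI by the noise standard deviation.
#' @examples
#' params <- ab_preset("time1")
#' tr <- sensory_trace(build_impulse_train(stimulus_spec(3)), params)
#' rai(attentional_load(tr, params, seed = 1), params)
#' @export
rai <- function(load, params) {
  stopifnot(inherits(load, "ab_load"), inherits(params, "ab_model_params"))
  window <- attr(load, "window")
  rai_value(max(load$load[window]), params)
}

#' @rdname rai
#' @param max_load Numeric vector of window maxima of the attentional load.
#' @export
rai_value <- function(max_load, params) {
  stopifnot(inherits(params, "ab_model_params"))
  if (params$y_b <= params$mu) {
    abort_ab("RAI undefined: `y_b` must exceed `mu`.", "ab_invalid_parameter")
  }
  (max_load - params$mu) / (params$y_b - params$mu)
}

#' @rdname rai
#' @param rai_value_ Numeric vector of resource allocation indices.
#' @param noise An [noise_params()] object (or [model_params()], whose noise
#'   is used).
#' @export
p3b_amplitude <- function(rai_value_, noise) {
  if (inherits(noise, "ab_model_params")) {
    noise <- noise_params(noise$mu, noise$sigma)
  }
  stopifnot(inherits(noise, "ab_noise_params"))
  rai_value_ / noise$sd
}

#' Noise-free resource allocation index at a lag
#'
#' RAI of the deterministic (noise-free) load path, used for smooth
#' parameter-space maps of the model P3b amplitude.
#'
#' @inheritParams simulate_trials
#' @return A scalar RAI.
#' @examples
#' rai_deterministic(ab_preset("time1"), lag = 3)
#' @export
rai_deterministic <- function(params, lag, n_targets = 2L) {
  stopifnot(inherits(params, "ab_model_params"))
  paths <- trial_base(params, lag, n_targets)
  rai_value(params$mu + params$g2 * max(paths$base_win), params)
}

#' P3b amplitude conditioned on the blink outcome
#'
#' Simulates trials at a lag, splits them by blink outcome, and reports the
#' mean per-trial P3b amplitude in each condition. Each trial's P3b uses its
#' own realised window maximum (noise included), since the conditioning is on
#' the trial's own blink event; blink trials therefore always have RAI >= 1
#' and a higher mean P3b than no-blink trials.
#'
#' @inheritParams simulate_trials
#' @return A one-row tibble with `lag`, `mean_p3b_noblink`, `mean_p3b_blink`
#'   (`NA` when a condition has no trials), `n_noblink`, `n_blink`.
#' @examples
#' conditioned_p3b(ab_preset("time1"), lag = 2, n_reps = 200, seed = 1)
#' @export
conditioned_p3b <- function(params, lag, n_reps = 1000L, seed = NULL) {
  trials <- simulate_trials(params, lag, n_reps = n_reps, seed = seed)
  noblink <- trials$p3b[!trials$blinked]
  blink <- trials$p3b[trials$blinked]
  tibble::tibble(
    lag = as.integer(lag),
    mean_p3b_noblink = if (length(noblink)) mean(noblink) else NA_real_,
    mean_p3b_blink = if (length(blink)) mean(blink) else NA_real_,
    n_noblink = length(noblink),
    n_blink = length(blink)
  )
}
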