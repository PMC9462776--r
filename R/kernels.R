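#' Finite impulse responses of the two processing stages
#'
#' The sensory stage uses a symmetric Gaussian window (standard deviation
#' `tau_ms`, the stage-1 time constant); the attentional stage uses a causal
#' Gamma window `t * exp(-t / tau_ms)` with its coefficient at t = 0 set to 0,
#' peaking at `t = tau_ms`. Both are returned as explicit coefficient vectors
#' so the filter cascade is fully specified: the Gamma shape is only defined up
#' to proportionality, hence each kernel carries a `normalization` mode
#' (`"unit_area"`: coefficients sum to 1; `"unit_peak"`: maximum coefficient 1;
#' `"raw"`: unscaled) and a multiplicative `gain` applied afterwards. The
#' package default convention is a unit-area sensory kernel with gain `g1` and
#' a unit-peak attentional kernel with gain `g2` (see [model_params()]).
#'
#' @param tau_ms Time constant in ms (Gaussian standard deviation, or Gamma
#'   rise time). Default 60 for the Gaussian and 500 for the Gamma.
#' @param length Window length in samples (default 90 and 263).
#' @param dt_ms Sampling period in ms (default 10).
#' @param normalization One of `"unit_area"`, `"unit_peak"`, `"raw"`.
#' @param gain Positive multiplier applied after normalization.
#'
#' @return An object of class `ab_kernel`: a list with `coefficients`, `kind`,
#'   `tau_ms`, `dt_ms`, `normalization` and `gain`.
#' @examples
#' h1 <- gaussian_kernel()
#' kernel_fwhm_ms(h1) # about 141 ms
#' h2 <- gamma_kernel()
#' which.max(h2$coefficients) - 1L # peak at sample 50, i.e. t = 500 ms
#' @name kernels
NULL

new_kernel <- function(coefficients, kind, tau_ms, dt_ms, normalization, gain) {
  normalization <- match.arg(normalization, c("unit_area", "unit_peak", "raw"))
  scale <- switch(normalization, unit_area = sum(coefficients),
                  unit_peak = max(coefficients), raw = 1)
  if (scale > 0) {
    coefficients <- coefficients / scale
  }
  structure(
    list(coefficients = coefficients * gain, kind = kind, tau_ms = tau_ms,
         dt_ms = dt_ms, normalization = normalization, gain = gain),
    class = "ab_kernel"
  )
}

#' @rdname kernels
#' @export
gaussian_kernel <- function(tau_ms = 60, length = 90L, dt_ms = 10,
                            normalization = "unit_area", gain = 1) {
  check_positive_scalar(tau_ms, "tau_ms")
  length <- check_count(length, "length")
  check_positive_scalar(dt_ms, "dt_ms")
  check_positive_scalar(gain, "gain")
  k <- seq_len(length) - 1L
  centre <- (length - 1) / 2
  s <- tau_ms / dt_ms
  coef <- exp(-((k - centre)^2) / (2 * s^2))
  new_kernel(coef, "gaussian", tau_ms, dt_ms, normalization, gain)
}

#' @rdname kernels
#' @export
gamma_kernel <- function(tau_ms = 500, length = 263L, dt_ms = 10,
                         normalization = "unit_peak", gain = 1) {
  check_positive_scalar(tau_ms, "tau_ms")
  length <- check_count(length, "length")
  check_positive_scalar(dt_ms, "dt_ms")
  check_positive_scalar(gain, "gain")
  t_ms <- (seq_len(length) - 1L) * dt_ms
  coef <- t_ms * exp(-t_ms / tau_ms)
  coef[1L] <- 0 # causal: zero response at t <= 0
  new_kernel(coef, "gamma", tau_ms, dt_ms, normalization, gain)
}

#' @export
print.ab_kernel <- function(x, ...) {
  cat(sprintf("<%s kernel> tau = %g ms, %d samples (dt = %g ms), %s, gain %g\n",
              x$kind, x$tau_ms, length(x$coefficients), x$dt_ms,
              x$normalization, x$gain))
  invisible(x)
}

#' @rdname kernels
#' @param x An `ab_kernel`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.ab_kernel <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x$coefficients) - 1L,
    time_ms = (seq_along(x$coefficients) - 1L) * x$dt_ms,
    coefficient = x$coefficients
  )
}

#' Full width at half maximum of a kernel
#'
#' Width, in ms, between the first and last points at which the coefficient
#' profile reaches half its maximum, with linear interpolation between samples
#' (the maximum itself is refined parabolically so that a peak falling between
#' two samples is not under-read).
#' For the default Gaussian sensory kernel (`tau_ms = 60`) this is 141 ms to
#' the nearest ms, matching the closed form `2 * sqrt(2 * log(2)) * tau_ms`.
#'
#' @param kernel An `ab_kernel`.
#' @return The width in ms.
#' @export
kernel_fwhm_ms <- function(kernel) {
  stopifnot(inherits(kernel, "ab_kernel"))
  coef <- kernel$coefficients
  peak <- max(coef)
  if (peak <= 0) {
    abort_ab("Kernel is identically zero; FWHM undefined.",
             "ab_degenerate_kernel")
  }
  # reference level: parabolic refinement of the sampled peak, so an argmax
  # falling between samples (e.g. an even-length symmetric window) does not
  # bias the width
  k <- which.max(coef)
  if (k > 1L && k < length(coef)) {
    fl <- coef[k - 1L]
    fm <- coef[k]
    fr <- coef[k + 1L]
    curv <- fl - 2 * fm + fr
    if (curv < 0) {
      peak <- fm - (fl - fr)^2 / (8 * curv)
    }
  }
  half <- peak / 2
  above <- which(coef >= half)
  i <- above[1L]
  j <- above[length(above)]
  # fractional 0-based crossing positions
  left <- if (i == 1L) 0 else {
    (i - 2) + (half - coef[i - 1L]) / (coef[i] - coef[i - 1L])
  }
  right <- if (j == length(coef)) j - 1 else {
    (j - 1) + (coef[j] - half) / (coef[j] - coef[j + 1L])
  }
  (right - left) * kernel$dt_ms
}
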