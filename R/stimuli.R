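#' Stimulus specification for an RSVP two-target trial
#'
#' Describes a rapid serial visual presentation (RSVP) trial on the model's
#' discrete sample grid. Targets are 100 ms impulses (10 samples at the default
#' 10 ms sampling period); the second target (T2) starts `lag` stimulus slots
#' after the first (T1), so the stimulus-onset asynchrony is `lag` x 100 ms and
#' the inter-stimulus interval is `(lag - 1)` x 100 ms. Distractors draw no
#' attentional resources in the model and are encoded as silence (0).
#'
#' @param lag T1-T2 lag, a 1-based positive integer. Lag 1 means T2 starts
#'   immediately at T1 offset.
#' @param n_targets Number of targets in the trial, 1 or 2.
#' @param sample_period_ms Sampling period in ms (default 10).
#' @param target_duration_samples Target duration in samples (default 10,
#'   i.e. 100 ms under the default sampling period).
#' @param t1_onset_sample 0-based sample index of T1 onset. The default (90)
#'   leaves a silent lead-in as long as the default sensory kernel so the
#'   filter transient is fully contained in the trial.
#' @param trial_length_samples Total trial length in samples. The default
#'   extends to T2 offset plus the default lengths of both impulse responses
#'   plus a 50-sample tail, so the attentional response decays inside the
#'   trial.
#'
#' @return An object of class `ab_stimulus_spec`.
#' @examples
#' stimulus_spec(lag = 3)
#' @export
stimulus_spec <- function(lag,
                          n_targets = 2L,
                          sample_period_ms = 10,
                          target_duration_samples = 10L,
                          t1_onset_sample = 90L,
                          trial_length_samples = NULL) {
  if (!is_scalar_number(lag) || lag < 1 || lag != as.integer(lag)) {
    abort_ab("`lag` must be a single integer >= 1.", "ab_invalid_lag")
  }
  lag <- as.integer(lag)
  if (!is_scalar_number(n_targets) || !n_targets %in% c(1L, 2L)) {
    abort_ab("`n_targets` must be 1 or 2.", "ab_invalid_parameter")
  }
  n_targets <- as.integer(n_targets)
  check_positive_scalar(sample_period_ms, "sample_period_ms")
  target_duration_samples <- check_count(target_duration_samples,
                                         "target_duration_samples")
  t1_onset_sample <- check_count(t1_onset_sample, "t1_onset_sample", min = 0L)

  # 0-based exclusive offset of the last target
  t2_offset <- t1_onset_sample + (lag + 1L) * target_duration_samples
  if (is.null(trial_length_samples)) {
    # 403 = default L1 (90) + default L2 (263) + 50-sample tail
    trial_length_samples <- t2_offset + 403L
  }
  trial_length_samples <- check_count(trial_length_samples,
                                      "trial_length_samples")
  if (trial_length_samples < t2_offset) {
    abort_ab("`trial_length_samples` is too short to contain the targets.",
             "ab_trial_too_short")
  }

  structure(
    list(
      lag = lag,
      n_targets = n_targets,
      sample_period_ms = sample_period_ms,
      target_duration_samples = target_duration_samples,
      t1_onset_sample = t1_onset_sample,
      t2_offset_sample = t2_offset,
      trial_length_samples = trial_length_samples
    ),
    class = "ab_stimulus_spec"
  )
}

#' @export
print.ab_stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<RSVP stimulus> lag %d (%d target%s), dt = %g ms, T1 onset at sample %d, %d samples\n",
    x$lag, x$n_targets, if (x$n_targets > 1L) "s" else "",
    x$sample_period_ms, x$t1_onset_sample, x$trial_length_samples
  ))
  invisible(x)
}

#' Build the binary impulse train of a trial
#'
#' Encodes the targets of an RSVP trial as a 0/1 impulse train on the sample
#' grid: T1 occupies `target_duration_samples` samples starting at the T1
#' onset; with two targets, T2 onset follows T1 onset by
#' `lag * target_duration_samples` samples.
#'
#' @param spec An [stimulus_spec()].
#' @param n_targets Number of targets; defaults to the value in `spec`.
#' @return An object of class `ab_impulse_train` with elements `values`
#'   (integer 0/1 vector) and `spec`.
#' @examples
#' train <- build_impulse_train(stimulus_spec(lag = 3))
#' sum(train$values) # two 10-sample targets
#' @export
build_impulse_train <- function(spec, n_targets = spec$n_targets) {
  stopifnot(inherits(spec, "ab_stimulus_spec"))
  if (!is_scalar_number(n_targets) || !n_targets %in% c(1L, 2L)) {
    abort_ab("`n_targets` must be 1 or 2.", "ab_invalid_parameter")
  }
  n_targets <- as.integer(n_targets)
  tds <- spec$target_duration_samples
  values <- integer(spec$trial_length_samples)
  t1 <- spec$t1_onset_sample # 0-based
  values[t1 + seq_len(tds)] <- 1L
  if (n_targets == 2L) {
    t2 <- t1 + spec$lag * tds
    if (t2 + tds > spec$trial_length_samples) {
      abort_ab("Trial too short to contain T2.", "ab_trial_too_short")
    }
    values[t2 + seq_len(tds)] <- 1L
  }
  structure(list(values = values, spec = spec, n_targets = n_targets),
            class = "ab_impulse_train")
}

#' @export
print.ab_impulse_train <- function(x, ...) {
  cat(sprintf("<impulse train> %d samples, %d target sample(s) set\n",
              length(x$values), sum(x$values)))
  invisible(x)
}

#' @describeIn build_impulse_train Tidy view of an impulse train as a tibble
#'   with columns `sample_index` (0-based) and `value`.
#' @param x An `ab_impulse_train`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.ab_impulse_train <- function(x, ...) {
  tibble::tibble(sample_index = seq_along(x$values) - 1L, value = x$values)
}

#' Inter-stimulus interval implied by a T1-T2 lag
#'
#' Each lag step adds one 100 ms stimulus slot between target onsets, so the
#' interval between T1 offset and T2 onset is `(lag - 1) * 100` ms: lag 3 gives
#' 200 ms, lag 1 gives 0 ms (T2 starts right at T1 offset).
#'
#' @param lag Positive integer vector of 1-based lags.
#' @return Numeric vector of inter-stimulus intervals in ms.
#' @examples
#' lag_to_isi_ms(c(1, 3, 5))
#' @export
lag_to_isi_ms <- function(lag) {
  if (!is.numeric(lag) || length(lag) < 1L || anyNA(lag) ||
      any(lag < 1) || any(lag != as.integer(lag))) {
    abort_ab("`lag` must contain integers >= 1.", "ab_invalid_lag")
  }
  (as.integer(lag) - 1L) * 100
}
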