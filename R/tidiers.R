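#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a detection-curve fit
#'
#' @param x An `ab_fit` from [fit_params()].
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `fixed` (whether the parameter was held at its initial value).
#' @exportS3Method generics::tidy
#' @export
tidy.ab_fit <- function(x, ...) {
  terms <- fit_free_params
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x$params[[t]], numeric(1)),
    fixed = !terms %in% x$free
  )
}

#' Glance at a detection-curve fit
#'
#' @inheritParams tidy.ab_fit
#' @return A one-row tibble with `objective_value` (sum of squared errors),
#'   `n_evaluations`, `n_lags` and `converged`.
#' @exportS3Method generics::glance
#' @export
glance.ab_fit <- function(x, ...) {
  tibble::tibble(
    objective_value = x$objective_value,
    n_evaluations = x$n_evaluations,
    n_lags = nrow(x$curve),
    converged = x$converged
  )
}
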