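# internal helpers shared across modules

.ab_env <- new.env(parent = emptyenv())

abort_ab <- function(message, class) {
  rlang::abort(message, class = c(class, "blinksim_error"))
}

# Evaluate `expr` under a fixed RNG seed when one is supplied; otherwise use
# the session RNG stream. Every stochastic exported function funnels through
# this, so seeded calls are bit-reproducible and never disturb the caller's RNG.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort_ab("`seed` must be a single integer or NULL.", "ab_invalid_seed")
    }
    withr::with_seed(as.integer(seed), expr)
  }
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_ab(sprintf("`%s` must be a single positive number.", name),
             "ab_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x < min || x != as.integer(x)) {
    abort_ab(sprintf("`%s` must be a single integer >= %d.", name, min),
             "ab_invalid_parameter")
  }
  as.integer(x)
}

# Full linear convolution of a signal with a causal FIR kernel, zero-padded
# boundaries, truncated to the length of the signal.
conv_fir <- function(x, coefficients) {
  n <- length(x)
  stats::convolve(x, rev(coefficients), type = "open")[seq_len(n)]
}

# Column maxima of a matrix without looping in R over columns.
col_maxima <- function(m) {
  do.call(pmax.int, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}
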