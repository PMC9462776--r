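# Shared fixtures: the calibrated reference presets (the stage-2 gain is
# solved once and cached inside the package, so repeated calls are cheap).
preset_t1 <- function() ab_preset("time1")
preset_t2 <- function() ab_preset("time2")

# Independent O(n m) direct-summation convolution used as an oracle against
# the FFT-based pipeline.
conv_direct <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    j <- seq_len(min(t, length(k)))
    out[t] <- sum(k[j] * x[t - j + 1])
  }
  out
}
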