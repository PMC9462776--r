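---
title: "A two-stage noisy-filter model of the attentional blink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage noisy-filter model of the attentional blink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinksim)
```

## The model

In a rapid serial visual presentation (RSVP) stream, observers often fail to
report a second target (T2) that appears 200–600 ms after a first one (T1) —
the *attentional blink* — yet report it well when it follows T1 immediately
(*lag-1 sparing*). `blinksim` implements a dynamical-systems account of both
effects in which attentional load is the response of a two-stage linear
filter cascade to target impulses, perturbed by additive Gaussian "mental
noise".

Targets are encoded as a binary impulse train $u(t)$ on a 10 ms sample grid:
each target is a 100 ms impulse (10 samples), and T2 starts `lag` stimulus
slots after T1, so the stimulus-onset asynchrony is `lag` × 100 ms.
Distractors are assumed to be rejected pre-attentively and are encoded as
silence.

**Stage 1 (sensory).** The train is filtered by a Gaussian window $h_1$
(standard deviation $\tau_1 = 60$ ms, 90 samples) and clipped at 1,

$$\hat y(t) = \min\{\,u(t) * h_1(t),\; 1\,\},$$

because the sensory trace is read as a likelihood of target presence. The
clipping makes the response to two overlapping targets *sub-linear*: the
shared trace is smaller than the sum of the single-target traces. Overlap —
and hence the clipped mass — is maximal at lag 1, which is what spares T2
there.

**Stage 2 (attentional).** The trace is filtered by a slower causal Gamma
window $h_2(t) \propto t\,e^{-t/\tau_2}$ ($\tau_2 = 500$ ms, 263 samples) and
white Gaussian mental noise $n(t) \sim \mathcal N(\mu, \sigma^2)$ is added:

$$y(t) = \hat y(t) * h_2(t) + n(t).$$

A *blink* occurs when $y(t)$ reaches or crosses the blinking threshold
$y_B$ anywhere in the analysis window; the crossing is attributed to T2
(missed T2, unaffected T1). The *resource allocation index*
$\mathrm{RAI} = (\max_t y(t) - \mu)/(y_B - \mu)$ measures the fraction of
attentional capacity consumed, and the model's T1-evoked P3b amplitude is
$\mathrm{RAI}/\sigma$: for the same demand, larger noise fluctuations mean a
smaller P3b.

Because the noise enters *after* the second filter, load samples are
independent Gaussians around the deterministic path $d(t)$, and the blink
probability has a closed form,
$$P(\text{blink}) = 1 - \prod_t \Phi\!\big((y_B - d(t))/\sigma\big),$$
which the package uses as its reference estimator (`method = "exact"`)
alongside Monte-Carlo simulation and an extreme-value (Gumbel)
approximation of the distribution of the maximal load.

## Reference parameters and the gain convention

The shipped presets use the reference values $\mu_1 = 17.4$,
$\sigma_1 = 3.2$ (before training), $\mu_2 = 13.2$, $\sigma_2 = 3.8$ (after),
$y_B = 53.3$, $\tau_1 = 60$ ms ($L_1 = 90$), $\tau_2 = 500$ ms
($L_2 = 263$), $\Delta t = 10$ ms.

Two gains are *not* determined by those values, because the Gamma kernel is
defined only up to proportionality and the threshold/noise scalars are
meaningless without a load-scale convention. `blinksim` resolves this
explicitly:

* $h_1$ is normalised to unit area and carries the gain $g_1 = 1.4$. The
  admissible interval for $g_1$ is (1.106, 1.681]: below it even two
  consecutive targets never reach the clipping threshold (no lag-1 sparing,
  since a unit-area Gaussian filtered 20-sample boxcar peaks at 0.904);
  above it a lone target already clips. We take the midpoint, which leaves a
  single target peaking at about 0.83 — a confident but not certain
  detection — while consecutive targets clip.
* $h_2$ is normalised to unit peak and carries a gain $g_2$ that is
  *calibrated*, by deterministic root finding on the exact blink
  probability, so that T2 detection at lag 3 under the pre-training noise is
  exactly 0.6 — the centre of the behavioural regime the reference
  parameters encode. The calibrated value is $g_2 = 1.1023$; all presets
  share it.

```{r}
params <- ab_preset("time1")
params
```

Identifiability is the flip side of this convention: the detection curve
constrains only $(y_B - \mu)/\sigma$-type combinations, so
$(g_2, \mu, \sigma, y_B)$ can be traded against each other by an affine
rescaling of the load axis. `fit_params()` therefore fits at most
$\{\mu, \sigma\}$ (optionally $y_B$ or $g_2$) while holding the rest fixed,
and the parameter-recovery tests fix $g_2$ at its true value.

## What the calibrated model does

```{r}
detection_curve(params, lags = 1:8, method = "exact")
```

The curve is U-shaped with lag-1 sparing (detection 0.858 at lag 1 versus
0.418 at lag 2) and recovers beyond lag 5. The U-shape criterion — the
product of the probabilities of *no* blink at lag 1, a blink at lag 2, and
no blink at lags 5–11 — evaluates to about 0.43 for the pre-training preset,
comfortably above the 0.2 mark used to delimit U-shaped regimes:

```{r}
ushape_product(params, method = "exact")
```

Training effects are modelled purely as changes of the noise parameters.
Under the post-training preset, lag-3 detection rises to 0.945 and the
noise-free P3b drops by a factor 1.326 (within the 1.25–2 band):

```{r}
1 - blink_prob(ab_preset("time2"), 3, method = "exact")$probability
(rai_deterministic(ab_preset("time1"), 3) / 3.2) /
  (rai_deterministic(ab_preset("time2"), 3) / 3.8)
```

Sweeping the $(\mu, \sigma)$ grid (defaults $\mu \in [12, 20]$,
$\sigma \in [2.5, 4.5]$, step 0.25, matching the region around the reference
values) and enumerating (time 1, time 2) pairs that satisfy the three
behavioural conditions gives a consistent region in which the baseline
drops — mean $\mu_2/\mu_1 \approx 0.79$ — while the fluctuations *increase*
in every pair ($\sigma_2 > \sigma_1$, mean ratio ≈ 1.36):

```{r}
sw <- sweep_noise_grid(params)
sw
```

## Numerical and design choices

* **Analysis window.** The maximum in the blink event and the RAI is taken
  from T1 onset to T2 offset plus the full length of both impulse responses,
  so the entire stimulus-driven response is covered; trials extend 50
  samples further so no response mass is truncated. The trial duration is
  not prescribed by the behavioural setup itself; results are insensitive to
  extending the window because the resting load sits ≈ 11σ below threshold
  (resting blink probability below 10⁻⁶ per trial).
* **Convolution boundaries.** Full linear convolution with zero padding
  (silence before and after the trial), truncated to the trial length.
* **Threshold semantics.** "Reaches or crosses" is implemented as a closed
  comparison (≥).
* **Gumbel approximation.** The expected exceedance count
  $\Lambda(y) = \sum_t \bar\Phi((y - d(t))/\sigma)$ is matched at the levels
  1 and $e$, fixing the location (where the maximum's CDF is $e^{-1}$) and
  scale of a double-exponential law from the per-sample marginals alone.
  Across lags 1–8 of the pre-training preset it deviates from the exact
  product form by at most ≈ 0.05.
* **Consistency checks.** `check_consistency()` and the sweep use the exact
  product-form probabilities by default, so the consistent region is
  deterministic and stable under reseeding; Monte-Carlo evaluation at 2000
  repetitions per lag is available. The P3b reduction factor (condition 2)
  uses the noise-free RAI at the detection lag, making it a smooth function
  of $(\mu, \sigma)$; the detection conditions default to lag 3 and the
  parameter-space maps to the blink regime around lags 2–4.
* **"Lag 5 and higher".** The U-shape criterion conjoins the no-blink events
  over *all* lags from 5 to the largest simulated lag (11 by default) — the
  stricter of the two possible readings; the lag set is configurable.
* **Optimiser.** The least-squares fit uses the exact detection probability
  inside the objective (no Monte-Carlo jitter), a coarse grid restart and
  Nelder-Mead refinement under box penalties (Brent in one dimension), so
  fits are reproducible bit-for-bit.
* **Seeding.** Every stochastic function takes an explicit `seed` and
  restores the caller's RNG state; seeded calls are bit-reproducible.

## What the synthetic curves do and do not emulate

`generate_synthetic_curve()` draws detection rates as binomial samples of
the model's own exact probabilities at stated per-lag trial counts. It
reproduces the structure of a behavioural lag curve — U shape, lag-1
sparing, sampling noise at realistic n — and is the ground truth for the
parameter-recovery tests (median relative error of recovered $\mu$, $\sigma$
and $y_B - \mu$ is ≈ 1–3 % at 2000 trials/lag over lags 1–8). It does not
emulate real-data features outside the model: lapses, response bias,
T1-report errors, order reversals at lag 1, or between-subject
heterogeneity. Passing recovery tests therefore demonstrates internal
consistency of the estimator, not validity of the model for any particular
data set.

## Known limitations

* Only white Gaussian mental noise is implemented. Temporally correlated
  (e.g. power-law) noise would break the product form and the Gumbel
  normalisation; the per-path estimator interface (`blink_prob_path()`)
  is the seam where a correlated generator could be added.
* The post-training reference pair (13.2, 3.8) satisfies the detection and
  P3b conditions but falls just short of the U-shape product (≈ 0.09 versus
  0.2) under this gain convention: at such a low baseline the lag-2 blink
  probability drops to ≈ 0.12, and the ratio of lag-2 to lag-3 response
  peaks is fixed by the Gamma kernel, so no gain choice can restore it. The
  practitioner scenario pair, (17.5, 3.15) → (14.5, 3.8), satisfies all
  three conditions and is the package's reference example of a consistent
  training effect.
* The group × time × blink-outcome P3b design reproduces the qualitative
  training pattern (novices unchanged; a ≈ 19 % no-blink P3b reduction for
  practitioners), but the *double-difference* interaction contrast is small
  (≈ 0.5–1 % of the time-1 no-blink mean) because dividing by $\sigma$
  reduces blink and no-blink cells almost equally; the selective part of the
  effect survives only as the conditional-truncation residual. Summaries of
  this design should therefore lean on the per-cell means, which
  `training_interaction()` reports alongside the contrast.
* Report-order reversals, distractor-triggered accounts, masking, and
  T1-difficulty manipulations are outside the model's scope.
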