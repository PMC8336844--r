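---
title: "Modelling intra-cellular OCT4 regulation in a growing colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intra-cellular OCT4 regulation in a growing colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptfcolony)
```

## The problem

OCT4 is one of the core pluripotency transcription factors (PTFs) of human
pluripotent stem cells. In time-lapse imaging of a growing colony, each
cell's OCT4 level (in arbitrary fluorescence units, a.f.u.) is a noisy,
*anti-persistent* time series: increases tend to be followed by decreases,
quantified by a Hurst exponent around 0.38 — well below the 0.5 of an
uncorrelated random walk. Expression is regulated around a set-point, its
distribution develops a positive skew and a downward mode shift over the
first two days, and after a differentiation agent (BMP4) is added at 43 h a
subset of cells collapses to near-zero OCT4 while the rest retain it.

`ptfcolony` simulates this system cell by cell and provides the statistics
used to characterise those features. It is a descriptive modelling toolkit:
the goal is to reproduce the qualitative and quantitative signatures above
from simple stochastic building blocks, not to infer molecular mechanism.

## Model family

All dynamics are driven by exact fractional Gaussian noise (fGn) with
Hurst exponent $H$, generated by Davies–Harte circulant embedding
(`generate_fgn`). The generator is exact in law for every $H \in (0,1)$:
its empirical autocovariance matches the closed form
$\gamma(k) = \tfrac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$
(`fgn_autocovariance`), which the test suite checks at lags 0–5 against
Bartlett standard errors.

Per-cell OCT4 series $O(t)$ are generated, one Euler step per 5-minute
frame, by one of:

* **fBm walk** — $O(t) = O(0) + \sigma_A B_H(t)$, optionally with absorbing
  or reflecting boundaries at 0 and 2500 a.f.u.;
* **stochastic logistic equation (SLE), additive noise** —
  $O_{t+1} = O_t + r\,O_t(1 - O_t/K) + \sigma_A\,\xi_t$, with an absorbing
  floor at zero (below zero the drift is also negative and the equation
  runs away);
* **SLE, multiplicative / combined noise** — integrated in
  $X = \ln O$: the drift $r(1 - e^X/K(t))\,g_t$ and the multiplicative term
  $\sigma_M \xi^{(2)}$ advance $X$, and the additive kick is applied in
  level space, $O_{t+1} = e^{\tilde X} + \sigma_A \xi^{(1)}$;
* **SLE with time-dependent $K$** — the combined form with piecewise-
  constant schedules for $K(t)$ (and, where needed, $r(t)$,
  $\sigma_A(t)$, $\sigma_M(t)$);
* **SLE with an Allee effect** — the drift factor becomes
  $g_t = (e^X - A)/K$ once the Allee term is armed (at 43 h in the
  presets), creating an unstable threshold at $O = A$: cells fluctuating
  below $A$ collapse to zero, cells above it continue with suppressed
  logistic growth. Differentiation is thereby *stochastic and emergent*
  rather than imposed by a label.

Rates are per 5-minute frame; schedules are functions of hours.

## The colony base model

`init_colony` starts $N_0$ cells (14 pro-pluripotent + 2 pro-differentiated
by default) with initial OCT4 and cycle durations drawn from samplers, and
— in the default asynchronous mode — a uniformly drawn elapsed-cycle
fraction, so first divisions are spread over frames instead of arriving in
synchronised waves. `run_colony` processes cells in division-time order:
each cell's series is simulated over its remaining cycle with the dynamics
bound to its fate; at division both daughters start at the mother's
pre-division value (symmetric inheritance) with freshly drawn cycle
durations. The run is terminated by a budget of *division events*, not
timesteps; `truncate_to_window` then clips to the window of interest.
A 68-h window on the 5-minute grid holds exactly 817 frame times.

Reproducibility: one root seed governs everything. Each cell's noise
streams and its daughters' cycle draws come from seeds derived
deterministically from (root seed, cell id, stream), so results do not
depend on iteration order, and re-running a manifest reproduces the
trajectory CSV byte for byte.

## Input distributions

The experiment the models were built against reports only summary anchors
for its input distributions, so the default fixtures are parametric
stand-ins chosen from positive-support, right-skewed families:

* cycle durations: a Gamma distribution truncated to [0.25, 30] h,
  moment-matched at construction so the *post-truncation* mean and SD are
  10.3 h and 4 h (the reported values) within 2%;
* initial OCT4: a lognormal with median 1290 a.f.u. (the median of all
  observed values, which also anchors $K$) and coefficient of variation
  0.25. The CV is *not* anchored by any reported value; it is exposed
  prominently in `fixture_config` and should be replaced when data are
  available.

Users with empirical columns (one number per line) get the kernel-density
route instead: `load_empirical` → `kde_sampler`, which resamples a datum
and adds Gaussian kernel noise (Silverman's rule bandwidth), rejection-
resampled into the support.

## Parameter presets

`preset()` returns the published parameter sets: the additive
(r = 0.02, K = 1290, σ_A = 90) and multiplicative (r = 0.005,
σ_M = 0.0045) regimes; the 20-h additive→multiplicative noise switch
(pluripotent K = 1290, differentiated K = 1000, r = 0.01); the 25-h
carrying-capacity drop (pluripotent 1500→1000, differentiated 1100→1000,
r = 0.015, σ_A = 30/20, σ_M = 0.035/0.03); its differentiation extension
(differentiated K→300 and r→0.008 from 43 h); and the Allee regime
(r = 0.025, K = 1290, σ_A = 35, σ_M = 0.035, A = 1000, armed at 43 h).
All use H = 0.38. One published table interleaves its r and K rows
typographically; the preset reconstructs it as the pluripotent K schedule
1500→1000 at 25 h with r = 0.015 throughout, and the differentiated row as
printed. Presets serialise verbatim through the JSON config layer.

## Numerical choices

* **Integration** is explicit Euler at one 5-minute frame per step — the
  cadence of the data, and the published rates (r ≤ 0.025 per frame)
  keep the discretisation error small: the zero-noise path error against
  the logistic closed form is below 1% for the log-space family through
  r = 0.03 and for the O-space additive form through r = 0.025 (1.1% at
  r = 0.03, which is above every published rate for that variant).
* **The additive term in log space.** Transforming the additive-noise SLE
  by $X = \ln O$ gives a noise term $\sigma_A e^{-X}\xi$. Stepping that
  term with Euler is unstable exactly where the Allee model must operate:
  as $O \to 0$ the factor $e^{-X}$ diverges and single steps overshoot by
  orders of magnitude. We therefore apply the additive kick in level
  space, $O_{t+1} = e^{\tilde X} + \sigma_A\xi$ — identical to first
  order, stable during collapse.
* **Expression floor.** Log-space series are clamped at 0.01 a.f.u.
  (indistinguishable from zero at measurement scale). The clamp does not
  decide the cell's future: an armed Allee drift holds a collapsed cell
  down; plain logistic regulation lifts it back towards $K$.
* **Overflow guard.** $X$ is capped at $\ln(10^6)$ with a warning; the
  cap is never hit under any preset (the tests treat a hit as a failure).
* **Division-time rounding.** Real-valued cycle draws are reconciled with
  the 5-minute grid by dividing at the first frame at or after the true
  division time; every cell lives at least one frame.
* **Allee drift prefactor.** The deterministic Allee form is implemented
  as $r\,O\,(1 - O/K)(O - A)/K$ in level space (equivalently
  $g = (O-A)/K$ in log space), giving equilibria at $0$, $A$ (unstable)
  and $K$ — the behaviour the weak/strong Allee regimes require.
* **Fate classification** for Allee runs happens *at the end of the
  observed window*: terminal cells with final OCT4 below the threshold
  (default $A$) are differentiated, the rest pluripotent, and labels
  back-propagate to ancestors as pro-fates (ancestors with mixed
  descendants are `unknown`). Classifying on frames beyond the window
  would let cells change side after the observation ends. The threshold
  itself is not reported anywhere; $A$ is the natural separatrix and is
  overridable.

## Hurst estimation

The per-cell estimator (`estimate_hurst`) is detrended fluctuation
analysis: integrate the demeaned fluctuation series, remove a linear trend
in non-overlapping windows at 12 log-spaced scales from 8 to $n/4$ (run in
both directions so the series tail is used), and read $H$ off the
log–log slope. On ensembles of exact fGn of length 1000 the ensemble mean
recovers the generating $H$ to 0.01–0.02 across $H \in [0.2, 0.8]$ —
calibrated against the generator, which is itself validated against the
closed-form autocovariance. Rescaled-range (R/S) analysis is included for
comparison but carries the classical upward bias for anti-persistent
series (≈ +0.07 at $H = 0.38$), so DFA is the default. Series of 50 or
fewer frames are rejected, the same per-cell inclusion rule used
experimentally; `hurst_ensemble` applies the estimator to each eligible
cell's increment series and reports the ensemble mean and SD. The exact
windowing of the original experimental estimate is not public, which
plausibly contributes to the ±0.09 spread reported there.

## Analysis statistics

`summarise_colony` bundles: the Hurst ensemble; the pooled within-cell
one-frame increment SD (the noise-scale estimator; mother→daughter joins
are excluded since they are continuity points with zero difference by
construction); the in-window median as the carrying-capacity estimate;
time-binned, per-fate OCT4 histograms with per-bin distinct-cell counts
and sample skewness; two-sample Kolmogorov–Smirnov tests between
consecutive time bins (asymptotic p, reject at 0.05, uncorrected — one
comparison per adjacent pair, matching how the shift in the binned
distributions is usually reported); and central tracks (mean, median, and
KDE-argmax mode — a histogram argmax would be a bin-width artefact).
Default time bins split 0–43 h (the pre-differentiation window) into four
equal bins; the true experimental bin edges are not published, so the
default is ours and configurable.

## What the tests do and do not show

The synthetic fixtures match the *reported summaries* (cycle mean/SD/range,
initial-OCT4 median) but not the unpublished shapes of the empirical
distributions, and the colony model deliberately omits: spatial structure
and cell motility, cell death, asymmetric OCT4 partitioning at division,
the post-BMP4 shortening of cycle times (the cycle sampler is reused
unchanged throughout, as in the original analysis), cross-division noise
correlation (each cell gets an independent fGn stream; anti-persistence is
within-cell), and high-OCT4 differentiation routes. Passing tests
therefore demonstrate that the implementation reproduces the *model
family's* behaviour and its published anchors — not that the model family
is a validated description of any new experiment.

Problem sizes used by the test suite: feature checks (noise switch, mode
shift, differentiation collapse, fate separation) run colonies of 16
founding cells to 40 h (450 events) or 68 h (1900 events); generator and
estimator checks use series of 10^3–10^5 points with fixed seeds. The
acceptance script regenerates its quantities from scratch at the sizes
stated in its comments (100 × 1000-point Hurst ensemble, 10^5 cycle draws,
10^5-frame walk, 480-frame deterministic limit).

## Known limitations

* DFA on short series (51–120 frames, typical cell cycles) is noisy per
  cell (SD ≈ 0.1); only ensemble means are meaningful, and `hurst_ensemble`
  reports the SD alongside.
* The KS tests on binned colony data pool non-independent frames from the
  same cells, so their p-values are optimistic; they mirror the standard
  usage for this kind of data rather than a strict inference procedure.
* The additive-noise SLE at its published σ_A = 90 produces occasional
  deep excursions towards zero; in the O-space variant these absorb (as
  the equation dictates), in the combined variant they recover by
  regulation. Real cells presumably do neither; both behaviours are
  model artefacts at the distribution tail.
* `run_colony` keeps every cell record in memory; colonies beyond ~10^4
  division events should be truncated or chunked by the caller.
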