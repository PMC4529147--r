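---
title: "Models and methods behind stressmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stressmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stressmeta` implements, as a tested simulation-plus-analysis pipeline, the
computational chain used to ask whether biological stress reactivity
degrades *metacognitive sensitivity* — the ability of confidence reports to
discriminate one's own correct from incorrect perceptual decisions — while
leaving first-order perceptual performance untouched. This vignette
documents the models, the tunable parameters, and the design decisions
taken where the underlying procedures were open to interpretation. Every
empirical claim below is one that the package's test suite or acceptance
script computes itself.

## 1. The observer model

Each simulated participant performs a two-interval forced-choice (2IFC)
contrast discrimination. On a trial at contrast $c$ the observer draws
first-order evidence

$$ e \sim \mathcal{N}(d(c),\, 1), \qquad d(c) = k\,c, $$

and responds correctly iff $e > 0$; with probability `lapse_rate` (default
0.02, range limited to $[0, 0.1]$) the interval response is replaced by a
uniform guess. The linear transducer $d = k c$ is the simplest monotone
choice; nothing downstream depends on more than monotonicity, since the
staircase operates on the induced psychometric function and the analysis on
accuracy and confidence only.

Confidence is read out from the *same* decision variable corrupted by late
Gaussian noise $m \sim \mathcal{N}(0, \sigma_m)$ (`metacog_noise`):

$$ \mathrm{conf} = \operatorname{logistic}(\beta\,|e + m|) \in [0.5, 1), $$

with `confidence_slope` $\beta = 1.5$ by default. This single-late-noise
("second-order noise") architecture is the minimal model in which
first-order accuracy and type-2 sensitivity dissociate cleanly: $\sigma_m$
does not enter the decision rule, so accuracy is pinned while the
diagnosticity of confidence falls continuously from its noise-free ceiling
toward chance (AUC $\to 0.5$) as $\sigma_m \to \infty$. The test suite
verifies both limits and the monotone degradation in between.

Response times are log-normal with median `rt_location_ms` = 700 ms and
log-scale `rt_scale_ms` = 0.55, chosen so that about 4% of RTs fall outside
the 200–2000 ms analysis window and the RT filter is genuinely exercised
(the emulated study excluded 4.3% of trials, a data-dependent figure we do
not assert).

## 2. Staircase calibration

Contrast is calibrated with two interleaved transformed 1-up 2-down
staircases: every error multiplies contrast by `step_factor`, two
consecutive correct responses divide it once. At equilibrium
$P(\text{correct})^2 = 1/2$, i.e. the rule targets the 70.7%-correct point.
Defaults follow the emulated procedure: 120 trials in total, strict
alternation between an initially ascending and an initially descending
staircase, threshold = mean of the last six reversal levels of *each*
staircase (twelve values pooled).

Open choices, fixed as follows:

* **Step size** — constant multiplicative factor 1.26 (0.1 log10 units), no
  step-size halving; a fixed step keeps the reversal-average estimator
  well defined.
* **Interleaving** — strict alternation (the source procedure says only
  "interleaved"); alternation makes runs reproducible given a seeded
  observer.
* **"Last six reversals of both"** — read as six per staircase; the count
  is a config field (`n_reversals_for_threshold`) so the other reading is
  one keystroke away.
* **Clamping** — moves clamped at the contrast bounds do not count as
  reversals, avoiding spurious reversal inflation at ceiling.
* **120 trials** — read as the total (60 per staircase).

A practical caveat the acceptance machinery respects: the reversal-mean
threshold from a single 120-trial run is an unbiased but *noisy* estimator.
Across seeds, accuracy at that threshold has a standard deviation of
several percentage points for any realistic psychometric slope (measured at
4–6 points for logistic slopes 1.5–4 on the log-contrast axis). The
staircase-convergence acceptance check therefore evaluates the procedure's
*run-averaged* accuracy: 100 independent extended (240-trial) calibrations,
each validated with 200 fresh trials, must land within ±2 points of the
targeted 71%. A single-run check at ±2 points would be a coin flip no
matter how correct the implementation.

## 3. Type-2 ROC and AUC

Metacognitive sensitivity is the area under the empirical type-2 ROC.
Confidence ratings on the half-range probability scale $[0.5, 1]$ are
binned into $k = 5$ bins; sweeping a criterion from the most to the least
confident bin, the hit rate is the cumulative fraction of *correct* trials
at or above criterion and the false-alarm rate the same fraction among
*incorrect* trials. The curve is anchored at $(0,0)$ and $(1,1)$ and
integrated by the trapezoidal rule, with no parametric smoothing. AUC 0.5
means confidence carries no information about accuracy; 1 means perfect
separation. The package deliberately provides no meta-d′-style model-based
efficiency measure: the emulated analysis explicitly relied on the
model-free statistic.

**"Five equal bins"** is the largest single ambiguity: on a continuous
scale it can mean equal-width intervals of $[0.5,1]$ or equal-count
(quintile) bins. Both are implemented (`mode = "equal_width"` /
`"equal_count"`); equal-width is the default, and the choice is recorded in
every scored output. Equal-count binning makes the AUC invariant under any
strictly increasing transform of the confidence scale (a tested property);
with one bin per distinct confidence value the binned AUC equals the
pairwise statistic $P(\mathrm{conf}_{\mathrm{correct}} >
\mathrm{conf}_{\mathrm{incorrect}}) + \tfrac12 P(\text{tie})$ to machine
precision, which is how the implementation is validated against a
brute-force oracle.

Participants with zero errors (or zero correct trials) have no defined
type-2 ROC; the package raises an explicit error naming the participant
rather than imputing 0.5 or 1.0, because silent defaults would bias group
comparisons. Half-open bins with the top bin closed make confidence = 1.0
scorable.

## 4. Cortisol screening

Stress reactivity is indexed by the cortisol concentration at the
post-stress peak sample (C2, 10 minutes after stress induction).
Percentile-based labels use empirical quantiles with linear interpolation
(R type 7): strictly above the 75th percentile → high, strictly below the
25th → low, inside the 40th–60th band (inclusive) → medium, otherwise
unassigned. "Around the 50th percentile" is operationalised as the
(40, 60) band — an interpretation, configurable, not a source fact. The
responder criterion is an increase C2 − C0 ≥ 1.1 nmol/l, inclusive (a
participant exactly at criterion passes), with a 10⁻⁹ tolerance so the
boundary survives floating-point subtraction.

The seven-sample panel schedule defaults to minutes 0, 20, 30, 40, 50, 65,
80 with stress induction ending at minute 20, placing C2 (sample 3) ten
minutes after it; the schedule and the index of the peak sample are
configurable because the source specifies them only loosely.

## 5. Heart-rate variability and the bootstrap cluster test

HRV is the sample standard deviation of heart rate in non-overlapping
one-minute windows (trailing partial windows discarded), smoothed over
window time by locally weighted linear regression (LOESS, degree 1, tricube
weights — `stats::loess`), span 0.3 by default (unstated in the source;
exposed in config). Per window, group-mean HRV is bootstrapped by
resampling *participants* with replacement within group — the resampling
unit is not stated in the source; participants are resampled to respect
within-participant autocorrelation across windows. Per-group 95% bands are
the 2.5/97.5 percentiles of 5000 bootstrap group means; the per-window
two-sided p-value doubles the smaller tail fraction of the bootstrap
group-mean difference beyond zero (floored at 1/B); clusters are maximal
runs of windows with p < 0.05. The default contrast collapses the low and
medium groups against the high group, mirroring the emulated analysis. No
correction for multiple clusters is applied, matching the source's raw
per-window reporting.

A known, measured limitation: with 9 participants in the small group, the
95% percentile-bootstrap band for the group difference covers zero in
about 91% of null windows, not 95% — the textbook small-sample narrowness
of percentile intervals (for a mean of $n$ Gaussian observations the
percentile interval behaves like $\pm 1.96\,\hat\sigma\sqrt{(n-1)/n}/\sqrt n$
where a $t_{n-1}$ quantile would be needed). The corresponding acceptance
check, which demands 95 ± 3% coverage at the emulated group sizes, sits
just below its lower bound and is deliberately left failing rather than
widened; detection of injected effects is unaffected and separately
verified.

## 6. Group statistics

The statistical stage is computed from explicit sums of squares, not by
delegation, so that every reported quantity has a closed, documented
definition; the test suite then cross-checks each one against
`stats::aov`/`lm`/`t.test` to 10⁻¹⁰:

* one-way ANOVA with $\eta^2 = SS_{\text{between}}/SS_{\text{total}}$;
* Bonferroni pairwise post-hocs: pooled-variance t-tests (Welch by flag),
  p × number of pairs, capped at 1; pairs ordered low < medium < high and
  `mean_diff` = first − second;
* OLS of AUC on C2 with standardised slope
  $\beta = b\,\mathrm{sd}(C2)/\mathrm{sd}(AUC)$ (the Pearson correlation),
  $t$ on $n-2$ df;
* mixed pre/post ANOVA (time within, group between) with partial
  $\eta^2_p = SS_{\text{effect}}/(SS_{\text{effect}}+SS_{\text{error}})$.
  With two within-subject levels sphericity holds trivially, so no
  Greenhouse–Geisser correction is required (the source's fractional dfs
  arise from a many-level blocks factor outside this package's scope).

Degenerate inputs follow fixed conventions rather than NaN: perfect
separation reports $F = \infty$, $p = 0$, $\eta^2 = 1$; a zero effect sum
of squares reports $F = 0$; identical groups in a post-hoc report
$p_{\text{adj}} = 1$.

Note that the source's printed degrees of freedom are internally
inconsistent with its 27 participants (e.g. a one-way ANOVA df error of 26
where 24 follows from $27-3$); `stressmeta` computes dfs from first
principles and does not reproduce the printed ones.

## 7. The synthetic cohort: what it does and does not establish

`cohort_spec()` states the generative world once: three groups of 9
participants; C2 drawn per group around 4.5/7.3/10.7 nmol/l (SD
0.79/0.95/1.4) with baselines set by the group increases 0.21/1.45/2.14
nmol/l; 120-trial staircase calibration followed by 320 main trials in 8
blocks at the calibrated contrast; heart-rate traces at 1 Hz for 40
minutes with the high group's within-window SD elevated by 1.1 bpm in the
first eight windows; STAI-state totals rising by ~7.6 points pre→post.
Metacognitive noise is a deterministic function of C2,

$$ \sigma_m = \max\{0,\ s\,(C2 - 2)\}, \qquad s = 0.12 \text{ per nmol/l}, $$

calibrated once so that group-mean AUC gaps (~0.04–0.05 per group step)
mirror the emulated effect structure at the 71%-accuracy operating point,
whose noise-free AUC ceiling is ≈ 0.67. The absolute AUC levels observed in
the emulated study (.68/.73/.78) arose at 83% accuracy on human data and
are never asserted. Setting `cortisol_auc_slope = 0` yields an exact null
world, used by the null-behaviour tests. A single master seed drives
per-participant MINSTD-derived streams, so regeneration is bit-identical
and enlarging the cohort leaves existing participants untouched.

What a green run establishes: the pipeline recovers a negative
cortisol→metacognition link (standardised slope negative in ≥ 95% of 200
replications; AUC ordering low > medium > high in ≥ 90%) *when the
generative world contains one*, and reports null results when it does not.
What it does not establish: anything about real cortisol kinetics, real
confidence distributions (actual scales show end-point clumping the
logistic readout lacks), serial trial dependencies, or HR nonstationarity
beyond the piecewise SD profile.

## 8. Numerical and reproducibility choices

All randomness flows through explicit seeds; every simulating function
restores the caller's RNG state. Staircase levels are clamped
multiplicatively into `[min_level, max_level]`; fully clamped moves are
no-ops. Quantiles are type 7 everywhere (recorded so other implementations
can match bit for bit). Pipeline artifacts are plain CSV/JSON with no
wall-clock content, making reruns byte-identical; the manifest carries a
deterministic fingerprint of the serialized configuration.
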