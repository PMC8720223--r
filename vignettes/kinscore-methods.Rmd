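---
title: "Estimating clinical scores from rehabilitation-session kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating clinical scores from rehabilitation-session kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscore)
```

## The problem

After a stroke, upper-limb impairment and its recovery are tracked with
standardised clinical scales — the Fugl-Meyer upper-extremity assessment
(FM-UE, 0–66), the Chedoke Arm and Hand Activity Inventory (CAHAI,
13–91) and the Barthel Index (BI, 0–100). These assessments require a
trained rater and are administered sparsely. Patients training with
rehabilitation gaming systems, however, generate hand-trajectory logs at
every unsupervised session: timestamped planar hand positions at
~100 Hz, target-interception events, and an adaptive difficulty trace.
`kinscore` turns those logs into kinematic descriptors and estimates the
clinical scores from them, together with the clinimetric evidence
(reliability, sensitivity, validity) needed to judge whether such
estimates are usable as a digital biomarker of motor function.

## Timescale-resolved displacement: Smoothness and TGDM

The central descriptor is the RMS residual of Gaussian trajectory
smoothing. For a sampled hand position $f(t_i)$, the smoothed path at
timescale $\sigma$ is the normalized kernel average over *all* samples

$$f_\sigma(t_i) = \frac{\sum_j f(t_j)\,
  e^{-(t_i-t_j)^2/2\sigma^2}}{\sum_j e^{-(t_i-t_j)^2/2\sigma^2}},
\qquad
J(\sigma) = \sqrt{\tfrac{1}{T}\sum_i \left[f_\sigma(t_i) -
  f(t_i)\right]^2}.$$

$J(\sigma)$ isolates the movement components living at timescale
$\sigma$: as $\sigma \to 0$ it vanishes, as $\sigma \to \infty$ it
approaches the RMS deviation about the (kernel-weighted) mean. Swept
against clinical scores, its correlation curve shows two peaks:

* **Smoothness** — $J$ at a high-frequency timescale (default 0.01 s,
  the data resolution), reported in mm. It captures fast, jittery
  components and grows with impairment.
* **TGDM** (Total Goal-Directed Movement) — $J$ at a low-frequency
  timescale matched to the task's inter-target interval (defaults
  8.8 s for FM-UE, 5.9 s for CAHAI, 17 s for BI), in metres. It
  captures the displacement spent on goal-directed reaches and grows
  with function.

`sigma_sweep()` recomputes the correlation curve on any cohort; the
split between the two peak search ranges defaults to 0.5 s, roughly the
geometric middle between the data timescale (~0.01 s) and the task
timescale (~10 s). Both peak timescales are configurable everywhere.

Alongside these, `extract_session_features()` produces the classical
descriptors: convex-hull work area (gift wrapping), distance covered,
raw finite-difference maximum reaching speed (no pre-filtering — raw
logs contain single-sample glitches and we keep them, as the field's
printed ranges imply), target-interception performance, mean
difficulty, interlimb differences (`Diff.x`, non-paretic minus
paretic), log transforms (`Log.x`) and a chronicity category.

### Numerical evaluation of J

The kernel weight $e^{-(d/\sigma)^2/2}$ underflows to exactly zero in
double precision beyond $d = 39\sigma$, so a $39\sigma$ cutoff
reproduces the full pairwise sum to machine precision. On uniform
grids the two kernel sums are FFT convolutions (padded to 2-3-5-smooth
lengths); non-uniform grids fall back to a blocked dense evaluation
with the same cutoff. The suite checks both paths against a literal
$O(T^2)$ transcription of the definition (relative error ~1e-14,
asserted below 1e-10).

## The double-noise bounded score model

Clinical scales are bounded and noisy, and so are the covariates. The
estimation model is a saturating regression with two noise sources,

$$S = a \tanh(\boldsymbol\beta \cdot \mathbf{Z} + \beta_0 + \sigma_1 u)
  + b + \sigma_2 v, \qquad a = \tfrac{B-A}{2},\ b = \tfrac{B+A}{2},$$

with $u, v \sim \mathcal N(0,1)$: $\sigma_1$ is covariate noise inside
the link, $\sigma_2$ score noise outside it. The noise-averaged
prediction always lies in $[A, B]$; $B \ge A$ (i.e. $a \ge 0$) removes
the tanh sign ambiguity. The range offsets $A, B$ are *fitted*, not
pinned to the scale limits. Fitting is maximum a posteriori: the
regularised objective adds a ridge $\tfrac{d}{2}|\boldsymbol\beta|^2$
(default $d = 1$ on z-normalized covariates; the value is a package
default, recorded in every fit) and weights $e^{-q/\sigma}$ on each
noise strength ($q = 10^{-10}$), which bound the objective from below
as $\sigma \to 0$.

Three variants are provided:

* `double` — full model; the marginal likelihood integral is evaluated
  by Gauss–Hermite quadrature (32 nodes, doubled adaptively until the
  objective changes by < 1e-8 relative).
* `score` — $\sigma_1 = 0$ limit, closed form.
* `covariate` — $\sigma_2 = 0$ limit; finite only while
  $|S_i - b| < a$ for every sample (`+Inf` otherwise), which makes the
  half-range effectively constrained to $a > \max_i |S_i - b|$.

The optimizer works on an unconstrained reparameterization
($a = e^\alpha$, and for the covariate model
$a = \max_i|S_i - b| + e^\alpha$ so the domain constraint holds at
every iterate; noise strengths enter as $\log\sigma$), with 16 random
multi-starts by default ($\beta \sim \mathcal N(0, 0.25)$,
$b = \mathrm{median}(S)$, $\sigma \in \{0.1, 0.5, 1\}$ cycled) and is
deterministic under a seed. A barrier formulation would be an
alternative for the covariate model's constraint; the
reparameterization was chosen because it keeps the optimizer
unconstrained and needs no barrier weight. Parameter standard errors
come from the curvature of the objective at the optimum
(central-finite-difference Hessian, steps scaled to parameter
magnitude); a non-positive-definite Hessian marks the fit fragile
rather than failing. Prediction defaults to the noise-averaged mean
($\sigma_1$ integrated out by quadrature); plug-in prediction is an
option.

The linear baseline $S = \boldsymbol\beta \cdot \mathbf{Z} + \beta_0 +
\sigma u$ (same ridge) is deliberately not clamped: on bounded scores
it produces out-of-range estimates, which is the failure mode the
bounded model exists to fix. Its MAP solution is computed by
alternating the closed-form ridge update with $\sigma^2 =
\mathrm{SSE}/n$.

Greedy forward selection (`select_active_variables()`) grows an active
covariate set from a forced core, adding whichever candidate most
improves mean validation accuracy under repeated 50/50
cross-validation, stopping below a 0.002 gain; ties break toward the
smaller set, then lexicographically. Rehabilitation-history covariates
(time since stroke, sessions completed, and functions of them) are
excluded from score-estimation sets so that the estimate reflects the
current clinical state only.

## Clinimetric conventions

* **Accuracy** is the median-split classification rate: the fraction of
  samples estimated on the correct side of the training-set median.
  Values exactly at the median count as "not above" on both sides; the
  tie rule only matters for discrete scores.
* **Cross-validation**: repeated random 50/50 splits (default 50
  repeats; the repeat count is a package default) and LOOCV.
  Normalization constants and the split median always come from the
  training half only.
* **Reliability**: ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — computed from the two-way mean
  squares; ICC(3,1) is available as a config option. Zero
  between-subject variance is an explicit error, not a silent NaN.
* **Retest error and MDC**: retest error is the RMS difference of
  paired estimates; with SEM $= \mathrm{RMS}/\sqrt2$, MDC95 $= 1.96
  \sqrt2\,$SEM $= 1.96 \times \mathrm{RMS}$ — the unique convention
  that maps a retest error of 5.9 points to an MDC of 11.6.
* **Recovery sensitivity**: of the pairs whose true score change
  reaches the clinical MDC (default 4 points), the fraction whose
  predicted change also reaches it. The threshold is configurable —
  the same function answers "detected above the model's own MDC".
* **RMSE** is $\sqrt{\mathrm{SSE}/n}$ throughout, and $R^2 = 1 -
  \mathrm{MSE}/\mathrm{Var}(S)$ with the population variance, so
  predicting the mean gives exactly 0 and bad models go negative.
* **Rescaling benchmarks**: estimating FM-UE as $66/91 \times$ CAHAI
  or $66/100 \times$ BI brackets the accuracy a kinematic estimator
  should beat or approach.
* The permutation threshold for variable-score correlations reports
  both a quantile of the pooled null $|r|$ distribution and the null
  SD of $r$ (≈ $1/\sqrt{n-1}$); the choice of statistic is exposed
  rather than hard-coded because published thresholds of this kind are
  rarely pinned to a stated quantile.

## The session simulator

No public dataset of rehabilitation-gaming logs exists, so the
simulator is a first-class module: every other module is exercised
against cohorts whose ground truth is known.

Each latent patient has a function level in $[0,1]$ (1 = least
impaired); the non-paretic limb's level is always at least the paretic
one. A session emulates target-interception gameplay: targets every
~10 s (±20%), minimum-jerk reaches toward lateral target offsets with
amplitude scaled by function level (plus a smaller frontal component),
band-limited Gaussian jitter (2–8 Hz) with amplitude scaled by
impairment, and sub-millimetre sensor noise. The minimum-jerk profile
is a realism choice; any smooth reach profile with the same
amplitude/jitter contracts would serve. Per-target success is
Bernoulli with probability $\mathrm{logit}^{-1}((\mathrm{ability} -
\mathrm{difficulty})/0.15)$, and the controller nudges difficulty
after each target whenever the trailing 10-target success rate leaves
the 70–80% band, holding long-run success inside it across ability
levels.

Scores are generated from the package's own bounded tanh model applied
to cohort-normalized extracted covariates (defaults: TGDM, Smoothness,
difficulty with $\beta = (0.9, -0.25, 0.3)$, $a = 31$, $b = 35$,
$\sigma_1 = 0.5$, $\sigma_2 = 0$, an FM-UE-like range), so parameter
recovery can be tested end to end. Retest pairs reuse the latent state
with fresh noise draws less than 48 h apart; recovery pairs advance
the function level by a truncated-normal improvement (default mean
0.1) with gaps beyond 16 days.

What the simulator does *not* emulate: trunk compensation, joint-angle
biomechanics, fatigue within a session, learning across sessions,
missing or corrupted log segments, and the idiosyncratic error
structure of camera-based tracking. Passing tests therefore show that
the pipeline recovers what it plants under its own noise model — not
that the same accuracy holds on clinical data.

## Problem sizes and defaults used by the tests

The generator's defaults are the study conditions (1800-s sessions at
100 Hz, targets every ~10 s). The test suite and the acceptance script
run the same code on reduced sizes chosen to keep the whole suite
around a minute: sessions of 300–420 s (still 10–20 targets after the
two-minute trims used at full length are shortened accordingly),
cohorts of 10–40 patients, 20 cross-validation repeats, and parameter
recovery at $n = 400$, $p = 3$ over 20 replicates. The acceptance
script (`scripts/acceptance.R`) states each quantity's problem size in
its output.

## Degenerate inputs and tie-breaks

* Hull of fewer than three distinct or collinear points: area 0; a
  missing frontal axis is an error, not a silent 1-D hull.
* Repeated timestamps make finite-difference speeds undefined: error.
* Sessions shorter than a comparison window fall back to one
  whole-session window with a warning.
* Log transforms of columns containing non-positive values (difficulty
  can be negative) use $\log(x - \min_{\mathrm{train}} + 10^{-6})$,
  with the shift stored in the feature matrix and reused for held-out
  data.
* Chronicity cut-offs (never standardised in the field): < 30 days
  acute, 30–180 subacute, > 180 chronic; configurable.
* Score-session coupling takes the nearest session within 4 days
  (inclusive); ties go to the earlier session; each score couples to
  one session.
* In a sigma sweep with a degenerate grid, both peaks are the argmax
  over the whole grid.

## Known limitations

* The covariate-noise model's likelihood is exact only at
  $\sigma_2 = 0$; on data with substantial score noise its error bars
  are optimistic. The double model handles both noises at the cost of
  a quadrature per evaluation.
* Curvature standard errors are asymptotic; the suite checks them
  against a bootstrap within a factor of 1.5 at $n = 400$, but they
  should not be trusted for very small cohorts.
* The simulator's score model and the estimator share the same
  functional form, which makes recovery tests well-posed but cannot
  reveal misspecification bias.
* Feature extraction assumes a planar, session-local coordinate frame
  in metres; no 3-D kinematics or joint angles.
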