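---
title: "Methods: convex log-linear EMG-force estimation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convex log-linear EMG-force estimation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgforce)
```

## The model and its assumptions

`emgforce` estimates a scalar force (or force-like target such as a
center-of-pressure coordinate) from the envelopes of multi-channel surface
EMG. The model is

$$ f(t) = w_0 + \sum_{i=1}^{M} w_i \,\ln \mathrm{sEMG}_i(t), $$

where $\mathrm{sEMG}_i(t)$ is the representative envelope of muscle $i$.
The logarithm linearises the saturating EMG-force relationship while
keeping the problem *linear in the parameters*: stacking samples gives
$A w = b$ with $A$ an $N \times (M+1)$ design (ones column, then
log-envelopes), and the least-squares objective is convex, so the solution
is a global minimum and is reproducible — no initialisation, no restarts.
The assumptions worth stating explicitly:

* the force is quasi-static relative to the envelope bandwidth (isometric
  ramps, postural sway); no electromechanical delay is modelled;
* envelopes are strictly positive where the muscle is active — silent
  samples are floored (below) before the log;
* antagonist action is representable by negative weights on a nonnegative
  envelope; the envelope itself is never signed.

## Envelope extraction

Per channel: full-wave rectification, then a second-order zero-lag
Butterworth low-pass at 2 Hz (suitable for slow contractions; the cutoff is
a parameter). Per muscle: the per-sample median across channels, or a
user-selected representative channel. Conditioning band-passes for the two
montages ship as presets (fourth-order 15–350 Hz and 20–450 Hz); the force
channel is smoothed with a fourth-order zero-lag low-pass at 1 Hz.

"Zero-lag" is implemented as forward-backward application of the
stated-order design: the net phase is zero and the magnitude response of
the stated order is squared. Three numerical choices matter here:

* **Edge handling.** Both passes use odd-reflection padding of
  $3(\text{order}+1)$ samples *and* steady-state initial conditions. The
  initial level is taken from a local linear fit over the filter's memory
  (the span over which the slowest pole decays to 1 %), extrapolated to the
  record edge. For smooth inputs this reduces to the first sample; for
  rectified noise it is the local mean. The second part is essential: a
  2 Hz smoother at 2048 Hz has a memory of roughly half a second, and
  padding alone leaves a startup transient that drives the envelope toward
  zero at the record edges — harmless in linear space, catastrophic after
  the log transform.
* **Clipping.** The low-pass can undershoot below zero after sharp
  activity drops; the envelope is clipped at zero to stay a valid
  amplitude.
* **Log floor.** Before the log, envelopes are floored at
  $\varepsilon = 10^{-8} \times$ (global envelope maximum). The relative
  form keeps the fix invariant to units; any positive rescaling of an
  envelope provably moves only the intercept.

## Solvers and diagnostics

Full-column-rank systems are solved via QR; the normal-equation inverse is
never formed, because $\mathrm{cond}(A) = \sqrt{\mathrm{cond}(A^\top A)}$ —
squaring the condition number is exactly what an explicit
$(A^\top A)^{-1}$ does. Rank-deficient systems (they arise by construction
in some comparison families) return the minimum-norm solution through the
SVD pseudo-inverse, zeroing singular values below
$\max(N,m)\,\sigma_{\max}\,\epsilon_{\text{mach}}$. Every fit records its
solver path and the condition number of its design.

## The comparison roster

Nine classical per-muscle model structures are implemented exactly as
printed in the EMG-force literature, summed over muscles (parameters
$a_i..e_i$): linear ($a e + b e$), power law ($a e^b$), exponential
($a e^{b e}$), double power law, quartic polynomial, affine, the
three-parameter $e^{a} + \exp(b - c e)$ structure, and the
cosine/sine expansions. Structures 1, 5, 6, 8, 9 plus OLS are linear in the
parameters and solved by least squares — structure 1 is rank-deficient *by
construction* (its two terms are the same regressor) and is deliberately
left as printed, with the pseudo-inverse absorbing the degeneracy.
Structures 2, 3, 4, 7 are non-convex and fitted by particle swarm
optimisation. Power terms floor the envelope at $\varepsilon$ so that
$0^{\text{negative}}$ cannot occur, and exponentials are clipped at
$10^{12}$ (the exponential structure is known to blow up on out-of-range
inputs; the clip turns that into a warning instead of an overflow).

**PSO configuration.** Global-best PSO with adaptive random neighbourhood:
$200 \times n_\text{weights}$ iterations, swarm
$\min(100, 10\,n_\text{weights})$, minimum neighbourhood fraction 0.25,
self- and social-acceleration 1.49, inertia adapted in $[0.1, 1.1]$. The
optimiser is restarted ten times (configurable) on the estimation-set SSE,
and the restart with the lowest *validation*-set RMSE wins — a stochastic
optimiser must not be selected on its own training objective. Bounds
default to $[-10, 10]$ for multiplicative/additive coefficients and
$[-5, 5]$ for exponents; no bound set is canonical in this literature, so
they are configurable. Everything is deterministic given the seed.

**Ridge (RLS).** The penalised objective has a closed form, so it is solved
in closed form; $\lambda = 0.01$ by default, and the intercept is not
penalised (penalising it would break mean recovery in the large-$\lambda$
limit). **SVR**: linear $\varepsilon$-insensitive regression with the cost
chosen by deterministic 5-fold CV over $10^{-3..3}$ on the estimation set.
The tube width defaults to 0.01 on the standardized target: the force
target is low-noise after conditioning, and the conventional 0.1 tube
demonstrably caps accuracy on noise-free realizable data. **ANN**: one
hidden layer of 10 tanh units ("ten hidden layers" in parts of this
literature is read as ten hidden *units* — a ten-layer perceptron is not
trainable by damped Gauss-Newton at this scale; the width is configurable),
trained by Levenberg-Marquardt with an analytic Jacobian, damping started
at 0.001 and adapted multiplicatively, early stopping on the validation
split, and up to three re-initialisations on divergence.

All baselines operate on the *raw* envelopes (the model structures are
printed with untransformed inputs); only the proposed model takes logs.

## Data allocation and evaluation

Samples are allocated to estimation/validation/test as contiguous time
blocks by default — sEMG envelopes are strongly autocorrelated, and
interleaving would leak information across sets; an interleaved scheme is
available where distribution-matched sets are wanted. Families needing
validation (PSO structures, RLS, SVR, ANN) use 30/20/50; single-solve
families use 50/50 estimation/test.

Goodness of fit: Pearson $r$, $R^2 = 1 - SSE/SST$ with the squared total
sum of squares, adjusted $R^2$ penalised by the parameter count, RMSE, MAE.
Negative $R^2$ is reported, not clipped. Residual diagnostics follow the
Bland-Altman construction (residual vs measured, bias $\pm$ 1 SD limits by
default — the regression-residual convention; a multiplier argument
restores the classical 1.96 — plus the residual-on-measured trend line).
The statistical battery: paired t-test for bias, one-way within-subject
(repeated-measures) ANOVA with Bonferroni-adjusted pairwise contrasts
against a reference model (the repeated unit is whatever the score rows
are — subjects or recording epochs; no sphericity correction is applied),
Mann-Whitney U with an exact tie-aware permutation p-value for
$n_a n_b \le 400$ (shift-algorithm dynamic program over midranks) and the
tie-corrected normal approximation otherwise, ROC with the Youden-optimal
cutoff (AUC through the rank identity; cutoff ties broken toward higher
specificity), and a paired DeLong test for AUC differences built on
placement covariances.

The minimum-sample-size computation inverts the noncentral-F power of the
overall regression test with effect size $f^2 = R^2/(1-R^2)$ and the
$\lambda = f^2 N$ noncentrality convention; conventions differ across
software by $\pm 1$ in $N$, which is why the choice is documented here.
Under this convention the two planning scenarios built into the tests
($R^2 = 0.964$ with 5 predictors; $R^2 = 0.960$ with 11) give $N = 8$ and
$N = 14$.

## The synthetic-data generator

The simulator emulates slow isometric protocols: per muscle, a nonnegative
activation profile — by default a 25 s series of triangular up-down ramps
through 30/50/70 % MVC above a 5 % baseline, phase-shifted per muscle so
the regressors are not collinear; alternatively a sway-like random-phase
multisine below 0.5 Hz, or a constant hold. Each channel is the profile
amplitude-modulating an independent unit-RMS carrier: white noise
(Laplacian by default, matching the heavy-tailed amplitude statistics of
voluntary sEMG; Gaussian optionally) band-pass filtered to 15–450 Hz at
2048 Hz. The force target is the log-linear model of the *true profiles*
(default weights $1, 2.5, 2.0, 1.5, 1.0$, with the same $\varepsilon$
convention as the fitter, so the generative and fitted model classes
coincide) plus white Gaussian noise with SD equal to 5 % of the noise-free
force range. All three stages are bit-reproducible given the root seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real recordings: motor-unit structure (no MUAP shapes,
recruitment or firing statistics), electrode geometry and crosstalk,
innervation-zone effects, nonstationary noise, movement artefacts, or
electromechanical delay. Two consequences are worth knowing. First,
envelope extraction is biased ($E|X| <$ RMS for any zero-mean carrier), so
full-pipeline weight recovery is approximate — the scale bias moves the
intercept exactly and the fluctuation bias slightly attenuates slopes —
which is why exact recovery is asserted only on true envelopes and the
full pipeline is held to held-out $R^2$ instead. Second, the distribution
switch (Laplacian vs Gaussian) is observable on the white innovations, not
on the band-passed carrier: filtering mixes samples and pulls kurtosis
back toward Gaussian.

## Problem sizes used by the test and acceptance suites

Pipeline-level checks run at the full default study conditions (4 muscles
× 3 channels, 25 s at 2048 Hz; 20 seeds for the noise-free held-out-$R^2$
check). Optimiser-level checks run on $N = 300$, $M = 2$ envelope fixtures:
the convexity-dominance check gives PSO its full iteration/swarm budget per
family, and the non-convex recovery checks use three restarts. Unit tests
use shorter records at reduced sampling rates with the carrier band scaled
into Nyquist. These sizes are the package's own choices for a reproducible
suite; nothing in the methods depends on them.

## Known limitations and open choices

* The held-out bias t-test is anticonservative by construction: the mean of
  test-set residuals of a model fit on a disjoint estimation set has
  variance $\sigma^2(1/N_t + c/N_e)$, not $\sigma^2/N_t$ (the second term
  propagates estimation error; $c \ge 1$, with equality when the two sets
  share the regressor distribution). At a 50/50 split the test statistic is
  inflated by at least $\sqrt 2$, so nominal $\alpha = 0.05$ rejects in
  ~16 % of well-specified replicates under matched splits, and more under
  contiguous splits whose halves differ in regressor mean. A single
  recording can still easily show a large bias p-value; a *calibrated*
  held-out bias test would need to widen the standard error by this factor,
  which the package deliberately does not do silently.
* Whether the representative envelope should be the median across channels
  or one selected channel is protocol-dependent; both are exposed.
* The detrending of the force target before fitting is available as an
  option but off by default (the intercept is part of the model).
* No online/recursive updating: each epoch is fit from scratch — the
  per-epoch timing harness shows this is well inside real-time budgets
  (sub-millisecond for 250 ms epochs on one CPU), which is the practical
  argument for the convex model.
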