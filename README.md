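# emgforce

Estimating muscle force from surface electromyography (sEMG) is a core
problem in neuromuscular biomechanics, rehabilitation and prosthesis
control. Most accurate estimators in the literature are either non-convex
(so their fits depend on the optimizer's luck) or black boxes (so clinicians
cannot read muscle contributions off the fitted model). `emgforce`
implements a convex, interpretable alternative — a log-linear model solved
exactly by least squares — together with the thirteen comparison estimators
commonly used in this literature, the full envelope-extraction pipeline, a
statistical evaluation battery, and a seeded synthetic sEMG/force simulator
so that every stage can be exercised and tested without recorded data.

## The model

The representative envelope of each muscle's sEMG is the low-pass-filtered
(2 Hz, second-order zero-lag Butterworth) full-wave-rectified signal, with
the per-sample median across the muscle's channels taken as representative.
Force is modelled as

```
f(t) = w0 + Σ_{i=1}^{M} w_i · ln( sEMG_i(t) )
```

which is linear in the parameters `(w0, w1, …, wM)`: stacking the samples
gives an `N × (M+1)` design matrix `A` (a column of ones, then the
log-envelopes) and the convex least-squares problem `min ‖Aw − b‖²`. Full
column rank systems are solved by a QR/triangular solve — the normal
equation inverse `(AᵀA)⁻¹` is never formed, since `cond(A) = √cond(AᵀA)` —
and rank-deficient systems fall back to the minimum-norm solution through
the SVD pseudo-inverse. The weights `w_i` are directly interpretable as the
log-sensitivity of force to each muscle's activity (load sharing), and the
weighted activities `w_i · ln sEMG_i(t)` decompose the estimated force into
per-muscle contributions.

The comparison roster covers nine classical EMG–force model structures
(power laws, exponentials, polynomials, trigonometric expansions — the
convex ones solved by least squares, the non-convex ones by multi-start
particle swarm optimization selected on validation RMSE), ordinary least
squares, ridge regression (λ = 0.01), linear support-vector regression with
cross-validated cost, and a Levenberg–Marquardt-trained feed-forward
network with early stopping.

## Worked example

```r
library(emgforce)

cfg  <- syntheticConfig(n_muscles = 4, duration_s = 25, noise_sd = 0.05, seed = 42)
ds   <- makeDataset(cfg)                 # EMG channels, true envelopes, force
envs <- extractEnvelopes(ds$emg)         # rectify -> 2 Hz zero-lag LP -> median
split <- defaultSplit("proposed", nSamples(ds$force))   # 50/50 contiguous
fit  <- fitModel("proposed", envs, ds$force, split)
fit
#> Log-linear sEMG-force model
#>   w0 = 2.91484
#>   w[m1] = 2.48046
#>   w[m2] = 2.00454
#>   w[m3] = 1.5276
#>   w[m4] = 1.0361
#>   condition number 50.99 (normal-solve)

ev <- evaluateOnSplit(fit, envs, ds$force, split$test_idx)
ev$metrics
#> Metrics (N = 25600, k = 5): r = 0.9657, R2 = 0.9319, adj.R2 = 0.9319, RMSE = 0.414, MAE = 0.3299
ev$bland_altman
#> Bland-Altman: bias = -0.03949, SD = 0.4121, limits [-0.4516, 0.3726] (+/- 1 SD)
```

The generator drew this recording from true weights `(1, 2.5, 2.0, 1.5,
1.0)` at 5 % force noise. The fitted slopes (2.48, 2.00, 1.53, 1.04) recover
the per-muscle weights; the intercept differs from the generative one
because envelope extraction rescales each regressor by the mean rectified
carrier amplitude, and any positive rescaling of an envelope moves only the
intercept (`w0 → w0 − w_i ln c`), never the predictions. Held-out R² of
0.93 at 5 % noise, with the residual bias two orders of magnitude below
the force range, is the expected behaviour for a well-specified convex fit.

The power analysis for planning a study with this model is one call:

```r
regressionSampleSize(0.964, 5)    # 8  subjects (5-predictor model)
regressionSampleSize(0.960, 11)   # 14 subjects (11-predictor model)
```

A thin command-line interface (`inst/scripts/emgforce`, or
`runCli()` programmatically) exposes `simulate`, `fit`, `evaluate`,
`compare` and `report` subcommands over the same functions.

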