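# iortc — dense-sampling analysis of inhibition-of-return time courses

`iortc` is an R package for researchers studying exogenous spatial attention
with Posner-style cueing tasks. A brief peripheral cue first speeds detection
of targets at the cued location and then — beyond roughly 225 ms — slows it
(inhibition of return, IOR). Whether that late slowing reflects a *sustained*
inhibitory tag against the cued location or a *theta-rhythmic* attentional
spotlight that keeps revisiting it can only be decided with densely sampled
cue–target onset asynchronies (CTOAs) and explicit model comparison. This
package implements that entire workflow, end to end, together with a seeded
trial-level simulator so everything is testable without an empirical dataset.

## The models at its core

The normalized difference time course d(t) = RT(invalid) − RT(valid) in
z-units, over CTOA t in seconds, is contrasted across five nested candidates:

| model        | d(t) =                                      |
|--------------|---------------------------------------------|
| intercept    | b₀                                          |
| linear       | b₀ + b₁·t                                   |
| exponential  | b₀ + N₀·e^(−t/τ)                            |
| rhythmic     | b₀ + a·sin(2πft + φ)                        |
| hybrid       | b₀ + N₀·e^(−t/τ) + a·sin(2πft + φ)          |

with a ≥ 0, φ ∈ [0, 2π), and f confined to 1–11 Hz (or a 3–8 Hz theta
preset). Fits are deterministic profiled least squares (exact linear solve
over a fixed f × τ grid, bounded polish); models are adjudicated by AICc and
BIC (k = parameters + 1), Akaike weights, BIC-approximate Bayes factors
exp(ΔBIC/2), and per-participant winner tallies. Rhythmicity is additionally
tested directly: second-order detrending, FFT amplitude spectra (2/N
normalization), and a max-statistic permutation test that shuffles CTOA
labels within participants to control the familywise error across frequency
bins. A 2 (validity) × 5 (CTOA) repeated-measures ANOVA with
Greenhouse–Geisser correction, generalized eta squared, and Bonferroni
post-hocs replicates the classic two-stage IOR check on the grid values
nearest 50, 100, 200, 300, 500 ms.

## Worked example

Simulate a 39-participant cohort (660 trials each: 25 CTOAs × 2 validities
× 12 trials + 60 catch), preprocess it, and compare the five models:

```r
library(iortc)
trials <- simulate_cohort(design_config(), effect_params(), noise_params(),
                          master_seed = 11)
prep <- preprocess(trials)     # screening, filtering, z-scaling, cell means
fits <- ior_fit_models(prep$diff_course)
fits
#> Candidate-model comparison (5 models)
#>        model k    rss    aicc     bic delta_aicc akaike_weight bf_best_vs_model
#>    intercept 2 1.5000  -65.71  -63.82      63.16      1.93e-14         5.05e+13
#>       linear 3 0.8860  -76.37  -73.85      52.50      3.98e-12         3.34e+11
#>  exponential 4 0.2300 -107.24 -104.37      21.62      2.02e-05         7.90e+04
#>     rhythmic 5 0.4920  -85.04  -82.11      43.82      3.05e-10         5.39e+09
#>       hybrid 7 0.0633 -128.87 -126.92       0.00      1.00e+00         1.00e+00
```

The hybrid (decay + slow sinusoid) wins decisively on this hybrid-generated
cohort: its Akaike weight is ~1, and the exponential trails by ΔAICc = 21.6
(Bayes factor ≈ 8·10⁴). The recovered parameters sit close to the generative
ones (the frequency lands on the 1 Hz band edge, flagged by `f_at_bound`):

```r
round(coef(fits$fits$hybrid), 3)
#>     b0     N0    tau      a      f    phi
#> -0.475  0.803  0.188  0.138  1.000  1.071
```

The replication ANOVA shows the expected validity × CTOA interaction
(facilitation at 42 ms turning into inhibition by ~300 ms):

```r
rm_anova_validity_ctoa(prep$cell_means)[, c("effect","F","df1_gg","df2_gg","p_gg","ges")]
#>          effect     F df1_gg df2_gg     p_gg    ges
#>        validity 10.20   1.00     38 2.82e-03 0.0282
#>            ctoa  1.75   3.68    140 1.47e-01 0.0169
#>   validity:ctoa 26.77   3.57    136 2.88e-15 0.2392
```

And the direct spectral test finds no significant bin in the difference
course — the slow component is absorbed by the quadratic detrend, as it
should be for a non-rhythmic trend:

```r
run_spectral_battery(prep$cell_means, n_perm = 2000, seed = 12)$difference
#> Max-amplitude permutation test: difference (invalid - valid)
#> n_perm = 2000, threshold(95%) = 0.0698
#>  freq_hz amplitude      p sig
#>    0.952    0.0187 1.0000
#>    1.905    0.0307 0.9915
#>    ...
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages and
writes every artifact (trial CSV, screening, time courses, ANOVA, fits under
both frequency presets, winner tallies, spectra) plus a JSON report; a thin
command-line wrapper with per-stage subcommands lives at
`inst/cli/iortc.R`. See the vignette in `vignettes/` for the modelling
conventions and their rationale.

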