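# sdsa — synthetic digital subtraction angiography by gamma-variate frame interpolation

Digital subtraction angiography (DSA) delivers some of the highest radiation
doses in diagnostic imaging, and dose is directly proportional to the
acquisition frame rate. `sdsa` implements a post-processing route to dose
reduction: deliberately drop frames from a DSA run (50%, 66% or 75% frame-rate
reduction), fit a first-pass contrast-transit model to every voxel's
time–intensity curve on the *reduced* data, and resample the fitted curves on
the original frame grid to regenerate the dropped frames — a *synthetic DSA*
(sDSA). The package is aimed at researchers in neuro-interventional and
perfusion imaging who want to study how far DSA frame rates can be lowered
before diagnostic content degrades.

## The model

Each voxel's time–intensity curve is modeled as a gamma-variate bolus curve,
the standard first-pass transit model in CT/MR/DSA perfusion:

```
v(t) = 0                                          t ≤ AT
v(t) = A · (t − AT)^α · exp(−(t − AT)/β)          t > AT
```

with amplitude `A ≥ 0`, shape `α > 0`, timescale `β > 0` (seconds) and
contrast arrival time `AT ≥ 0`. The curve is unimodal with its peak at
`Tmax = AT + α·β`; the *leave time* (washout) is the post-peak time where the
curve falls to 5% of peak. Fitting is bounded Levenberg–Marquardt least
squares seeded by a log-domain linearization (for fixed `AT` the model is
linear in `log A`, `α`, `1/β` on the log scale) plus a deterministic
multi-start. Voxels below the noise floor are classified background; voxels
with too few samples fall back to piecewise-linear interpolation.

Reconstruction fidelity is quantified by the relative signal-intensity error

```
R_SI(t) = |SI_o(t) − SI_s(t)| / SI_o(t)
```

time-averaged per voxel (masked where the original intensity is at
background level), summarized as mean ± SD over valid voxels, and rendered
as green-to-red heatmaps (green ≤ 3% error, red ≥ 15%).

The package also implements the statistics used to grade sDSA quality in a
reader study: the 4–20 composite rubric score (four 1–5 items: arterial,
capillary, venous phase, overall quality), Kendall's coefficient of
concordance W with mid-rank tie correction, the coefficient of variation,
and the noncentral-t sample-size calculation for comparing two group means.

Because no public DSA data accompany the method, a phantom module generates
synthetic angiographic stacks with a procedural vessel tree whose voxels
follow compartment-specific kinetics (arterial, capillary, venous arrival
windows) with known ground-truth parameters — the test bed for everything
above.

## Worked example

```r
library(sdsa)

# a 64x64, 16-frame, 2 fps phantom with known gamma-variate ground truth
ph <- generate_phantom(phantom_spec(seed = 1, noise_sigma = 0))
ph$stack
#> frame_stack: 16 frames of 64x64 voxels @ 2 fps (contrast_bright) [phantom(seed=1)]

# drop 3 of every 4 frames, fit every voxel, resample at the original rate
res <- synthesize_study(ph$stack, frr_scheme(75))
fit_census(res$fit_map)
#>          fitted      background fallback_interp          failed
#>             698            3398               0               0

error_map(ph$stack, res$sdsa)
#> error_map: 698 valid voxels, mean error 47.404% (sd 75.923%), epsilon 0.9981

res50 <- synthesize_study(ph$stack, frr_scheme(50))
error_map(ph$stack, res50$sdsa)
#> error_map: 698 valid voxels, mean error 1.762% (sd 5.408%), epsilon 0.9981
```

At 50% reduction the mean voxel error is 1.8% — the same regime as the
2 ± 2.5% reported for clinical anteroposterior runs — while this 7.5-s,
16-frame phantom is too short for 75% reduction (4 retained samples) to
constrain late venous curves, so its mean error is large. Parameter recovery
for the 50% fit is exact to numerical precision (median relative errors per
compartment):

```r
print(truth_error(res50$fit_map, ph$truth), digits = 3)
#>       class   n amplitude    alpha     beta       at     tmax
#> 1  arterial 333  8.59e-16 1.17e-15 6.04e-16 9.28e-16 1.40e-16
#> 2 capillary 119  7.99e-16 1.04e-15 7.55e-16 3.37e-16 0.00e+00
#> 3    venous 246  1.24e-14 1.38e-14 7.74e-15 4.20e-15 8.40e-16
#> 4       all 698  1.24e-15 1.81e-15 9.92e-16 9.11e-16 1.62e-16
```

Reader-study statistics:

```r
# per-group n to detect composite scores of 16±2 vs 13±3 (alpha .05, power .75)
sample_size_two_means(16, 2, 13, 3, alpha = 0.05, power = 0.75)
#> [1] 12

ratings <- rbind(r1 = c(12, 15, 9, 18, 11),   # 3 raters x 5 studies
                 r2 = c(13, 14, 10, 17, 12),
                 r3 = c(11, 16, 9, 19, 10))
unlist(kendalls_w(ratings)[c("W", "p")])
#>          W          p
#> 1.00000000 0.01735127
```

A small synthetic score table ships in
`inst/extdata/reader_scores_synthetic.csv` for experimenting with
`read_reader_scores()` and `score_table_summary()`.

## Command line

`inst/cli/sdsa_cli.R` exposes the pipeline as subcommands:

```sh
Rscript inst/cli/sdsa_cli.R full --seed 1 --out runs/demo          # end to end
Rscript inst/cli/sdsa_cli.R phantom --rows 64 --cols 64 --out ph.raw
Rscript inst/cli/sdsa_cli.R synthesize --in ph.raw --frr 75 --out sdsa.raw
Rscript inst/cli/sdsa_cli.R evaluate --truth ph.raw --synthetic sdsa.raw --out-prefix ev
Rscript inst/cli/sdsa_cli.R readerstats --scores scores.csv --out summary.csv
```

`full` writes the phantom, three sDSA stacks, error heatmaps, a CSV report
and a JSON manifest (seed, configuration, versions) that reproduces the run
bit for bit.

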