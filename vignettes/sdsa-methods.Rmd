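---
title: "Synthetic DSA: model, fitting strategy, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic DSA: model, fitting strategy, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the
contrast-transit model and its assumptions, the numerical choices inside the
voxelwise fitting, what the synthetic phantom does and does not emulate, and
the design decisions taken where more than one convention was defensible.

## The contrast-transit model

A digital subtraction angiogram is a time series of 2-D frames in which only
contrast-filled vessels appear. During a first pass, the time–intensity
curve (TIC) of a voxel is well described by the gamma-variate function

$$ v(t) = A\,(t - AT)^{\alpha}\, e^{-(t-AT)/\beta}, \qquad t > AT, $$

and $v(t) = 0$ for $t \le AT$, with four parameters:

| parameter | meaning | units | bounds (defaults) |
|---|---|---|---|
| $A$ | intensity scale | intensity / s$^\alpha$ | $[0, \infty)$ |
| $\alpha$ | bolus shape (skewness of the wash-in/wash-out) | – | $[0.1, 25]$ |
| $\beta$ | transit timescale | s | $[0.01, 50]$ |
| $AT$ | contrast arrival time | s | $[0,$ last sample$]$ |

Derived quantities: the peak time $T_{max} = AT + \alpha\beta$, the peak
value $A(\alpha\beta)^\alpha e^{-\alpha}$, and the *leave time* — the
post-peak time where the curve decays to a fraction of peak. The washout
fraction is configurable and defaults to 5%: the literature names the leave
time but does not pin a threshold, so a concrete, testable convention was
required; 5% of peak is where residual enhancement is visually
indistinguishable from background in 8–12-bit angiographic data.

The model deliberately covers the first pass only. Recirculation,
extravascular leakage through a disrupted blood–brain barrier, and the
projection overlap of vessels are all outside its scope, mirroring the scope
of the synthetic-DSA approach itself.

All times are seconds internally; frame indices are 0-based, and conversion
between frames and seconds happens only in the `time_grid` container
(frame $k$ is acquired at $\mathrm{origin} + k/\mathrm{rate}$).

## Frame-rate reduction

The three reduction schemes keep every 2nd, 3rd or 4th frame (nominal 50%,
66%, 75% reduction), always starting at frame 0. Keeping the first frame
guarantees the pre-arrival baseline is sampled, which anchors the arrival
time; the figure-level convention in the source method retains the first
sample as well. "66%" is implemented as an exact stride of 3 — the label is
rounded, the drop rule is exact.

## Voxelwise fitting

`fit_voxel` classifies before it fits:

1. **Background.** A voxel whose peak intensity is below
   `noise_floor_k * sigma` (default $3\sigma$) never enhances; it is
   reconstructed as constant zero baseline and excluded from error
   statistics. `sigma` is estimated once per stack as the median absolute
   deviation of all frame-to-frame first differences, scaled by
   $1/\sqrt{2}$ — robust against the minority of enhancing voxels. On data
   whose background noise has been clipped at zero the estimate runs low
   (clipped pairs contribute exact-zero differences); the derived
   thresholds are then mildly permissive. This is a known limitation of
   the estimator on the phantom's clipped-noise model.
2. **Too few samples.** With fewer than `min_fit_points` (default and floor
   4 — four free parameters) retained samples, the voxel is marked for
   piecewise-linear interpolation of the retained samples instead of a fit.
3. **Fit.** Bounded Levenberg–Marquardt least squares (via `minpack.lm`),
   tight tolerances (`ftol = ptol = 1e-10`) so that noise-free curves are
   driven to numerical precision.

Nonlinear least squares on a 4-parameter unimodal model with a handful of
samples is basin-sensitive, so the starting point matters more than the
optimizer. Two mechanisms make the fit reliable and deterministic:

* **Log-linear scan start.** For a *fixed* arrival time the model is linear
  in $(\log A, \alpha, 1/\beta)$ on the log scale:
  $\log v = \log A + \alpha \log(t - AT) - (t - AT)/\beta$. Nine candidate
  arrival times between the last zero-valued sample and the first positive
  sample are each solved by ordinary least squares, and the candidate with
  the smallest original-scale residual seeds the optimizer. For noise-free
  data this start is exact up to the AT grid spacing, which the LM polish
  removes. This rescues narrow curves ($\beta \sim 0.3$ s) whose peak falls
  between samples and whose decaying tail carries most of the information.
* **Deterministic multi-start.** The heuristic start (arrival at the latest
  pre-peak sample below 10% of peak; shape from a two-point log estimate
  using the sample nearest half-peak, where the estimate is best
  conditioned) plus four perturbations of it (shape halved/doubled, arrival
  shifted by one frame). The lowest-RMSE converged fit wins; ties cannot
  occur because candidates are evaluated in a fixed order with a
  strictly-smaller acceptance.

An iteration-capped fit whose RMSE is below $10^{-8}\times$ peak is accepted
as converged: when several parameter vectors reproduce the samples exactly
(see *identifiability* below) the optimizer wanders a flat valley and hits
the iteration cap with a numerically zero residual — that is a solution, not
a failure. Genuinely non-converged fits fall back to linear interpolation,
so the pipeline always emits a full stack.

### Identifiability

Four parameters need four informative samples. Samples before arrival are
only inequality constraints, so a voxel whose retained sampling contains
fewer than four post-arrival points — or whose peak lies beyond the last
retained sample — admits a continuum of exact fits (for any admissible $AT$,
the remaining three parameters solve a linear system). The package's
exact-recovery guarantee is therefore conditional: *noise-free curves
sampled with at least `min_fit_points` post-arrival points spanning
$T_{max}$ are recovered to better than $10^{-3}$ relative error* (in
practice, to $\sim 10^{-14}$). Under-sampled voxels still reconstruct
through an exactly interpolating curve, but the interpolant is not unique
and its values at dropped frames can deviate. This is a property of the
sampling, not the optimizer; it is why reconstruction error grows steeply
from 50% to 75% reduction on short runs.

## Synthesis

The synthetic DSA samples every voxel's reconstruction on the original
frame grid. The acquired (retained) frames are *also* replaced by model
values by default, so the output series is a single smooth curve rather
than a mixture of model and measurement; `keep_acquired = TRUE` passes the
acquired frames through verbatim for workflows that must preserve measured
data. Model values are clamped at zero (under the parameter bounds negative
values cannot occur; the clamp is an invariant guard, and tests assert it
never fires).

## The error metric

Fidelity against the ground-truth run is the relative signal-intensity
error $R_{SI}(t) = |SI^o(t) - SI^s(t)|/SI^o(t)$, time-averaged per voxel
over the frames where it is defined, then summarized as mean ± SD over
valid voxels. The ratio is singular at zero original intensity, so frames
with $SI^o \le \varepsilon$ are masked and a voxel is valid if at least one
frame is defined. The default guard is
$\varepsilon = \max(3\hat\sigma,\; 0.01 \times \text{full scale})$: the
background threshold, floored at 1% of the stack's maximum because below
that level "signal" in 8–12-bit angiographic data is quantization noise and
the ratio is meaningless (on noise-free synthetic data $\hat\sigma = 0$ and
the floor is what keeps the metric finite). Multiplying both stacks by a
common positive factor leaves the map unchanged when $\varepsilon$ is
scaled accordingly.

Heatmaps follow the reporting convention of the underlying method: green at
or below 3% error, red at or above 15% (clipped), a linear
green–yellow–red progression between, neutral gray where masked.

## The phantom

The phantom stands in for clinical cerebral DSA runs, which are not
publicly available. It emulates:

* a procedural vessel tree — random-walk polylines with tapering caliber
  (6 voxels down to 1), rasterized with anti-aliased strokes, giving both
  large-vessel and parenchymal regimes;
* three kinetic compartments with staggered arrival windows (arterial
  0.5–1.5 s, capillary 1.5–3 s, venous 3–5 s), shape $\alpha \sim U(1.5,4)$,
  timescale $\beta \sim U(0.3,1.2)$ s, peak enhancement 30–100% of full
  scale, scaled by edge coverage as a partial-volume effect;
* additive Gaussian noise (default 2% of full scale), clipped at zero as
  subtracted pixel data would be;
* full determinism: every draw flows from one seed, and generation leaves
  the caller's RNG stream untouched.

Default geometry is 16 frames at 2 fps and $64\times 64$ voxels — the
shortest run the clinical inclusion floor admits, at desk scale. Tests run
this size (or smaller) throughout; a full three-scheme synthesis of a
$64\times64\times16$ phantom takes on the order of a second.

It does **not** emulate: anatomically realistic vasculature, X-ray physics
(scatter, beam hardening), recirculation, motion (an optional global
translation is deliberately absent by default, matching the exclusion of
motion-degraded runs), or vessel overlap in projection. Consequently,
passing tests demonstrate the *pipeline's* correctness — exact parameter
recovery where identifiable, correct error accounting, deterministic
reproduction — not clinical image quality.

One structural consequence of the default geometry deserves emphasis: a
7.5-s acquisition cannot contain the full venous transit implied by the
compartment kinetics (venous $T_{max}$ can reach 9.8 s), so late-arriving
voxels are intrinsically under-sampled after reduction. Mean error figures
on the default phantom are therefore dominated by exactly the voxels a
longer clinical run would constrain; users studying venous-phase fidelity
should generate longer phantoms (e.g. `n_frames = 32`).

## Reader-study statistics

* **Composite score.** Four rubric items (arterial, capillary, venous
  phase, overall quality), each 1–5, summed to 4–20. The rubric table in
  the source material lists paired 1–5 scales per phase, but its own
  composite range (4–20) admits exactly four items; the four-item reading
  is implemented.
* **Kendall's W.** Rubric scores are heavily tied, so scores are converted
  to mid-ranks within each rater and the tie-corrected form
  $W = 12S / (m^2(n^3-n) - mT)$ is used; without ties it reduces to the
  classical $12S/(m^2(n^3-n))$, and both forms are cross-checked in the
  tests against a brute-force rank-sum-variance oracle. Significance uses
  the $\chi^2 = m(n-1)W$ approximation with $n-1$ degrees of freedom. A
  matrix in which every rater scores all subjects identically has no
  rank variance to measure and is rejected as undefined.
* **Coefficient of variation.** $100 \cdot s/\bar{x}$ with the sample
  (n−1) standard deviation.
* **Sample size.** Smallest per-group $n$ such that a two-sided two-sample
  t-test with pooled SD $\sqrt{(s_1^2+s_2^2)/2}$ attains the requested
  power, evaluated with the noncentral-t distribution at $2n-2$ degrees of
  freedom. Sidedness and the per-group/total reading were not stated in the
  source; the standard two-sided, per-group convention is implemented (the
  design values 16 ± 2 vs 13 ± 3 at $\alpha = 0.05$, power 0.75 give
  $n = 12$ per group, matching the published design). The noncentral-t
  result tracks the closed-form normal approximation to within ±2 subjects
  for moderate-to-large $n$, which the tests assert.

## I/O and formats

`raw_array` (flat little-endian float64 plus a plain-text sidecar) is the
package's lossless interchange format and the fixture format of the test
suite. `tiff_stack` writes multi-page TIFF at 32-bit sample depth with the
same sidecar; samples are normalized, so round-trips are exact to one part
in $2^{32}$ of full scale — far below any detector's quantization, but not
bit-exact. Multi-frame X-ray angiography DICOM is read through the host
Python's `pydicom` (no R DICOM reader is available); frame-rate provenance
is explicit override first, then the cine-rate, display-rate and frame-time
tags, then an error — clinical metadata is too unreliable to guess.
Subtracted angiograms render contrast dark, so DICOM input defaults to
polarity inversion; the package's canonical polarity is contrast-bright,
which keeps every downstream formula branch-free.

## Known limitations

* Exact recovery — and with it, sub-percent reconstruction error — is
  limited to voxels whose reduced sampling identifies the model (see
  *Identifiability*); on the default 16-frame phantom the venous
  compartment is partly outside that set, and 75% reduction leaves only
  four samples for four parameters, so noisy $T_{max}$ estimates at 75%
  carry median errors of several percent where 50% reduction stays near
  1–2%.
* The noise estimator biases low on zero-clipped background, loosening the
  background/masking thresholds on noisy phantoms.
* Fitting is purely per-voxel (no spatial regularization), matching the
  underlying method's description, so single-voxel noise is not smoothed
  spatially.
* The reader-study module computes the statistics; it does not address
  randomization, blinding or display calibration of an actual reader study.
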