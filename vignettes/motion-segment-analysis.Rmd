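---
title: "Analyzing spine motion-segment mechanics with spinemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing spine motion-segment mechanics with spinemech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemech)
```

# The measurement problem

Rodent studies of disc and vertebral pathology test a vertebra–disc–vertebra
*motion segment* on a materials-testing machine through a standard battery:

* **cyclic axial loading** — 20 cycles of ±0.5 N tension–compression at 1 Hz;
* **creep** — 45 min under a constant 0.5 N compressive step;
* **cyclic torsion** — 20 cycles of ±10° rotation at 1 Hz;
* **torsion to failure** — a 1°/s rotation ramp until the joint fails.

Each test yields a time series of load (force or torque) and deformation
(displacement or rotation). `spinemech` turns those recordings into the
scalar outcomes that factorial group comparisons need, and ships a synthetic
generator that emulates the whole experiment so the entire pipeline can be
validated without instrument data.

# Hysteresis-loop parameterization

The last (20th) cycle is extracted by `extract_cycle()`, re-phased to start
at the rising zero-crossing of the load channel. `axial_metrics()` and
`torsional_metrics()` then compute:

* **limb stiffness** — the slope of a line fitted over the extreme 20%
  (`window_fraction`) of the controlled-channel range at each end of the
  loading branch. For tension–compression this gives tensile and compressive
  stiffness in N/mm; for torsion the clockwise and counterclockwise slopes
  are averaged into one torsional stiffness in N·m/rad.
* **range of motion (ROM)** — the deformation span between the ± load limits
  on the loading branch, interpolated at the limit loads.
* **neutral-zone (NZ) length** — the deformation span over which |load| stays
  below 10% (`nz_fraction`) of the load amplitude, averaged over the loading
  and unloading branches. A dual-line alternative (the span between the
  zero-load intercepts of the two limb lines) is available via
  `nz_method = "intersection"`.
* **load/torque range** — the span of the load channel.

Three conventions deserve comment, because published protocols rarely print
them and different codes disagree:

* **Branch split.** Loading and unloading branches are separated at the
  extremes of the *controlled* channel — applied force in axial tests,
  imposed rotation in torsion. On a noiseless loop this is identical to
  splitting at the deformation extremes (the limb map is monotone), but when
  the measured channel carries sensor noise a split keyed to the measured
  extremes wanders by several samples and silently truncates the stiffness
  windows.
* **Regression orientation.** The measured channel is always the regression
  response: displacement is regressed on force, torque on rotation. The
  opposite orientation puts noise in the regressor and attenuates the slope
  (classical errors-in-variables bias); in simulation at bench-typical noise
  it understates stiffness by tens of percent.
* **Crossing interpolation.** Levels (load limits, NZ thresholds) are located
  on a branch after replacing the load by its isotonic regression along the
  branch. That is the identity on clean data, and under noise it is a
  consistent monotone de-noiser that keeps threshold crossings meaningful
  even when the threshold is close to the noise floor.

# The five-parameter creep model

Creep is analyzed with a five-parameter viscoelastic solid: an elastic
spring (stiffness $k_0$) in series with two Kelvin–Voigt arms — a fast arm
($k_1$, $\tau_1$) and a slow arm ($k_2$, $\tau_2$). Under a step load $F$
the displacement is

$$d(t) = \frac{F}{k_0}
       + \frac{F}{k_1}\left(1 - e^{-t/\tau_1}\right)
       + \frac{F}{k_2}\left(1 - e^{-t/\tau_2}\right).$$

This form carries three closed-form identities used throughout the package
and its tests: the elastic displacement is $F/k_0$, the asymptotic creep
displacement is $F(1/k_1 + 1/k_2)$, and total displacement is their sum.
We report the $t\to\infty$ asymptote rather than the 45-min value: the
asymptote is the quantity the model identities constrain, and with the slow
time constants seen in practice (≈ 12 min) the test window covers 3–6 slow
time constants, so the two differ by a few percent at most.

`fit_creep()` first trims the loading ramp — samples before the load reaches
95% of the step are discarded and time is re-zeroed at the first retained
sample (creep models assume a step; where the true load history matters the
trim point, not the nominal start, is the honest origin). The fit is
nonlinear least squares in *log-parameter* space, which enforces positivity
without constraints and removes the $\tau_1/\tau_2$ exchange symmetry trap
once arms are relabelled fast-first after the fit. Levenberg–Marquardt
(`minpack.lm::nls.lm`) runs from 8 starts — $\tau_1 \in \{10, 60\}$ s ×
$\tau_2 \in \{300, 1500\}$ s × two splits of the endpoint-estimated creep
compliance — with an analytic Jacobian, box bounds
($\tau \in [0.1, 10^5]$ s, $k \in [10^{-3}, 10^4]$ N/mm) and a cost
tolerance of $10^{-10}$. On noiseless 45-min, 10 Hz curves the generating
parameters are recovered to well under 0.1%; under 2 µm displacement noise
the median error of every parameter stays below 5% across replicate seeds.

# Failure detection

Failure strength and angle-to-failure are usually picked by eye. The
deterministic surrogate in `detect_failure()` is: failure strength = maximum
of the (optionally smoothed) torque; angle-to-failure = rotation at that
maximum; a specimen is *failed* only if torque subsequently drops by ≥ 20%
of the peak, otherwise the test is censored. Smoothing is a centered moving
average (default 0.5 s, `0` = raw peak). On clean ramps the detector equals
the brute-force argmax exactly. Under noise the localization error scales
with the smoothing window and the slopes flanking the peak; at bench-typical
torque noise (SNR ≈ 50) a 1 s window keeps the detected angle within one
window of the true peak, while the 0.5 s default occasionally lands just
outside its own window on shallow-rising ramps — worth knowing when failure
angles feed a group comparison.

# Morphometry

`compute_dhi()` implements the disc height index
DHI = (DH1 + DH2 + DH3)/(A1 + A2 + A3) from three disc-height and three
adjacent-vertebral-length measurements; it is permutation-symmetric within
each triple and scale-invariant, so magnification drops out.
`notochordal_band_fraction()` and `cell_density()` are the two
histomorphometric ratios (band area as % of nucleus pulposus area; cells
per mm² of counted area). Landmarking and outlining are upstream manual
steps; the package takes their measurements as given.

# The statistics layer

Each outcome is compared with a per-sex two-way fixed-effects ANOVA
(genotype × diet with interaction, `two_way_anova()`) followed by Tukey
pairwise comparisons among the four cells (`tukey_hsd()`), at α = 0.05.
Sexes are analyzed separately as strata, never pooled as a factor. Type II
sums of squares are the default so unbalanced cells are handled; on balanced
designs they coincide with the sequential decomposition (asserted in the
tests). Tukey p values use the studentized range with the Tukey–Kramer
correction for unequal n. No multiplicity correction is applied across
outcomes. Degenerate designs fail loudly: empty or single-observation cells
raise errors, and a saturated (zero-residual) fit reports limit p values
(1 for a zero effect, 0 otherwise) with a warning rather than NaNs.

Calibration is tested, not assumed: type-I error per effect is 0.05 ± 0.01
over 2000 null simulations, the one-way collapse satisfies $F = t^2$ against
the pooled t-test to $10^{-9}$, and Tukey p values are compared with a
10000-permutation max-T reference on n = 5/cell data. That last comparison
is made over six data realizations and judged at the median: the permutation
law conditions on each sample, so individual normal realizations can
disagree with the unconditional studentized-range tail by up to ~0.03 even
when both procedures are correct.

# The synthetic generator

`generate_recording()` inverts the analysis operators: noiseless output is
*exactly* analyzable, with limb slopes, ROM, NZ, creep parameters and
failure point equal to the per-specimen truth. Design choices that make the
round trip exact rather than approximate:

* Cyclic loops use a piecewise-linear limb construction with a low-stiffness
  central zone. The controlled channel follows a triangle wave sampled at
  200 Hz, so every knot (the 10% NZ threshold, the 80% window edge, the
  apex) falls exactly on the sample grid and linear interpolation between
  samples is exact. A smooth tanh limb (`shape = "sigmoid"`) is provided as
  a second functional form for robustness testing.
* Quantities that cannot land on the grid are snapped to it and the snapped
  value recorded as the truth: the torsional NZ edge and the failure angle
  (both to within one sample interval).
* The failure ramp rises as a concave power law with non-zero slope at the
  peak, then drops linearly by 50% over a further 20% of the failure angle.
  A corner peak keeps the smoothed argmax localized under noise; a
  flat-topped rise would let it wander.

`generate_cohort()` draws per-specimen truths from per-cell truncated-normal
distributions (truncation at 0.05 × mean keeps parameters physical; a
sampled fast time constant exceeding the slow one is label-swapped). The
default cell means and SDs (`reference_group_params()`,
`reference_morphometry_params()`) describe a 2 × 2 genotype-by-diet
factorial in juvenile mice of both sexes with n = 10 per cell. Default
sensor noise — 0.005 N force, 10⁻⁴ N·m torque, 2 µm displacement, 10⁻³ rad
rotation, white and Gaussian — represents plausible bench values, not a
measured instrument spectrum; real rigs show colored noise and drift the
generator does not emulate, so passing tests demonstrate correctness of the
estimators under the stated noise model, not robustness to every artifact
of real data.

Two physical-consistency adjustments are applied during sampling and
recorded in the emitted truth table:

* Draws whose stiffness-window spans cannot fit inside the drawn range of
  motion (or torque range) are redrawn — such a combination admits no
  monotone load–deformation loop at the protocol amplitude.
* The nominal torsional NZ distribution (≈ 0.37–0.40 rad) exceeds the total
  ±10° = 0.349 rad rotation span, which no within-loop definition of a
  neutral zone can reach; sampled values are capped at 90% of the feasible
  maximum (≈ 0.25 rad). Because every specimen hits the cap, this outcome
  is effectively constant within groups, and — with the 10% torque threshold
  only 1.5× above the torque noise sd — its noisy recovery is biased by a
  few percent. It is therefore excluded from the end-to-end
  mean-recovery check; all other outcomes are recovered within 2 SE of
  their generating means in a full simulated female cohort.

# Problem sizes and reproducibility

The validation suite runs a noiseless and a 100-seed noisy creep-recovery
study (27 001 samples each), 2000 null ANOVA simulations, six 10
000-permutation max-T comparisons, and a full female cohort (4 cells × 10
specimens × 4 recordings) analyzed end-to-end twice to confirm bit-identical
reruns under a fixed seed — sizes chosen so the whole suite completes in a
few minutes on one core while leaving Monte-Carlo error well below the
asserted tolerances. All randomness flows through R's Mersenne-Twister
generator from user-supplied seeds; identical seeds give byte-identical
recordings, tables and reports.

# Known limitations

* The five-parameter solid is linear; poroelastic or nonlinear viscoelastic
  behavior, and stress (rather than force) normalization by disc geometry,
  are out of scope.
* Stiffness-window and NZ-threshold fractions are conventions (20% / 10%);
  published values extracted with different windows are comparable only
  qualitatively.
* Hysteresis energy and loss angle are not computed; the default generator
  loop is loss-free.
* Failure-location labels (growth plate vs disc) are annotations passed
  through, never inferred from the signal.
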