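---
title: "Methods: dynamic TSPO-PET quantification with ponsPET"
author: "ponsPET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic TSPO-PET quantification with ponsPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponsPET)
```

## The problem

Diffuse intrinsic pontine glioma (DIPG) is an infiltrative pediatric
brainstem tumour centred on the pons. Because DIPG cells (and activated
glia) overexpress the 18 kDa translocator protein (TSPO), dynamic PET with
a TSPO radioligand such as ^18^F-DPA-714 can delineate the tumour where
static SUV images struggle against ependymal and vascular background
binding. `ponsPET` implements the quantitative analysis chain for such a
study in a rat xenograft setting — SUV normalisation, regional
time–activity curves (TACs), late-window averaging, pons-to-striatum AUC
ratios, an image-derived whole-blood input function (IDIF), and Logan
graphical analysis yielding regional and voxel-wise total volumes of
distribution $V_T$ — together with a digital phantom simulator that
provides ground truth, since no public rat dataset of this design exists.

## Acquisition model

A dynamic acquisition is a contiguous `FrameSchedule` in seconds. The
default is the 24-frame, 60-min protocol
$3\times30, 5\times60, 5\times120, 3\times180, 3\times240, 4\times300,
1\times150$ s. Images are decay-corrected activity concentration in
kBq/cm^3^, so no isotope decay appears anywhere in the simulator. Each
reconstructed frame is modelled as the *time average* of the underlying
concentration over the frame (reconstruction integrates counts), not an
instantaneous sample; `frameAverage()` makes this explicit and is reused
by both the simulator and the test oracles.

## Kinetic model

Tissue kinetics follow the standard reversible two-tissue compartment
model (2TCM) with rates $K_1$ (mL·cm^-3^·min^-1^), $k_2, k_3, k_4$
(min^-1^) and fractional blood volume $v_B$:

$$C_{PET}(t) = (1 - v_B)\, \big(\mathrm{IRF} \otimes C_b\big)(t)
  + v_B\, C_b(t), \qquad
  \mathrm{IRF}(t) = \phi_1 e^{-\alpha_1 t} + \phi_2 e^{-\alpha_2 t},$$

with macro-rates $\alpha_{1,2}$ the eigenvalues of the compartment
system; $k_3 = 0$ reduces to the one-tissue model. Reversibility
($k_4 > 0$ whenever $k_3 > 0$) is enforced at the type level because the
total volume of distribution

$$V_T = \frac{K_1}{k_2}\Big(1 + \frac{k_3}{k_4}\Big)$$

is otherwise infinite and Logan analysis inapplicable. $V_T$ here is the
*tissue* distribution volume: the $v_B$ term is treated as a measurement
nuisance and excluded from `analyticVt()`. This matters when reading the
phantom results below: a whole-blood Logan fit on data containing 5%
blood volume recovers approximately $(1-v_B)V_T + v_B$, a known positive
bias of blood-input graphical methods that the package documents rather
than hides.

The whole-blood input is the tri-exponential bolus model
$C_b(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t}$ with $\lambda_1 > \lambda_2 > \lambda_3 > 0$,
clipped at zero, which gives $C_b(0) = 0$, a sharp early peak and a
slowly clearing tail.

### Numerical evaluation

The convolution is evaluated on a uniform 0.05-s grid. Each exponential
mode is propagated by the exact update for piecewise-linear input,

$$y_{i+1} = e^{-\alpha \Delta t} y_i + \int_0^{\Delta t}
e^{-\alpha(\Delta t - u)} C_b(t_i + u)\, du,$$

whose integral has a closed form; the recurrence is executed in C via
`stats::filter`. The only discretisation error is the piecewise-linear
representation of $C_b$ within a step; against an independent stiff ODE
solution (`deSolve::lsoda`, tested in the suite) the worst-case
difference is below $10^{-6}$ of the curve peak.

## The digital phantom

`defaultPhantomSpec()` describes a 28 × 24 × 18 voxel grid (1 mm
isotropic) holding simple disjoint ellipsoids for the seven brain VOIs —
pons, medulla, cerebellum, choroid plexus, midbrain, striatum and the
rest of the forebrain — plus an abstract "left-ventricle" blood-pool
cylinder in a separate slab. Shapes are deliberately schematic: the
pipeline consumes region *identities* and kinetics, so anatomical realism
buys nothing here, and no cardiac motion or partial-volume effect is
modelled.

### Calibration of the defaults

The animal study this design emulates is not deposited, so all kinetic
parameters are simulator inputs. The defaults are a *calibration*, not
ground truth, chosen once on noiseless curves:

* pons $V_T = 0.15$ mL/cm^3^ in the sham condition; the DIPG group
  doubles it to $0.30$ via `applyVtMultiplier()`, which rescales $k_3$ at
  fixed $K_1/k_2$ so delivery and early kinetics are untouched;
* the striatum — the designated pseudo-reference region with negligible
  specific binding — has the lowest $V_T$ (0.08), putting the noiseless
  pons-to-striatum AUC ratio near 1.49 for sham animals and 2.37 for the
  tumour group. With an exact $V_T$ doubling these two ratios cannot be
  squeezed into an arbitrary pair; the package prioritises the $V_T$
  contrast and reports the AUC ratios that follow;
* input amplitudes are scaled so the sham pons late-window SUV is about
  0.33 at the reference injected dose of 169 kBq per gram of body
  weight. Each subject's blood curve scales linearly with its own dose
  per gram, which makes SUV dose-invariant by construction;
* $v_B = 0.05$ for all brain regions; the blood pool carries the pure
  blood curve.

### Noise model

Voxel noise is zero-mean Gaussian with standard deviation
$\sigma = \eta \sqrt{(C + C_0)/w}$, where $C$ is the noiseless voxel
value, $C_0$ a small floor (0.05 kBq/cm^3^) so background is not exactly
zero, and $w$ the frame duration relative to the mean frame duration —
short early frames are noisier, as after reconstruction. The default
pipeline level $\eta = 1$ corresponds to roughly 10% single-voxel CV on
late tissue frames, a realistic post-reconstruction magnitude; raw-count
Poisson simulation is deliberately out of scope. A second, simpler model
(`addFrameNoise()`, constant CV) serves curve-level robustness studies
where the duration weighting would only obscure the question. Simulations
are bit-reproducible: a master seed deterministically derives per-subject
seeds, and the simulator restores the caller's RNG state.

What the phantom does *not* emulate — anatomy, partial volume, motion,
scatter, attenuation, metabolite kinetics in blood — bounds what passing
tests show: they validate the estimators and the pipeline, not the
biology of any particular animal.

## Quantification choices

* **SUV** is concentration divided by injected dose per body weight,
  taking 1 cm^3^ of brain as 1 g; it is linear in concentration and
  inversely proportional to dose per gram (both tested as identities).
* **Region means** are unweighted voxel averages.
* **Static averaging** uses the 25.5–60 min window; frames belong to the
  window by *mid-time* membership (unambiguous for straddling frames) and
  are weighted by duration. On the default schedule exactly 8 frames
  qualify.
* **AUC** integrates the SUV curve by the trapezoidal rule on frame
  mid-times over 0–60 min, with a (0, 0) anchor prepended when the first
  sample lies after injection — the tracer concentration at $t = 0$ is
  zero, and leaving the first 15 s rectangle open would be arbitrary.
  Interval edges interpolate linearly; an upper edge beyond the last
  mid-time truncates rather than extrapolates. Whether the emulated
  protocol anchored its AUC at the origin is unknown; this choice is the
  package's own and is additive over adjacent intervals by construction.
* **AUC ratio** divides a target region's AUC by the striatum's for the
  same subject and interval.

## Logan graphical analysis

With running integrals anchored at the origin, the fit is ordinary least
squares of $\int_0^T C_T\,dt / C_T(T)$ on $\int_0^T C_b\,dt / C_T(T)$
restricted to frame mid-times $T \ge t^* = 22.5$ min (9 of 24 frames on
the default schedule); the slope is $V_T$ and the intercept is kept as a
diagnostic. The tissue-to-blood ratio curve (`tissueToBloodRatio()`) is
the documented $t^*$ diagnostic: it should be approximately stable after
$t^*$. Choices the underlying method leaves open were resolved as
follows and are configurable: plain OLS (no perpendicular or multilinear
variant), trapezoidal integrals on mid-times with origin anchoring, and
mid-time-based frame selection at $t^*$.

The voxel-wise map shares the precomputed blood integral and runs the
same estimator on every voxel of an analysis mask — by default, voxels
whose late-window mean exceeds 0.2 of the brain mean (labelled non-blood
voxels). Voxels with any non-positive late-frame value have no defined
Logan coordinates; they are dropped from fitting, counted in `nDropped`,
and zeroed rather than silently imputed. On noiseless phantoms the
per-region median of the map agrees with the ROI fit to machine
precision, which the acceptance suite asserts at 10^-6^.

Because $V_T$ is a tissue-to-blood ratio, scaling the input function by
$c$ divides the slope by $c$, scaling the tissue curve multiplies it by
$c$, and a joint rescaling (a calibration-unit change) leaves it
unchanged — all three are tested.

## Statistical layer

Group summaries report mean ± sample SD ($n-1$; a single subject's SD is
missing, not zero). The group effect is assessed with a two-way
fixed-effects ANOVA on brain structure × group with interaction,
followed by per-structure two-group comparisons with Bonferroni
adjustment across the seven structures ($p_{adj} = \min(1, 7p)$), at a
95% confidence level. Two dialect decisions the emulated design leaves
open: the pairwise test defaults to the Welch unequal-variance form
(sensible with 6 vs 4 subjects; Student's form is a flag away), and the
unbalanced ANOVA uses Type-II sums of squares, which avoids
interaction-ordering ambiguity for main effects and reduces to the
textbook decomposition on balanced data (asserted against explicit
sums-of-squares formulas at 10^-8^).

## The pipeline and reproducibility

`runPipeline()` composes simulate → quantify → model → compare from one
configuration list (or YAML file) that exposes every tunable named
above. It writes, per subject, the dynamic image with its BIDS-style
frame-timing sidecar, the static SUV image, the TAC table, and the $V_T$
map; per cohort, tidy measurement/summary/comparison tables and a JSON
manifest with the configuration, its hash, per-stage wall times and MD5
checksums of every output. Identical seeds give identical checksums;
any stage failure aborts with the stage name and offending subject.

## Problem sizes and known limitations

Simulation-based checks in the test-suite and acceptance script use
deliberately modest sizes — the 12-point kinetic grid with 100 noisy
replicates per point, 10 simulated cohorts of 6 + 4 subjects for the
contrast recovery, 1000 null repetitions (at the curve level, where the
image resolution adds nothing to the question of test size) for the
type-I error — chosen so the full suite re-runs in minutes while leaving
the Monte-Carlo error well inside each asserted tolerance.

Known limitations, all documented rather than corrected: the whole-blood
IDIF is used without metabolite or plasma-parent correction; the $v_B$
term biases blood-input Logan $V_T$ upward by roughly
$(1-v_B)V_T + v_B$; Logan with noiseless data still carries a small
negative finite-$t^*$ bias (up to ~5% on the slowest grid kinetics); and
the phantom's between-subject variability stems from measurement noise
and dosing only, not from biological parameter spread, so simulated
p-values are cleaner than animal data would give.
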