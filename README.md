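# ponsPET

Quantification of dynamic brain PET for an orthotopic rat model of
diffuse intrinsic pontine glioma (DIPG) imaged with the TSPO radioligand
^18^F-DPA-714 — written for imaging scientists who need the full chain
from 4D dynamic images to group statistics, with a simulator providing
ground truth at every step.

DIPG is an infiltrative pediatric brainstem tumour centred on the pons.
Its cells overexpress the 18 kDa translocator protein (TSPO), so a TSPO
radioligand can delineate the tumour where static SUV imaging struggles
against ependymal/vascular background. The package implements:

* **SUV** normalisation: `SUV = C (kBq/cm³) / (dose (kBq) / weight (g))`,
  with 1 cm³ of brain taken as 1 g;
* **TAC extraction** over seven brain VOIs (pons, medulla, cerebellum,
  choroid plexus, midbrain, striatum, forebrain), late-window (25.5–60
  min) static averaging, and 0–60 min **AUC** (SUV·min) with the
  **pons-to-striatum AUC ratio** using the striatum as pseudo-reference;
* an **image-derived whole-blood input function** from a blood-pool VOI;
* **Logan graphical analysis**: OLS of `∫C_T/C_T(T)` on `∫C_b/C_T(T)`
  for frame mid-times `T ≥ t* = 22.5 min`; the slope is the total volume
  of distribution `V_T = (K1/k2)(1 + k3/k4)` (mL/cm³), fitted per ROI and
  voxel-wise into parametric maps;
* the **statistical layer**: structure × group two-way ANOVA (Type-II)
  with Bonferroni-adjusted per-structure comparisons, plus Welch
  two-group tests;
* a **digital phantom simulator**: reversible two-tissue-compartment
  kinetics over disjoint shape primitives, a tri-exponential blood
  model, duration-weighted Gaussian noise, and DIPG-vs-sham cohorts
  (6 vs 4 subjects, pons V_T doubled through k3) with per-subject seeds
  and full ground truth.

Everything is S4 with validity checking; images travel as NIfTI-1 with a
BIDS-style frame-timing JSON sidecar, tables as TSV.

## Worked example

```r
library(ponsPET)
sim <- simulateStudy(defaultPhantomSpec(noiseLevel = 1),
                     defaultFrameSchedule(),
                     dose = 16900, weight = 100, seed = 1)
sim
#> SimulatedStudy: subject sim01 (sham), 7 regions, 24 frames
#>   true V_T (mL/cm3): pons=0.150, medulla=0.130, cerebellum=0.120,
#>   choroid_plexus=0.160, midbrain=0.120, striatum=0.080, forebrain=0.110

idif <- extractIdif(sim@study, sim@labels)
loganFit(extractTac(sim@study, sim@labels, "pons"), idif)
#> LoganResult sim01/pons: V_T = 0.1917 mL/cm3 (intercept -4.620 min,
#>   n = 9, R2 = 1.0000, t* = 22.5 min)

pons <- suvTransform(extractTac(sim@study, sim@labels, "pons"), 16900, 100)
stri <- suvTransform(extractTac(sim@study, sim@labels, "striatum"), 16900, 100)
aucRatio(tacAuc(pons), tacAuc(stri))
#> [1] 1.496223
```

The Logan estimate (0.192) sits above the true tissue V_T (0.150) by
almost exactly `(1 - vB)·V_T + vB` — the documented blood-volume bias of
whole-blood-input Logan analysis, not an estimator defect. The AUC ratio
1.50 is this sham subject's pons-to-striatum contrast; a DIPG subject
(pons V_T doubled) lands near 2.4.

A full cohort run — simulation, per-subject images, TACs, AUC ratios,
ROI and voxel-wise V_T, group statistics, manifest — is one call:

```r
res <- runPipeline(defaultRunConfig("out", seed = 1))
subset(res$comparisons, measure == "VT" & significant)
```

With the default configuration the pons is the only region whose V_T
survives Bonferroni adjustment, mirroring the tumour contrast the
simulator encodes.

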