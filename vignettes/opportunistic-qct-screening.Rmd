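---
title: "Opportunistic QCT screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic QCT screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(QCTscreen)
```

# The measurement problem

Routine perioperative CT of the lumbar spine contains, for free, the
information a dedicated densitometry exam would acquire: the X-ray
attenuation of trabecular bone in the vertebral bodies. Opportunistic
screening extracts it in three steps — isolate the trabecular
compartment, convert mean attenuation to volumetric bone mineral density
(BMD, mg/cm³ calcium-hydroxyapatite equivalent), and classify against
the ACR bands — and the case-control stage then asks whether patients
with an adverse outcome (here, pedicle-screw loosening after semi-rigid
lumbar instrumentation) had systematically lower BMD than matched
controls. This vignette records the models behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open.

# Trabecular ROI extraction

Per vertebral level (L1–L4), the measurement ROI is derived from a label
map co-registered with the CT volume. The label dialect is fixed and
enforced on read: 0 background, 1–4 vertebral bodies L1–L4, 101–104 the
corresponding posterior elements, 200 hardware. Three set-shrinking
stages follow.

**Body selection.** Only the body label enters; posterior elements are
removed by construction. Imported segmentations that do not separate
posterior elements from bodies cannot be processed without an upstream
split — the package does not attempt one.

**Metal exclusion** (`metal_threshold_hu`, default 1400 HU). Any voxel
at or above the threshold is removed. The boundary is deliberately
inclusive (≥, not >): a voxel at exactly the threshold is almost
certainly a partial-volume metal voxel, and a metal voxel inside a
density ROI is a worse error than one discarded bone voxel.

**Metric erosion** (`erosion_depth_mm`, default 10 mm). The mask keeps
exactly the voxels whose Euclidean distance to the mask complement
exceeds the depth, computed in world millimetres. Two points were
decisive here:

* *Metric, not morphological.* The depth is a physical quantity and the
  voxels are anisotropic (sagittal reformations have 2–3 mm slices), so
  iterating a structuring element would erode different physical depths
  along different axes. The implementation is a separable exact squared
  Euclidean distance transform (lower-envelope algorithm per axis, with
  the per-axis spacing as the sampling step), run on the mask's bounding
  box padded by one voxel — exact, because every voxel outside a mask's
  bounding box belongs to the complement. The test suite checks the
  transform against an exhaustive distance-scan oracle on random
  anisotropic masks.
* *Order of operations:* selection → metal exclusion → erosion. Removing
  metal first means the screw hole is part of the complement when the
  erosion runs, so the 10 mm margin also buffers the partial-volume halo
  around hardware. Only bone well clear of both cortex and metal remains.

**QC** replaces visual inspection with explicit rules: a level is
excluded if it is on the `manual_exclusions` list (the analogue of a
reader dropping a fractured or severely degenerated vertebra), if
erosion emptied its mask, or if fewer than `min_roi_voxels` (default 50)
survive. The default floor keeps the standard error of the ROI mean
below ~3 HU at a trabecular noise SD of 20 HU. A level is included iff
no reason applies.

# Densitometry

Calibration is linear, `BMD = slope·HU + intercept`, per tube voltage
(120 kVp standard, 140 kVp postmyelography; the equation's kVp must
match the volume's, enforced with an error). The coefficients are
scanner-specific, established from separately scanned density phantoms,
and deliberately have **no default**: the command-line `screen` refuses
to run without a calibration file, because a silently wrong calibration
produces plausible-looking, wrong BMD. By linearity, calibrating the ROI
mean equals averaging per-voxel calibrated values, which the tests assert
exactly.

The patient value is the **unweighted mean over included levels** — the
plain reading of averaging "over multiple levels" — rather than a
voxel-weighted mean, which would let a single large vertebra dominate.
The patient's ACR category is derived from the aggregated BMD, not from
a vote over per-level categories, matching how single per-patient values
are reported clinically. Band boundaries are inclusive to low bone mass:
osteoporosis BMD < 80, low bone mass 80 ≤ BMD ≤ 120, normal > 120
mg/cm³.

# The phantom generator

The generator exists to give the pipeline inputs with known ground
truth, not to imitate CT physics. A vertebral body is an elliptic
cylinder: a cortical shell (default 800 HU, thickness 2 mm) enclosing a
trabecular interior of i.i.d. Gaussian HU; a posterior box stands in for
the posterior elements; screws are cylinders of ≥ 1400 HU (default
3000 HU) painted over whatever they intersect. The flat cylinder (no end
caps) keeps the analytic interior/shell decomposition exact, and the
topology — a dense shell enclosing the compartment being measured — is
the only anatomical feature the pipeline's arithmetic is sensitive to.
Degeneration is emulated as a sclerotic spherical inclusion (600 HU)
inside the body, giving the QC exclusion path something real to act on.

Default tissue values (soft-tissue background 50 HU, cortical 800 HU,
screws 3000 HU) are plumbing defaults in the plausible clinical range,
all configurable. Geometry uses world millimetres with 0-based voxel
indices, so voxel *i* sits at *i*·spacing.

Randomness is split into one stream per operation, seeded from the user
seed plus an operation tag: adding hardware or simulating a cohort never
perturbs the trabecular noise of an already generated volume, and every
generator is bit-reproducible under a fixed seed.

The cohort simulator's defaults are the published study conditions: 23
cases with BMD ~ Normal(86.5, 29.5²) and 23 controls with
BMD ~ Normal(118.2, 32.9²) mg/cm³ (where the summary table prints the
control SD rounded to 33, the text value 32.9 is taken as canonical),
61% women, age ~ Normal(69.9, 9.1²) years, constructs distributed
2:16:8:18:2 over L1-5, L2-5, L2-S1, L3-S1, L4-S1. Covariates follow the
matched design: each control shares its case's sex and construct with a
small age jitter, because the study groups were matched on exactly those
variables. Normality is an assumption — the source reports only means
and SDs — with a consequence discussed under Limitations.

**What passing tests show, and what they do not.** The phantoms have
uniform Gaussian trabecular noise, perfect labels, no beam hardening,
no metal streak artifacts, no scanner noise spectrum, and no real
anatomical variation. Tests passing on them demonstrate that the
pipeline's geometry and arithmetic are correct — metal exclusion, metric
depth, calibration, aggregation, the statistics — not that segmentation
or calibration would be accurate on clinical scans. Conversely, failures
on real data would implicate the inputs (labels, coefficients), not this
arithmetic.

# Case-control statistics

**Matching** is greedy 1:1 nearest-age within exact sex/construct
strata, processing cases in ascending age, ties toward the younger
control then record order. Optimal (e.g. Hungarian) assignment was
deliberately not used: the emulated study does not describe its
algorithm, and the greedy rule is deterministic and auditable.

**Variance gate.** Group means are compared with an independent-samples
t-test whose variance assumption follows Levene's test: mean-centred
(the classic variant, an ANOVA F on absolute deviations from group
means — not the median-centred Brown–Forsythe), gate at p < 0.05 →
Welch. A summary-statistic variant (`tFromSummaries`) computes the same
test from printed means/SDs/sizes, which is how a published comparison
is re-derived without raw data.

**Chi-square** on 2×2 category tables is Pearson's statistic *without*
Yates continuity correction. This was not a style preference: the
published per-category p-values (0.003 for osteoporosis, 0.022 for
normal BMD) are reproduced only by the uncorrected statistic — the
corrected one gives ≈ 0.009 and ≈ 0.05 — so the uncorrected variant is
what the original analysis used.

**ROC.** The AUC is the Mann–Whitney statistic (tied case-control pairs
count ½), with lower BMD marking the case state. Significance against
AUC = 0.5 uses the null-hypothesis standard error
√((n₁+n₂+1)/(12 n₁n₂)); the 95% CI uses the Hanley–McNeil standard error
at the observed AUC, clipped to [0, 1]. This pairing reproduces the
published significance level (p = 0.002 at AUC 0.769, n = 23/23); the
CI remains an approximation — the published interval (0.634–0.905) is
slightly asymmetric about its AUC, so the original software's variant
differed marginally. A closed-form binormal oracle,
AUC = Φ(|μ₂−μ₁|/√(σ₁²+σ₂²)), anchors the simulation tests: at the
published group parameters it gives 0.763.

**Youden point.** Candidate cutoffs are the midpoints between
consecutive distinct pooled scores plus ±∞ sentinels — between two
observed values every cutoff yields the same confusion matrix, so
midpoints lose nothing and avoid knife-edge comparisons at observed
values. Ties in J are broken toward higher sensitivity, then the lower
cutoff: in a screening context, missing a true positive is the costlier
error, and the rule is deterministic.

All p-values are two-sided; outputs round to 3 decimals for display
while full precision is retained and serialised.

# Numerical choices and degenerate inputs

* ROI SD uses the n−1 denominator; a single-voxel ROI reports SD 0.
* Zero-variance degenerate cases return limits rather than errors where
  a limit is well defined: identical constant samples give t = 0, p = 1
  (and Levene W = 0, p = 1); constant samples with differing means give
  |t| = ∞ with p reported at the double floor; an all-tied ROC is
  flagged degenerate at AUC 0.5.
* Empty eroded masks are legal and routed to QC, not errors; an empty
  ROI reaching the measurement stage is an error, because QC should have
  caught it.
* Erosion at depth 0 is the identity; erosion distances are compared
  strictly (> depth), so a voxel exactly at the depth is removed.

# Problem sizes

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo tolerances meaningful while keeping the suite quick: phantom
grids of 48×64×40 voxels at 1 mm (one vertebra, ROI ≈ 1,000–1,800
voxels), 20-phantom recovery sweeps with true BMD uniform in [60, 160],
brute-force oracle comparisons on masks up to 7×6×5 voxels, 10⁵-draw
cohort checks for generator calibration, and 2,000 replicate cohorts of
n = 23 + 23 for the AUC consistency band. Recovery accuracy is asserted
at 2 mg/cm³ absolute error, with a sign test at the 1% level guarding
against bias.

# Known limitations

* The published operating point (sensitivity 91.3%, specificity 56.5%
  at BMD < 81.8 mg/cm³) is not consistent with normal group
  distributions at the published means and SDs — a normal model puts the
  case sensitivity near 44% at that cutoff — so the empirical BMD
  distribution was evidently non-normal. The simulator therefore cannot,
  and does not try to, reproduce the threshold 81.8; only the J
  arithmetic (0.913 + 0.565 − 1 = 0.478) and AUC-level consistency are
  checked.
* Calibration application only: fitting slope/intercept from a density
  phantom scan is out of scope, as are DXA areal BMD, T-scores and
  fracture-risk scores.
* No learning-based segmentation: labels are ground truth from the
  generator or supplied by the user; vertebra labelling from images is
  out of scope.
* Screw loosening is an assigned group label, not a mechanistically
  simulated outcome; the phantom does not model radiolucent halos.
* Single-reader QC, logistic adjustment, multiple-testing correction and
  DeLong confidence intervals are intentionally absent, mirroring the
  emulated analysis.
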