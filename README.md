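# QCTscreen

Opportunistic osteoporosis screening from routine CT, end to end: from a
lumbar CT volume with vertebra labels to a per-patient volumetric bone
mineral density (BMD), and from a matched case-control cohort of such
measurements to the full comparison statistics. The package is aimed at
researchers studying the link between low BMD and pedicle-screw loosening
after lumbar instrumentation, and more generally at anyone validating an
opportunistic QCT measurement pipeline against published summary results
without access to raw patient data.

## What it computes

**Trabecular ROI extraction.** For each vertebral level L1–L4 in a label
map, the measurement ROI is built in three steps, each returning a subset
of the previous mask:

1. *body selection* — only the vertebral-body label is kept (posterior
   elements and hardware carry distinct codes);
2. *metal exclusion* — every voxel with attenuation ≥ 1400 HU is removed,
   which cleanly delineates pedicle-screw contours;
3. *metric erosion* — the mask is eroded by a physical depth of 10 mm,
   computed with an exact anisotropic Euclidean distance transform in
   world millimetres, excluding cortical bone and partial-volume effects
   around metal.

A rule-based QC stage (manual exclusion list, empty-mask and minimum-size
checks) replaces visual inspection.

**Densitometry.** The ROI mean attenuation x̄(HU) is converted to
volumetric BMD by an asynchronous linear calibration BMD = a·x̄ + b
(scanner- and kVp-specific coefficients; 120 kVp standard, 140 kVp
postmyelography), averaged unweighted over included levels, and
classified by the ACR bands: osteoporosis BMD < 80, low bone mass
80 ≤ BMD ≤ 120, normal BMD > 120 mg/cm³.

**Case-control statistics.** Greedy nearest-age matching within exact
sex/construct strata; Levene-gated two-sample t-tests (pooled Student t
when the mean-centred Levene p ≥ 0.05, Welch otherwise), also directly
from printed summary statistics; uncorrected Pearson chi-square on 2×2
tables; the Mann–Whitney AUC (ties ½) with null standard error
√((n₁+n₂+1)/(12 n₁n₂)) for significance and the Hanley–McNeil standard
error for the 95% CI; and the Youden-optimal operating point
(J = sensitivity + specificity − 1, scanned over midpoints between
consecutive distinct scores).

**Synthetic phantoms.** A first-class generator produces lumbar CT
phantoms (elliptic-cylinder bodies with a cortical shell, Gaussian
trabecular interior, posterior elements, optional ≥ 1400 HU pedicle
screws) with ground-truth label maps, plus matched case-control cohorts
whose default parameters are the published group summaries (case BMD
~ N(86.5, 29.5²), control ~ N(118.2, 32.9²) mg/cm³, n = 23 per group).

## Worked example

Paint a phantom vertebra at a true BMD of 95 mg/cm³ under the calibration
BMD = 0.8·HU − 5, add a pedicle screw, and screen it:

```r
library(QCTscreen)
eq <- CalibrationEquation(120, slope = 0.8, intercept = -5)
ph <- generateVolume(
  list(vertebraSpec("L1", center = c(24, 20, 20),
                    trabecular_mean_hu = bmdToHu(95, eq),
                    trabecular_sd_hu = 15)),
  grid = list(dim = c(48, 64, 40), spacing = c(1, 1, 1)), seed = 7)
hw <- hardwareSpec(3, 36, 3000,
                   trajectories = list(list(entry = c(38, 20, 2),
                                            direction = c(0, 0, 1))))
inst <- addInstrumentation(ph$volume, ph$labels, hw)
runScreening(inst$volume, inst$labels, eq = eq)
#> Opportunistic BMD screening report: patient
#>   L1: mean 124.7 HU over 1161 voxels -> 94.8 mg/cm^3 (low_bone_mass)
#>   patient BMD 94.8 mg/cm^3 (low_bone_mass), levels L1
```

The screw and a 10 mm margin around it are excluded, so the measured
94.8 mg/cm³ recovers the painted 95 mg/cm³ to within the trabecular-noise
standard error. A simulated matched cohort runs through the full
analysis stage:

```r
buildTable2(simulateCohort(cohortSpec(seed = 1)))
#> Case-control BMD analysis
#>   case    n=23, BMD 89.2 (28.9) mg/cm^3
#>   control n=23, BMD 123.9 (30.9) mg/cm^3
#>   t-test: t = -3.94, df = 44.0, p = 0.000 (pooled variance)
#>   ACR category counts (case/control):
#>     osteoporosis  10 / 2  (chi-square p = 0.007)
#>     low_bone_mass 10 / 9  (chi-square p = 0.765)
#>     normal        3 / 12  (chi-square p = 0.005)
#>   ROC: AUC = 0.792 (95% CI 0.660-0.924), p = 0.001 vs 0.5
#>   Youden point: BMD < 108.5, sens 0.783, spec 0.783, J = 0.565
```

Here lower BMD marks the case (screw-loosening) state: cases sit about
one ACR band below controls, and BMD separates the groups with an AUC
near 0.78 — the behaviour the cohort defaults were calibrated to emulate.

A thin command-line wrapper is installed at `inst/cli/qctscreen`
(`phantom volume`, `phantom cohort`, `screen`, `stats run`, `reproduce`).

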