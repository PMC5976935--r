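---
title: "Methods: opportunistic CT biomarkers and matched mortality modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opportunistic CT biomarkers and matched mortality modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmort)
```

## The problem

Low-dose chest CT acquired for lung cancer screening contains far more
prognostic information than the nodules it is read for.  Four
"opportunistic" biomarkers are quantifiable from the same images at no
extra cost to the patient: coronary artery calcification (CAC),
emphysema, pectoralis muscle area, and subcutaneous fat attenuation.
ctmort implements a complete analysis chain for asking whether these
biomarkers separate survivors from nonsurvivors among subjects whose
lung cancer was detected by screening: image quantification, a
screen-detected cohort flow with variance-normalised 1:1 matching, and
multivariate logistic and Cox mortality models.

Trial imaging and rosters of this kind are access-restricted, so the
package treats synthetic data as a first-class module: thorax phantoms
whose ground truth is *enumerated from the painted label masks* (never
copied from the generating configuration), and rosters reproducing the
published stratum counts.  Every imaging operator is validated against
exact painted truth; every model is validated by planted-effect
recovery.

## Image quantification

All operators consume a `ct_volume`: a Hounsfield-unit (HU) grid with
physical pixel spacing in mm, read from DICOM series (rescale slope and
intercept applied) or MetaImage files.  In-plane index order is
`(row, col)` throughout; all area computations depend only on spacing.

**CAC** (`cac_score` and friends).  A circular heart region of interest
(centre, radius in pixels) is a required user input, matching the
original semi-automatic workflow; there is no automatic heart
detection.  The slice is first normalised against its background: the
air level is estimated as the *median of all pixels below -800 HU* and
the difference from -1000 HU is subtracted everywhere.  The published
method says only that images were "normalized via the background
values"; median-of-air was chosen because it is robust to the lung
parenchyma that also falls below -800 HU and is exactly testable on
phantoms.  Calcified pixels are those *strictly above 130 HU* with
centres inside the circle.  Counts map to the four-grade scale (0 none,
1 minimal, 2 moderate, 3 severe) through three cutpoints calibrated by
quantile matching against reader grades: the cutpoint below grade *k*
sits at the count quantile equal to the cumulative reader frequency of
grades below *k*, realised as the midpoint between the two straddling
sorted counts.  Two conventions are frozen: a count exactly equal to a
cutpoint takes the *higher* grade, and grades are coded 0-3 internally
(the source literature mixes 1-4 and 0-3 codings; the 0-3 scale is the
one consistent with reported grade means of about 1 and 2).

**Emphysema** (`segment_lungs`, `compute_laa`).  Lung fields are the
connected components below -400 HU that do not touch the image border
(exterior air does), keeping the two largest.  The low-attenuation-area
(LAA) fraction is the proportion of lung voxels *strictly below
-950 HU* — "less than" is taken literally and frozen.  The fraction is
a pure voxel histogram statistic: permutation-invariant within the mask
and monotone in the threshold.  The original analysis delegated lung
segmentation to external software, so this stage is the package's own
and is validated only on phantoms, where it recovers the painted lungs
exactly.  "Proportion of total lung volume" is interpreted as a
voxel-count proportion, which on a single slice reduces to an area
proportion.

**Body composition** (`segment_pectoralis`, `muscle_metrics`,
`segment_subcutaneous_fat`, `fat_attenuation`).  The T3-level slice is
a required user choice; no vertebral-level detection is attempted.  The
slice is thresholded by the skeletal-muscle window, default
`[-29, 150]` HU — the source method cites a threshold method without
printing numbers, so the field's conventional window is the default and
it stays configurable.  The connected component containing the
user-supplied mediastinum seed (one mouse click in the original
workflow) is removed; remaining components form the pectoralis mask.
Muscle area is `pixels × row_spacing × col_spacing / 100` cm²; mean
attenuation is the plain mask mean.  Subcutaneous fat is the body-mask
pixels inside `[-120, -60]` HU that belong neither to interior lung
components nor to muscle-window components; on real images this
window-plus-exclusion rule only approximates "subcutaneous", a
documented limitation.  All connected-component operations use
4-connectivity in-plane (face connectivity across slices), frozen.

## Cohort construction

`derive_fields` adds BMI (`weight / height²`) and survival time
(`fup_days − candx_days`, days from diagnosis to death or last known
alive).  `apply_exclusions` reproduces the cohort flow: keep
screen-detected cancers; survivors are subjects alive at trial end;
nonsurvivors are lung-cancer-related deaths only (deaths from unrelated
causes and indeterminate-status subjects are excluded and counted);
subjects missing stage are excluded with their own log line (the
package-wide policy: missing values propagate and each stage declares
its own exclusions, keeping the audit trail in one place); stage IV is
dropped from both groups.

`nsm_match` implements the six-criterion matching.  Four criteria are
continuous — age, BMI, pack-years, survival time — and enter a
normalised Euclidean distance
`d(i,j) = sqrt(Σ_c (x_ic − x_jc)² / var_c)` with variances pooled over
all eligible subjects of both groups (frozen; this makes distances
invariant to affine rescaling of any criterion).  The remaining two,
gender and stage, are exact-match criteria: the source names five
criteria but counts six, and treating stage as the sixth, enforced
exactly, is the only reading consistent with the reported per-stage
matched counts.  Within each (stage, gender) cell a global
minimum-total-distance 1:1 assignment is solved exactly (Jonker-
Volgenant shortest augmenting path, implemented in C++); "included all
possible matches" is read as *optimal* rather than greedy assignment,
with greedy available via `match_config(method = "greedy")` for
sensitivity analysis.  Each cell yields `min(cell sizes)` pairs, so
every possible match is used.  Inputs are pid-sorted before solving,
making the output invariant to row order with deterministic
tie-breaking.  `balance_check` reports standardized mean differences
(pooled-SD denominator) before and after matching.

## Models

`fit_logistic` (binomial GLM) and `fit_cox` (`survival::coxph`, Efron
tie handling — the source is silent on ties) fit the same covariate
set: muscle area, fat attenuation, emphysema fraction, CAC grade as
three indicators against "none", tumour stage, age, gender, height.
Both report `exp(coefficient)` ratios with Wald 95% intervals and a
likelihood-ratio model chi-square.  Two modelling choices deserve
explanation:

* **Stage coding.**  The published models report a chi-square on 10
  degrees of freedom.  With three CAC indicators fixed by the published
  coefficient table, ten terms are only reachable if stage enters as a
  *single ordinal term*; expanding stage to indicators gives eleven.
  The default is therefore ordinal stage
  (`analysis_spec(stage_coding = "ordinal")`), with indicator coding
  available as an option.
* **Emphysema scale.**  Emphysema enters as a fraction in `[0, 1]`, so
  its odds/hazard ratio is "per whole unit of LAA fraction" and is
  numerically large by construction — consistent with the magnitude of
  the published estimate.

`group_compare` uses the Welch unequal-variance t-test (the source
never names its test; Welch is the safer default), and
`stratified_analysis` repeats it within stage, smoking history
(dichotomised at 50 pack-years; exactly 50 falls in the "<=50" stratum,
only strictly greater values are ">50"), or COPD strata.  No
multiple-testing correction is applied, mirroring the source (α = 0.05
per test); this is a faithful reproduction, not an endorsement.

## The synthetic world

**Phantoms** (`make_phantom`) paint, on a default 160×160 grid at
0.8 mm pixels: an air background (-1000 HU), a body outline filled with
fat (clipped normal, mean -92.5, sd 4.4 HU), two pectoralis
compartments (57 HU), two lung fields (-850 HU) with a seeded random
subset of pixels at -980 HU sized to the target LAA fraction (default
0.13), a heart disk (35 HU) carrying plaques painted as small disks at
300-800 HU fully inside it, and a mediastinal soft-tissue bridge that
lies inside the muscle window but is verified 4-disjoint from the
pectoralis compartments, so seeded exclusion is genuinely exercised.
HU levels echo the descriptive scale of a screening cohort (muscle
~57 HU, fat ~-92.5 HU, LAA ~0.13).  Regions are disjoint by
construction (one label per pixel); truth is enumerated from the labels
and final image, never from the configuration.  No partial-volume blur
is applied, so pixel counts are exact oracles.  HU values are rounded
to integers before truth enumeration, matching 16-bit CT storage and
making file round-trips lossless.  Two deliberate departures from
realism: low-attenuation pixels are scattered rather than clustered
into bullae (exactness of the count is the point), and the phantom is a
scaled-down thorax, so its absolute muscle area (~6 cm²) is below the
30 cm² clinical scale — the closed-form area conversion is tested at
the clinical scale directly.  A green phantom test therefore
establishes operator correctness, not performance on real anatomy:
noise, partial volume, contact between muscle and mediastinum, and
non-uniform field offsets are all absent.

One numerical consequence of the -1024 HU scanner floor: a uniform
background offset below -24 HU saturates at the floor, so the planted
offset is no longer exactly recoverable (the estimated offset stops at
-24).  Threshold counts remain invariant regardless, because plaque
attenuation sits far above the 130 HU threshold; the equivariance suite
checks counts across offsets in [-50, +50] HU and exact offset recovery
only above the saturation point.

**Rosters** (`make_roster`) reproduce the published cohort flow
exactly: 373 survivors (stage I/II/III/IV = 296/40/22/4 plus 11 with
missing stage), 182 lung-cancer-related deaths with eligible strata
I/II/III = 49/19/65, 34 unrelated deaths, and 34 indeterminate-status
subjects reconciling the 623 screen-detected total.  The published
stage-IV nonsurvivor count (70) contradicts the published eligible
total (49+19+65+70 = 203 ≠ 182); the default carries 49 stage-IV
nonsurvivors so that both the 182 total and the printed I-III strata
hold exactly — the two quantities that drive the reproduced cohort
sizes.  Marginals: age 64 ± 5 y, height 1.7 ± 0.1 m, weight 80 ± 16 kg,
54:36 male:female, survivor follow-up 1660 ± 488 d (truncated to
405-2744), nonsurvivor time to death 894 ± 542 d (truncated to
14-2399).  Pack-years are not printed in the source; 56 ± 24 truncated
at the screening-eligibility floor of 30 is used, chosen once as
realistic for a screening population.  Optional per-subject biomarker
columns are drawn from the published group-conditional descriptive
marginals so the model stage can run on a roster alone.

**Survival data** (`make_survival_data`) draw exponential event times
with hazard `λ0·exp(Xβ)` — proportional hazards by construction, so
planted coefficients are true log hazard ratios.  Censoring is
independent exponential with rate `mean-hazard × r/(1−r)`, giving an
expected censored fraction `r`.

## Numerical conventions, frozen

* Strict inequalities: calcified pixels are `> 130 HU`; LAA voxels are
  `< -950 HU`.  Inclusive windows: muscle `[-29, 150]`, fat
  `[-120, -60]`.
* Circle/ellipse membership is by pixel centre with the boundary
  included; the same rule paints phantoms and evaluates ROIs, so counts
  agree exactly.
* Grade boundary: count equal to a cutpoint takes the higher grade.
* Cutpoint calibration requires all four grades in the reference and
  errors on tied counts across a grade boundary rather than guessing.
* Assignment ties resolve to the lowest column index over pid-sorted
  input; matching output is row-order invariant.
* Empty masks: muscle metrics return area 0 and a missing mean; fat
  attenuation returns missing with a warning; an empty lung mask is an
  error.
* Voxels are clipped to [-1024, 3071] HU at construction.

## Known limitations

* The DICOM support is a minimal explicit-VR little-endian single-frame
  reader/writer — sufficient for fixtures and simple series, not a
  general implementation (no sequences, no compressed syntaxes).
* Muscle mean attenuation near 57 HU is high for unenhanced CT; the
  window that produced the published value is unstated, so the window
  here is configurable and the default is the field convention.
* CAC is counted on a single slice; slab/volume counting is not
  implemented.
* The phantom validates operators, not reader agreement; the
  grade-agreement statistic is exercised on synthetic grade vectors.
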