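---
title: "Predicting the new baseline GFR after radical nephrectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the new baseline GFR after radical nephrectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalsplit)
```

## The model and its assumptions

After radical nephrectomy the remaining (contralateral) kidney carries the
patient's entire renal function. The package's central model predicts the
new baseline GFR (NBGFR, the stable value 3–12 months post-surgery) as

$$\widehat{NBGFR} = RFC \times GFR_{global} \times SRF_{contra},$$

where $GFR_{global}$ is the preoperative global eGFR, $SRF_{contra}$ is the
contralateral kidney's split renal function (its fraction of total
function), and $RFC$ is the renal functional compensation multiplier — the
hypertrophic gain of the remaining kidney. The model assumes (i) SRF is well
proxied by the kidney's share of total parenchymal volume, (ii) compensation
is multiplicative and roughly constant across patients, and (iii) the
preoperative global eGFR is accurate. `RFC` is a configuration constant, not
fitted: adult compensation reliably falls in 1.20–1.30, and the default is
1.25 (`run_config(rfc_multiplier = )`).

## Estimating split renal function

Three interchangeable SRF sources feed the model:

* **Software PVA** — a volume triplet per patient: contralateral
  parenchyma, ipsilateral parenchyma-plus-tumor, and tumor (cm³).
  `pva_parenchymal_volumes()` subtracts the tumor;
  `srf_from_volumes()` normalises the contralateral volume by the total.
* **LWH ellipsoid** — five linear measurements per kidney (one maximal
  coronal length, two anterior–posterior, two medial–lateral, all cm, the
  paired measurements taken at the polar line). `lwh_volume()` computes
  $0.52 \times L \times \overline{AP} \times \overline{ML}$; 0.52
  approximates $\pi/6$ for an ellipsoid.
* **Nuclear renal scan** — the reported SRF fraction is consumed directly
  (`srf_nrs` column); no renogram physics is modelled.

Laterality is handled surgically (contralateral = preserved kidney,
ipsilateral = removed); left/right is metadata only. Whole-percent display
(`srf_percent_display()`) rounds half away from zero and defines the
complement by subtraction so the pair always totals 100 % — chosen because a
52.5 % volume share must display as 53 %/47 %, which round-half-even would
not produce.

`ckd_epi_egfr()` provides both CKD-EPI creatinine equations behind a
switch. Stored eGFR values in historical cohorts may have been computed with
either vintage; the package defaults to the 2021 race-free refit for
consistency with current practice, and keeps the 2009 form (which then
requires an explicit race covariate — a missing value is a hard error, never
a silent non-Black default) for historical replication. An explicit
`egfr_pre_global` column always wins over creatinine, with a warning when
both are present.

## The evaluation suite

For each SRF method, predicted NBGFR is scored against the observed value
with:

* **Pearson r** between predicted and observed;
* **bias** — the *median* residual (observed − predicted), robust to the
  skew of GFR;
* **precision** — the interquartile range of the residuals. Quantiles use
  linear interpolation between order statistics (R's default type 7); no
  other rule is used anywhere in the package;
* **MSE** — $\frac1n\sum_i (Y_i - Y^*_i)^2$;
* **P30 accuracy** — the percentage of predictions within ±30 % of the
  observed value, boundary inclusive ($|pred-obs| \le 0.30\,obs$);
* **AUC** — discrimination of observed NBGFR > 45 mL/min/1.73 m² using the
  predicted NBGFR as score, computed from the Mann–Whitney rank statistic
  with midrank ties. Following the clinical design, the ROC analysis is
  restricted to patients whose preoperative global GFR already exceeds
  45 (strict inequalities on both thresholds): patients below it can rarely
  reach the postoperative target, and keeping them would inflate apparent
  discrimination.

Patients missing a method's inputs are dropped for that method only, with
logged counts — never imputed.

### Bootstrap inference

Confidence intervals and method comparisons use the nonparametric bootstrap
over patients, 1000 resamples by default. Comparisons are *paired*: the same
resampled patients are scored under both methods, respecting the
within-patient correlation of the two predictions. The two-sided p-value is
the doubled tail of the bootstrap difference distribution with an add-one
correction,

$$p = \min\!\Big(1,\; \frac{2\min(\#\{d \le 0\}+1,\ \#\{d \ge 0\}+1)}{B+1}\Big),$$

which keeps $p$ strictly positive at any $B$. CIs are percentile intervals
from the same resamples — the simplest defensible choice, adequate at
$B = 1000$ for the effect sizes involved. Resamples on which a statistic is
undefined (a single-class AUC resample, a zero-variance correlation) are
dropped and counted, not silently imputed. Every stochastic step requires an
explicit seed; there is deliberately no timestamp fallback, so a fixed
configuration reproduces its report byte for byte.

## The synthetic cohort generator

`generate_cohort()` emulates the functional structure of a contemporary
renal-cancer RN cohort so the whole pipeline is testable without patient
data:

| quantity | distribution | default |
|---|---|---|
| global eGFR $G$ | lognormal | median 70, sdlog 0.318 (IQR ≈ 56–86) |
| true contralateral SRF | normal, truncated to (0.05, 0.95) | mean 0.557, sd 0.04 |
| compensation RFC | normal, truncated to (0.5, 2.5) | mean 1.26, sd 0.22 (IQR ≈ 1.01–1.41) |
| observed NBGFR | $G \cdot SRF \cdot RFC \cdot$ lognormal noise | sdlog 0.08 |
| per-method SRF | truth + Gaussian noise, clipped to (0.01, 0.99) | sd 0.02 (PVA), 0.11 (NRS, LWH) |

The lognormal/truncated-normal families were chosen as the minimal-parameter
shapes matching the skewed median/IQR structure of such cohorts. Volumetric
columns are *back-solved*: software volumes and LWH measurement sets are
constructed so that the volume pipeline reproduces each method's noisy SRF
exactly (LWH sets by isotropic scaling of an 11 × 4.2 × 4.1 cm template
kidney), with total parenchymal volume near 324 cm³ (software) and 200 cm³
(LWH) and a wide lognormal tumor-volume distribution (median 104 cm³, sdlog
1.4). The truth table (true SRF and RFC per patient) is written separately
from the cohort CSV so analysis code cannot accidentally consume oracle
columns.

**Noise calibration.** The per-method SRF noise sds are the generator's only
calibrated knobs: they were set, once, so that at $n = 235$ the simulated
Pearson r of predicted vs observed NBGFR reproduces the reported performance
pattern of the three methods — about 0.85 for software PVA and about 0.72
for NRS and LWH, with PVA's MSE roughly half the others'. With PVA noise at
0.02 SRF units, that pattern requires NRS/LWH noise near 0.11; smaller
values (e.g. 0.055) leave the NRS correlation near 0.82 and compress the gap
below what distinguishes the methods in practice. Tests assert the
*ordering and gap* of the methods across replicates, never exact metric
values, which depend on the seed.

**What the generator does not emulate.** Components are independent across
blocks: no correlation between tumor size and ipsilateral function loss, no
demographics–disease structure, no CKD progression, and the SRF errors of
the three methods are mutually independent given the truth (real NRS and
LWH errors may correlate). Passing tests therefore show the pipeline is
correct and well calibrated under the assumed generative model — not that
any method achieves a particular accuracy on real patients.

## Numerical conventions and degenerate inputs

* eGFR and SRF are carried at full floating precision; rounding
  (whole-percent SRF, 1-decimal volumes) is presentation-only.
* Inclusion requires preoperative global eGFR strictly > 15 and an observed
  NBGFR; the thresholds 45 (ROC label and subset) are likewise strict.
* A tumor volume exceeding the ipsilateral total, a non-positive LWH
  measurement, an SRF outside (0, 1), or a zero-variance correlation input
  is an error, not a warning; a kidney length shorter than its thickness is
  a warning (anatomically implausible but computable).
* Truncated normals are drawn by rejection (exact; the truncation mass is
  tiny at the defaults). Clipping of noisy SRF to (0.01, 0.99) keeps
  back-solved volumes positive.
* Malformed cohort CSV rows are rejected with line numbers and collected in
  an attribute; they are never silently dropped.

## Problem sizes in the test suite

The packaged checks use 200 replicate cohorts of $n = 235$ for the
method-ordering property, 500 replicates with 1000 bootstrap resamples for
the null calibration of the paired test (rejection rate at the 0.05 level
expected in roughly 2–9 %), 100 random cohorts of $n \le 50$ for
metric-vs-oracle equivalence at $10^{-9}$, and $10^4$ patients for the
lognormal-median check — sizes chosen to make the stochastic assertions
stable at the default seeds while keeping the suite quick.

## Known limitations

* Only the creatinine CKD-EPI equations are provided (no MDRD,
  Cockcroft–Gault, cystatin C, pediatric, or measured GFR).
* SRF-from-volume assumes function is proportional to parenchymal volume;
  differential parenchymal *quality* (scarring, obstruction) is invisible.
* The RFC multiplier is a constant; real compensation varies with age and
  baseline function, which the model absorbs into residual error.
* Which CKD-EPI vintage produced a given historical cohort's stored eGFRs
  is usually unknowable; both are provided, neither is asserted to match
  any particular dataset.
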