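---
title: "Projected secondary-cancer risk from DVHs: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projected secondary-cancer risk from DVHs: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oedrisk)
```

## The problem and the model

Long-term survivors of early breast cancer face a small but real risk of
radiation-induced secondary malignancies (RISM) in organs that receive
incidental dose during radiotherapy: the contralateral breast, the lungs,
the thyroid and the esophagus. Comparing treatment techniques — partial
breast irradiation (PBI) at an MR-guided linac versus PBI or whole breast
irradiation (WBI) at a conventional linac with daily cone-beam CT (CBCT)
image guidance — requires a dose metric that reflects carcinogenesis, not
just physical dose.

The organ equivalent dose (OED) framework provides that metric. Cancer
induction is taken to be linear in dose at low doses, while at
radiotherapy-level doses cell sterilization removes the very cells that
would have been transformed. The risk-equivalent dose (RED) kernel encodes
this: the default *linear-exponential* form is

$$\mathrm{RED}(D) = D\,e^{-\alpha D},$$

with an organ-specific cell sterilization parameter $\alpha$ (per Gy). A
purely linear kernel ($\mathrm{RED}(D)=D$) is the low-dose limit, and a
saturating *plateau* kernel $(1-e^{-\delta D})/\delta$ is shipped for
sensitivity analyses but disabled by default, since all default projections
use the linear-exponential form. Because an organ's dose is non-uniform,
the OED averages the kernel over the dose-volume histogram (DVH):

$$\mathrm{OED} = \frac{1}{V_T}\sum_i v_i\,\mathrm{RED}(D_i),$$

where bin $i$ holds volume $v_i$ at dose $D_i$ and $V_T$ is the organ
volume. The OED is the uniform dose with the same projected incidence as
the actual distribution; it is never larger than the mean dose for
$\alpha>0$. The projected excess absolute risk is then linear in the OED,

$$\mathrm{EAR} = \mu \cdot \mathrm{OED},$$

in cases per 10,000 person-years, so an EAR of 1 corresponds to one
additional cancer per 1000 treated patients over 10 years
(`excess_cases()`).

The shipped coefficients are literature values: $\alpha$ = 0.129 (lung),
0.033 (thyroid), 0.274 (esophagus) and 0.25 (breast; a site-specific
estimate rather than a tabulated constant), and $\mu$ = 9.47 (lung), 0.86
(thyroid), 1.9 (esophagus), 2.49 (breast) EAR per Gy of OED. The three
lung structures (both / ipsilateral / contralateral) share the lung
$\alpha$ and $\mu$ and are reported separately, matching the reference
analysis. No age-at-exposure or attained-age modification is applied: the
projections are deliberately *projected* risks with fixed coefficients,
comparable between techniques for the same organ, not absolute clinical
predictions.

## DVH conventions

DVHs enter as plain text (`read_dvh()`), cumulative or differential,
absolute (cm³) or relative (%). All integration happens on the
differential form with half-open bins $[e_i, e_{i+1})$ evaluated at bin
centers — the standard planning-system export semantics — so the OED is a
simple weighted sum. Choices worth knowing:

* **Default bin width 0.1 Gy.** The export granularity of the source
  plans is unknown; a grid-refinement test in the suite shows the OED of a
  smooth DVH moves by less than 0.5% between 0.1 and 0.01 Gy grids, so the
  default is comfortably converged.
* **Relative volumes require an explicit total.** A `%`-valued block
  without a `volume_cm3` header is an error, never a silent 100 cm³
  assumption.
* **Maximum dose** is the upper edge of the highest bin holding more than
  a numerical-zero volume (1e-9 cm³); the reference reports Dmax without a
  volume criterion, so the floor exists only to ignore floating-point
  dust.
* **Validation is strict.** Non-monotone cumulative curves, negative
  volumes, unknown group labels and inconsistent lung volumes (both-lungs
  differing from ipsilateral + contralateral by more than 1%) are hard
  errors naming the offending line or patient.

## Image-guidance dose as a uniform organ shift

Daily CBCT at the conventional linac adds dose that an MR-guided workflow
avoids. The reference analysis derived per-organ mean-dose increments from
Monte-Carlo simulation of the imaging beam; only those organ-level means
are available, so this package applies the increment as a **uniform shift
of the organ's DVH** (`apply_uniform_dose()`): volumes are untouched and
every dose coordinate moves by the increment. This reproduces the organ
mean dose exactly — the shipped 15-scan PBI protocol raises the mean dose
by 0.55 / 0.52 / 0.66 / 0.36 / 0.51 / 0.45 Gy for contralateral breast,
both lungs, ipsilateral lung, contralateral lung, thyroid and esophagus,
about half a Gray everywhere — while ignoring the spatial heterogeneity of
a ≤ 0.7 Gy component, a second-order effect on the OED. This is the
module's central approximation, and whether the reference summed voxel
doses before re-histogramming is unknown; only the uniform-shift contract
is promised. Per-scan dose is the reference total divided by the reference
scan count (15 for the PBI protocol, 6 for the WBI protocol; the two
tables are independent because the imaged anatomy differs), making the
shift exactly additive in the scan count. WBI patients receive no imaging
dose by default — their scan frequency was patient-adapted in the
reference cohort — with the 6-scan protocol available as a sensitivity
mode. Planning-CT dose is excluded throughout, as it is identical across
techniques.

## Cohort comparison

Per organ, groups are compared with the **Welch (unequal-variance)
two-sided t-test**, from raw samples or directly from printed mean/SD/n
summaries (`welch_from_summary()` — the two routes agree to machine
precision by construction). The Welch variant, rather than the pooled
test, is a deliberate reverse-engineering decision: recomputing the
reference comparison columns from their printed summaries matches the
small adjusted values (e.g. the esophagus CBCT-vs-MRL cell of 0.002) only
under Welch, while the large cells (1.737, 3.96) match either variant.

Multiplicity is handled per organ across the four group pairs with an
**uncapped Bonferroni** multiplier: adjusted $= m \times p_{\text{raw}}$
with $m = 4$, deliberately *not* truncated at 1, because the reference
table prints adjusted values such as 1.737 and 3.96 — only consistent with
an uncapped ×4. `stats::p.adjust()` caps at 1 and is therefore not used.
No correction is applied across organs (the reference corrects within
organ only). Significance is called at adjusted < 0.05. A Shapiro-Wilk
screen is attached per organ × group as advisory information; it never
gates the t-test because the reference workflow reports no non-parametric
fallback. Zero-variance samples raise errors rather than silently
continuing. Auxiliary comparisons (target-volume sizes, contralateral
breast Dmax) use the same machinery with a configurable multiplier
(`auxiliary_compare()`, $m = 1$ for the single PTV comparison; the Dmax
family is plausibly $m = 3$ but the reference leaves the family unstated,
so the multiplier is an argument, not a constant).

## The synthetic cohort generator

Patient-level DVHs of the reference cohort are not published, so the
package ships a seeded generator (`generate_cohort()`) that emulates the
*statistical structure* the analysis needs: three groups of 11 patients,
prescription 40.05 Gy in 15 fractions, six organs per patient. Each organ
× group has a two-component dose mixture (`organ_dose_profile()`):

* a **near-field** fraction `p_high` of the organ volume with
  normally-distributed doses (`high_mean`, `high_sd`) — tissue near the
  target; this component exists for the contralateral breast and the
  ipsilateral lung;
* an exponential **low-dose bath** (`bath_scale`) for the remainder —
  scatter and leakage. Where a near-field component exists, bath doses are
  capped at its mean, so the maximum dose is governed by the near field.

The two-component family is the simplest able to hit both the group mean
EARs and the contralateral-breast maximum-dose means simultaneously (OAR
DVHs in breast radiotherapy are bimodal in practice). Organ volumes are
truncated normals (breast 600 ± 120, each lung 1400 ± 250, thyroid
18 ± 5, esophagus 35 ± 8 cm³, all ≥ 10 cm³ — typical adult anatomy); the
both-lungs DVH is the bin-wise union of the two lung DVHs, so volume
bookkeeping and the OED mixture property hold exactly. Doses are capped
at 110% of prescription. Each DVH is histogrammed from 2000 equal-volume
voxel samples at 0.1 Gy — enough that sampling noise on a group mean EAR
is far below inter-patient spread, while keeping a full cohort below a
quarter second.

Inter-patient heterogeneity is one standard-normal draw per patient that
scales `p_high` and `bath_scale` through a mean-one lognormal multiplier
with organ-specific log-sd, so a "large-anatomy" patient is hot in all
organs at once — the within-patient correlation real anatomy induces —
while each organ keeps its own observed coefficient of variation.
Randomness uses L'Ecuyer-CMRG streams split per patient from the master
seed, so results are bit-reproducible and independent of generation
order, and the caller's RNG state is left untouched.

**Calibration.** `calibrate_profiles()` tunes profiles to target group
summaries by damped multiplicative coordinate updates: mean-EAR ratios
steer `p_high` and `bath_scale`, coefficient-of-variation ratios steer
the heterogeneity log-sd, and mean-Dmax ratios steer the near-field
location. Iterations reuse one fixed set of random streams (common random
numbers), so the search is deterministic and does not chase simulation
noise; a candidate meeting all tolerances is confirmed on an independent
validation seed before acceptance. Tolerances are ±10% on means, ±30% on
SDs and ±20% on mean Dmax — means first, SDs looser because 11-patient SD
estimates are themselves noisy. The shipped `default_profiles()` are the
frozen result of calibrating against the reference EAR summaries and
contralateral-breast Dmax means; the calibration converges in a handful
of iterations and the suite re-verifies the targets against fresh seeds.

**What the generator does not emulate.** DVH *shapes* beyond the
calibrated summaries (no beam geometry, no anatomical correlation between
neighbouring organs beyond the shared multiplier, no inter-organ dose
gradients), per-patient values of the reference cohort, and any
systematic difference in organ volumes between groups. Passing tests
therefore demonstrate that the *pipeline* — I/O, dose response, imaging
dose, statistics — reproduces the reference results given data with the
reference's summary structure; they are not evidence about any individual
patient's DVH.

**Statistical power of the pattern.** With 11 patients per group, the
reference's own effect sizes give the significance pattern of the
PBI-comparison column (breast lower at the MR-linac, thyroid higher,
lungs indistinguishable, at Bonferroni-adjusted 0.05) limited
replication probability: cohorts drawn with exactly the reference group
means and SDs reproduce the full joint pattern in well under half of
replicates, and the shipped generator behaves accordingly (the
acceptance script measures the rate, typically 0.4–0.5 across 200
seeded replicates). This is a property of small-sample inference, not a
defect of the generator; individual components (e.g. the breast call)
reproduce far more often than the joint pattern.

## Numerical choices and degenerate inputs

* Bin-center integration everywhere; converting representations, rebinning
  (overlap-proportional volume splitting) and uniform shifts conserve
  volume to 1e-6 relative or better, exactly where algebraically possible.
* All-zero-volume DVHs, zero total volume, negative doses/volumes and
  empty groups are errors, never silent zeros.
* Ties / zero variance in a comparison raise; Shapiro needs n ≥ 3 and
  positive variance.
* Output files round at write time only (6 decimals in machine tables;
  report p-values at 2–4 significant digits with `<0.0001` below
  resolution); internal computation is never rounded.
* Test problem sizes are chosen to exercise the claims at desk scale: the
  voxel-sampling Monte-Carlo oracle uses 10⁵–10⁶ draws per DVH, the
  permutation oracle 10⁵ resamples, and the distributional cohort checks
  200 seeded replicates.

## Limitations

* Risk coefficients and sterilization parameters carry large literature
  uncertainties; EARs are comparative projections between techniques for
  the same organ, not absolute predictions.
* The uniform-shift imaging model cannot capture intra-organ heterogeneity
  of the CBCT dose.
* No DICOM import (declared extension point), no 3D dose computation, no
  ERR (relative-risk) models, no latency or age modification.
* The generator's per-patient realism is limited to calibrated group
  summaries; analyses of DVH shape on synthetic cohorts would be circular.
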