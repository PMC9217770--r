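# oedrisk

Projected radiation-induced secondary-malignancy risk from dose-volume
histograms (DVHs), for comparing breast radiotherapy techniques.

After breast-conserving surgery, radiotherapy exposes the contralateral
breast, lungs, thyroid and esophagus to incidental dose. `oedrisk`
implements the organ-equivalent-dose (OED) framework to turn per-organ
DVHs into projected excess absolute risks (EARs) and compares treatment
cohorts — partial breast irradiation (PBI) at an MR-guided linac, PBI at a
conventional linac with daily cone-beam CT (CBCT), and whole breast
irradiation (WBI) — the way a medical-physics plan-comparison study does.
It is aimed at medical physicists and biostatisticians who have
planning-system DVH exports (or want a calibrated synthetic stand-in) and
need reproducible risk projections and group statistics.

## The model

The risk-equivalent dose kernel suppresses linear cancer induction by cell
killing at therapeutic doses,

    RED(D) = D · exp(−α·D)

with organ-specific sterilization parameter α (per Gy). The OED averages
the kernel over the DVH,

    OED = (1/V_T) Σ_i v_i · RED(D_i)

(bin volumes v_i at bin-center doses D_i), and the projected risk is

    EAR = µ · OED

in cases per 10,000 person-years (EAR = 1 ⇔ one excess cancer per 1000
patients over 10 years). Shipped coefficients: α = 0.129 / 0.033 / 0.274 /
0.25 and µ = 9.47 / 0.86 / 1.9 / 2.49 for lung / thyroid / esophagus /
breast. CBCT image-guidance dose is added as a uniform organ-dose shift
from per-protocol mean-dose increments (15-scan PBI protocol ≈ 0.5 Gy per
organ). Cohorts are compared per organ with Welch two-sided t-tests and
uncapped ×4 Bonferroni adjustment (adjusted values above 1 are reported
as-is), flagged at adjusted p < 0.05.

Because the underlying patient DVHs of the reference cohort are not
public, the package includes a seeded synthetic cohort generator
(two-component near-field + scatter-bath dose mixtures, lognormal
inter-patient heterogeneity) calibrated so that group mean ± SD EARs and
contralateral-breast maximum doses match the published summaries.

## Worked example

```r
library(oedrisk)

# a synthetic 33-patient cohort (3 groups x 11 patients, 6 organs each)
recs <- generate_cohort(cohort_config(seed = 1))
patient_risk_profile(recs[[1]])
#>                  organ   oed    ear
#> 1 breast_contralateral 0.318  0.792
#> 2           lungs_both 0.712  6.742
#> 3     lung_ipsilateral 1.110 10.515
#> 4   lung_contralateral 0.295  2.790
#> 5              thyroid 0.333  0.286
#> 6            esophagus 0.389  0.738
```

OED is in Gy; EAR per 10,000 person-years — this patient's ipsilateral
lung projects ~10.5 extra cancers per 10,000 person-years, the dominant
organ, as expected from its proximity to the target.

```r
# add the daily-CBCT dose for conventional-linac PBI and compare groups
dosed <- lapply(Filter(function(p) p$group == "PBI_CTL", recs),
                with_imaging_dose,
                protocol = imaging_protocols()$PBI_CTL, n_cbct = 15)
ear <- cohort_ear_table(c(recs, dosed))
build_comparison_table(ear)
#> organ                  PBI_CTL M+/-SD   PBI_MRL M+/-SD   ... PBI_CTL vs PBI_MRL ...
#> breast_contralateral   1.467 +/- 0.298  0.936 +/- 0.288      0.00156 *
#> lungs_both             8.858 +/- 1.566  7.790 +/- 2.476      0.974
#> lung_ipsilateral       12.921 +/- 1.539 12.318 +/- 3.921     2.57
#> lung_contralateral     4.907 +/- 1.238  3.524 +/- 1.187      0.0583
#> thyroid                0.197 +/- 0.108  0.366 +/- 0.146      0.0251 *
#> esophagus              0.836 +/- 0.166  0.920 +/- 0.317      1.78
```

Columns are group mean ± SD EARs and Bonferroni-adjusted (uncapped, ×4)
Welch p-values; `*` marks adjusted p < 0.05. In this seed the
contralateral breast is significantly lower and the thyroid significantly
higher at the MR-linac, with no lung difference — the qualitative picture
the technique comparison is about. `run_pipeline(run_config(...))` wraps
the same flow with CSV artifacts and a run log; `inst/cli/oedrisk.R`
exposes `simulate` / `compute` / `compare` / `report` / `run` subcommands
for shell use.

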