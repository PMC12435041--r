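# romtraj

Trajectory analysis of active range of motion (ROM) after anatomic (aTSA)
and reverse (rTSA) total shoulder arthroplasty, for clinical-outcomes
researchers working with long-format visit data. The package quantifies how
fast patients recover motion, how fast they lose it again at long-term
follow-up, classifies each patient as fast / average / slow on both ends,
and screens patient, operative and radiographic factors for association with
slow recovery or fast decline. A synthetic longitudinal cohort generator
with the same statistical structure makes the whole pipeline testable
without patient data.

## The statistics at its core

For each ROM measure *m* (abduction, forward elevation, external rotation in
degrees; internal rotation as the ordinal 0–6 IR score), with months since
surgery *t*:

- **Rate of improvement (ROI)**, per recovery-window visit (0–24 months):
  `ROI(t) = (y(t) − y(0)) / t` in units per month.
- **Peak improvement**: the highest value of *m* among visits 2–3 years
  after surgery (closed window [24, 36]; ties take the earliest visit).
- **Rate of decline (ROD)**, per long-term visit (96+ months), relative to
  the peak: `ROD(t) = (y_peak − y(t)) / (t − t_peak)`, stored
  decline-positive.
- **Classification**: cohort-average rates are computed per prosthesis ×
  measure × follow-up interval; each of a patient's rates casts one vote,
  exceeding when strictly above the cohort mean. Exceedance fraction
  > 2/3 → FAST, < 1/3 → SLOW, otherwise AVERAGE; fewer than 4 usable votes →
  UNCLASSIFIED.
- **Risk screen**: Welch t-tests (continuous) and exact hypergeometric
  Fisher tests (binary) contrast the extreme class against the pooled rest;
  univariate-significant factors (p < 0.05) enter one multivariate logistic
  regression (IRLS), reported as odds ratios with Wald 95% CIs,
  `OR = exp(β)`, `CI = exp(β ± 1.96·se)`.

## Worked example

```r
library(romtraj)

cohort <- simulate_cohort(simulation_config(n_atsa = 200, n_rtsa = 200,
                                            seed = 20260919))
roi    <- compute_roi_records(cohort)
labels <- classify_cohort(cohort, roi, "ROI")
table(labels$prosthesis, labels$label)
#>        AVERAGE FAST SLOW
#>   aTSA      89   59   52
#>   rTSA      89   61   50
```

Why are the slow improvers slow? They started with far more motion:

```r
summarize_groups(cohort, labels, "preop", measures = "abduction")
#> # A tibble: 6 × 9
#>   prosthesis label   measure       n  mean    sd ... p_fast_vs_slow
#> 1 aTSA       AVERAGE abduction    89  84.6  24.6           2.39e-13
#> 2 aTSA       FAST    abduction    59  67.0  24.1           2.39e-13
#> 3 aTSA       SLOW    abduction    52 105.   23.2           2.39e-13
#> 4 rTSA       AVERAGE abduction    89  66.9  28.2           1.27e-13
#> 5 rTSA       FAST    abduction    61  52.7  27.8           1.27e-13
#> 6 rTSA       SLOW    abduction    50  97.4  27.3           1.27e-13
```

SLOW-ROI patients begin with ~35–45° more abduction than FAST-ROI patients
(Welch p ≈ 10⁻¹³): high preoperative motion leaves little room to improve,
and such patients typically dip during the first three months before
recovering. The same machinery summarises decline: feeding it the published
full-cohort means for anatomic prostheses (peak improvement at 2–3 years vs
latest 8+-year follow-up),

```r
decline_from_peak(
  c(abduction = 131.9, forward_elevation = 150.5,
    external_rotation = 53.3, ir_score = 5.4),
  c(abduction = 115.8, forward_elevation = 138.2,
    external_rotation = 43.8, ir_score = 4.5))
#> # A tibble: 4 × 5
#>   measure           peak_mean latest_mean decline_raw decline
#> 1 abduction             132.        116.         16.1      16
#> 2 forward_elevation     150.        138.         12.3      12
#> 3 external_rotation      53.3        43.8         9.5      10
#> 4 ir_score                5.4         4.5         0.9       1
```

a long-term anatomic cohort loses on average 16° of abduction, 12° of
forward elevation, 10° of external rotation and 1 IR-score point from its
2–3-year peak.

## The analysis workflow

The `analysis/` directory holds the pipeline as numbered, narrative
driver scripts over the package functions; each writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # 200 + 200 patient synthetic cohort
Rscript analysis/02_rates.R      # ROI records, 2-3 yr peaks, ROD records
Rscript analysis/03_classify.R   # fast/average/slow voting classification
Rscript analysis/04_screen.R     # per-prosthesis risk-factor screens
Rscript analysis/05_report.R     # cohort tables + decline summary
```

`run_pipeline(pipeline_config(...))` executes the same stages in one call
(with a deterministic run log); `read_cohort()`/`write_cohort()` accept any
data conforming to the documented `patients.csv`/`visits.csv` schema, so the
workflow runs unchanged on real exports.

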