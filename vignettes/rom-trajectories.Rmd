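---
title: "Recovery and decline trajectories of shoulder arthroplasty range of motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovery and decline trajectories of shoulder arthroplasty range of motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(romtraj)
```

## The problem

After anatomic (aTSA) or reverse (rTSA) total shoulder arthroplasty, active
range of motion (ROM) typically improves rapidly over the first months,
peaks around 2–3 years, and then drifts slowly downward over long-term
follow-up. Patients differ on both ends: some improve slowly during recovery
(often those who started with a lot of motion, who may even *lose* motion in
the first three months), and some decline quickly after their peak (often
driven by systemic illness, implant fixation problems, or revision surgery).

`romtraj` implements a complete analysis pipeline for this setting:

1. per-visit **rate of improvement (ROI)** over the recovery window,
2. **peak** extraction in the 2–3-year window and per-visit **rate of
   decline (ROD)** at long-term follow-up,
3. a deterministic **fast / average / slow voting classification** against
   prosthesis-specific cohort baselines, and
4. a **univariate → multivariate logistic risk-factor screen** contrasting
   the extreme classes.

Because per-patient clinical data of this kind are not publicly deposited,
the package ships a synthetic longitudinal cohort generator that reproduces
the statistical structure the analysis assumes, so every stage is testable
end to end.

## Rate definitions and time windows

All times are months since surgery; the preoperative visit sits at $t = 0$.

* **ROI** for measure $m$ at a recovery visit at time $t$:
  $\mathrm{ROI}(t) = (y_m(t) - y_m(0)) / t$, in degrees (or IR-score points)
  per month. Recovery visits are those with $0 < t < 24$ by default.
* **Peak**: the highest observed value of each measure among visits in the
  closed window $[24, 36]$ months ("2–3 years", read inclusively). Ties take
  the *earliest* visit, which makes the decline denominator conservative.
* **ROD** at a long-term visit ($t \ge 96$ by default):
  $\mathrm{ROD}(t) = (y^{peak}_m - y_m(t)) / (t - t^{peak})$, stored
  *decline-positive*, so faster decline means a larger ROD. The denominator
  is time since the **peak visit**, because the decline is defined relative
  to the peak; dividing by time since surgery instead is available via
  `compute_rod_records(..., time_base = "surgery")`. Long-term visits at or
  before the peak time are excluded and counted in the skip log.

Recovery visits are binned into nominal follow-up intervals for baseline
averaging: 3 → (0, 4.5), 6 → [4.5, 9), 12 → [9, 18), 24 → [18, 30) months.
Edges sit at midpoints between scheduled visits. The last bin extends to 30
months so that a jittered "2-year" visit still has a bin *if* the user
widens the recovery window; with the default window, ROI records stop at 24
months and the tail of that bin is simply unused. Patients whose measure has
no preoperative value contribute no ROI record (skipped and logged), and
patients with no visit in the peak window are excluded from ROD for that
measure — mirroring the fact that not every patient has enough follow-up to
be classified.

## The voting classifier

Cohort baselines are arithmetic mean rates per (prosthesis, measure,
interval bin) for ROI and per (prosthesis, measure) for ROD, computed over
*all* records — a patient's own records are not held out, matching the
simple cohort-average procedure the analysis reproduces.

Each of a patient's rate records casts one vote against its matching
baseline cell; the vote "exceeds" when the rate is **strictly** greater than
the cell mean (a rate exactly at the mean has not exceeded it). With
exceedance fraction $f$:

* $f > 2/3$ → FAST, $f < 1/3$ → SLOW, otherwise AVERAGE (both inequalities
  strict, so exactly two-thirds is AVERAGE);
* fewer than `min_votes = 4` matched votes → UNCLASSIFIED (about one vote
  per measure; patients with almost no usable visits should not be forced
  into a class).

For ROD the same rule applies to decline-positive rates, so "exceeds" means
*declining faster* than the cohort and FAST ROD is fast decline.

One open choice is the vote unit: the default is one vote per (measure,
visit) record, which uses all the information and matches the per-visit
definition of the rates. A coarser alternative — one vote per measure, using
the patient's mean rate — is available via
`classifier_config(vote_unit = "per_measure_mean")`.

## The risk-factor screen

`run_screen()` contrasts SLOW-ROI patients against pooled fast/average ROI
(or FAST-ROD against slow/average ROD), separately per prosthesis:

* **Univariate stage**: Welch's two-tailed unpaired $t$-test for continuous
  factors and Fisher's exact test for binary factors. Welch is the default
  because equal variances between trajectory classes cannot be assumed; a
  pooled-variance switch exists (`two_sample_t_test(var_equal = TRUE)`). No
  multiple-testing adjustment is applied, by design: the screen reproduces
  the conventional $\alpha = 0.05$ per-factor workflow, and its output
  should be read accordingly.
* **Entry rule**: factors with univariate $p < 0.05$ enter one multivariate
  logistic regression. Binary factors with an empty cell in either class are
  completely separated — their maximum-likelihood odds ratio is infinite —
  so they are reported univariate-only (listed in the
  `"excluded_zero_cell"` attribute) rather than voiding the whole fit.
* **Multivariate stage**: logistic regression fitted by iteratively
  reweighted least squares (the engine in `stats::glm.fit()`), convergence
  declared on the relative deviance change falling below `tol = 1e-8` within
  100 iterations, covariance from the inverse observed information. Odds
  ratios are $e^\beta$ with **Wald** 95% intervals
  $e^{\beta \pm 1.96\,\mathrm{se}}$ — the interval form whose behaviour near
  sparse cells (very wide, asymmetric CIs) matches what such cohort tables
  report. Any remaining coefficient with $|\beta| > 15$ is treated as
  quasi-separation: the fit is flagged non-converged and
  `wald_odds_ratios()` refuses to report intervals that would be
  meaningless.

### Numerical choices

* Fisher's exact $p$ is computed by full hypergeometric enumeration with
  `stats::dhyper()`: the sum of probabilities of all tables with the
  observed margins whose probability does not exceed the observed table's.
  Ties are accepted within a relative slack of $10^{-7}$ (the conventional
  tolerance, shared with `stats::fisher.test`), which makes exact ties
  robust to floating-point evaluation order; no continuity correction.
* Degenerate $t$-test input (both samples constant) returns $p = 1$ when the
  means agree — a factor identical across classes carries no evidence — and
  $p = 0$ when they differ.
* Reporting precision: angle summaries round **half-up** to the nearest
  degree and IR-score summaries to the nearest half point (base `round()`
  rounds half to even, which would turn a 9.5° decline into 9°).

## The synthetic cohort generator

Each patient's mean trajectory for each measure is

$$\mu(t) = P - (P - R_0)\,e^{-t/\tau}
  \;-\; D\,\tfrac{t}{\tau_d}\,e^{\,1 - t/\tau_d}
  \;-\; s\,\max(0,\, t - t_{dec}),$$

with $R_0$ the preoperative value, $P$ the peak target, $\tau = 4$ months
the recovery time constant, and a gamma-shaped transient dip of depth
$D = c\,\max(0, R_0 - \theta)$ reaching its trough exactly at
$t = \tau_d = 3$ months. The late decline is linear with slope $s$ from
$t_{dec} = 36$ months. This six-parameter form reproduces the qualitative
features such cohorts show — saturating recovery, an early dip confined to
patients with high preoperative motion, similar peaks across classes, and a
slow late drift — with every parameter clinically interpretable.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| preop mean ± SD | per measure/prosthesis, e.g. abduction 84.8 ± 29.7° (aTSA), 72.6 ± 34.5° (rTSA) | full-cohort preoperative summaries typical of long-term aTSA/rTSA series |
| peak mean ± SD | e.g. abduction 131.9 ± 28.4° (aTSA), 121.1 ± 25.9° (rTSA) | full-cohort 2–3-year peak summaries |
| peak–preop correlation | 0.2 | peaks are similar across ROI classes despite very different starting points, so the link must be weak |
| preop cross-measure correlation | 0.6 | a stiff shoulder is stiff in every plane; class contrasts separate on *all* preoperative measures simultaneously, which independent draws cannot reproduce |
| dip coefficient $c$ | 0.75 (abduction, forward elevation), 0.25 (external rotation), 0.05 (IR score) | calibrated so patients above the threshold lose ~25–35° by 3 months, bracketing the reported ~28° declines for ≥120° starters |
| dip threshold $\theta$ | 90° (angles), 3 points (IR) | dips are reported only for high-preoperative-motion strata |
| decline slope $s$ | per patient, $\max(0, N(0.08, 0.05^2))$°/mo; IR 0.012 ± 0.008 pts/mo | ~6–9° loss from peak to 8+ years; the IR slope is rescaled because an angle-sized slope would drain a 0–6 ordinal scale in a few years |
| visit schedule | preop, 3, 6, 12, 24, 36, 60, 84, 96, 108, 120 mo; jitter SD 0.8 mo; missingness 0.15 | the visit lattice of a long-term follow-up program with realistic irregularity |
| noise SD | 5° (angles), 0.5 pts (IR, pre-rounding) | repeat-measurement variability of goniometry / ordinal scoring |

Values are clamped to the valid range ([0, 200]° for angles; integers 0–6
for IR after half-up rounding) **after** noise, so every simulated dataset
passes the same total validation as read-in data.

Planted covariate effects (`effect_spec()`) act through three channels:
`early_rate_multiplier` scales the recovery amplitude $P - R_0$ (defaults:
diabetes ×0.8 and injections ×0.85 after rTSA); `decline_slope_add` adds to
$s$ in degrees/month, rescaled per measure (defaults: heart disease +0.15
after aTSA, any comorbidity +0.05 after rTSA); and `class_probability`
multiplies the odds (base probability 0.2) of a latent slowed-recovery
modifier (recovery $\tau$ ×3, amplitude ×0.7) — a mechanism for planting
class-membership effects that are not mediated by a single curve parameter.
Revision is modelled structurally as a 30° (1.5 IR-point) step loss at a
uniformly drawn post-peak time, reflecting that revision is linked to fast
decline without a characterised trajectory shape. Effect magnitudes are
generator inputs for testing recovery of associations, not estimates.

### What the generator does and does not emulate

It emulates: preoperative and peak distributions per prosthesis, the early
dip for high-preoperative-ROM patients, saturating recovery, late linear
decline, covariate prevalences typical of these cohorts (with `cm_none`
derived so the comorbidity flags are internally consistent), visit jitter
and missingness, and revision. It does **not** emulate: composite clinical
scores (ASES, Constant, SAS, VAS, global function — the schema carries them
as opaque columns but the generator only produces the four ROM measures),
informative missingness or loss to follow-up correlated with outcome,
between-surgeon or between-site variability, measurement drift, or any fit
to real per-patient data (none are deposited). Passing tests therefore show
that the pipeline recovers structure *of this kind* at these sample sizes —
not that the generator's parameters describe any particular clinic's
patients.

## Validation experiments and problem sizes

The test-suite and acceptance script rerun the pipeline's claims from
scratch at sizes chosen to give stable Monte-Carlo estimates:

* decline-from-peak arithmetic on published full-cohort means (exact);
* voting rule against an independently coded brute-force rule on the
  exhaustive grid of up to 40 votes plus 200 randomized tallies;
* Fisher enumeration against `stats::fisher.test` on 500 random 2×2 tables
  with $N \le 40$, and the closed-form diagonal table $p = 1/3$;
* logistic IRLS against the closed-form 2×2 odds ratio (4.0 to $10^{-6}$);
* planted-effect recovery: a binary factor with true OR 2.2 for slow-ROI
  membership at $n = 600$ (exposure prevalence 0.20, baseline class rate
  0.25 — chosen by a power calculation to give ~95% power at
  $\alpha = 0.05$), detected with a multivariate OR inside (1.2, 4.0) in at
  least 80% of 50 replicates;
* null calibration over 100 label permutations: the $t$-test rejects at
  $5\% \pm 3\sigma$; Fisher's exact test is *conservative by construction*
  on discrete data, so it is bounded above by $5\% + 3\sigma$ rather than
  held to a two-sided band;
* dip realism on an 800-patient default cohort: mean 0→3-month abduction
  change in $[-40, -15]$° for ≥120° starters and positive for <60°
  starters;
* byte-identical reruns of the full pipeline on a 200-patient cohort.

## Known limitations

* The voting classifier's baseline includes each patient's own records; for
  very small cohorts this shrinks exceedance fractions toward 1/2.
* ROD requires a peak-window visit; cohorts with sparse mid-term follow-up
  lose patients from the decline analysis, exactly as the source procedure
  does.
* Wald intervals are poor near separation; the screen withholds them (zero
  cells, $|\beta| > 15$) rather than reporting numbers that would mislead.
* The screen performs complete-case analysis per factor and no imputation.
* The generator draws visit-level noise independently over time; real
  repeat measurements are autocorrelated, so real per-visit rates are
  noisier at short follow-up than simulated ones.
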