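#!/usr/bin/env Rscript

# Stage 1: generate the study cohort.
#
# Simulates 200 anatomic + 200 reverse total shoulder arthroplasty patients
# with a preoperative visit and jittered follow-up visits out to 10 years,
# using the default trajectory calibration (saturating recovery, early dip
# for high-preop patients, late linear decline, planted covariate effects).

library(romtraj)

seed <- 20260919
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_atsa = 200, n_rtsa = 200, seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, file.path(out, "patients.csv"), file.path(out, "visits.csv"))

print(cohort)
cat(sprintf("postoperative visits per patient (median): %.0f\n",
            median(table(cohort$visits$patient_id[!cohort$visits$is_preop])) /
              length(rom_measures())))
pre <- cohort$visits[cohort$visits$is_preop &
                       cohort$visits$measure == "abduction", ]
cat(sprintf("preoperative abduction: mean %.1f deg, %.0f%% of patients >= 120 deg\n",
            mean(pre$value), 100 * mean(pre$value >= 120)))
cat("wrote", file.path(out, "patients.csv"), "and visits.csv\n")
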