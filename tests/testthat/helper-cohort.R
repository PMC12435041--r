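# Small builders used across test files. Fixtures are always generated in
# code; nothing is read from disk.

blank_patient <- function(patient_id = "P1", prosthesis = "aTSA", ...) {
  p <- tibble::tibble(
    patient_id = patient_id, prosthesis = prosthesis, age_years = 65,
    sex = "F", bmi = 30,
    previous_surgery = FALSE, injections = FALSE,
    dx_osteoarthritis = TRUE, dx_osteonecrosis = FALSE,
    dx_rotator_cuff_tear = FALSE, dx_cuff_tear_arthropathy = FALSE,
    dx_rheumatoid_arthritis = FALSE,
    cm_none = TRUE, cm_hypertension = FALSE, cm_heart_disease = FALSE,
    cm_diabetes = FALSE, cm_tobacco = FALSE, cm_renal_failure = FALSE,
    humeral_rll = FALSE, glenoid_rll = FALSE, glenoid_rll_grade = 0,
    scapular_notching = FALSE, notching_grade = 0,
    complication = FALSE, revision = FALSE, revision_time_months = NA_real_
  )
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

visit_rows <- function(patient_id, measure, times, values) {
  tibble::tibble(
    patient_id = patient_id, time_months = times,
    is_preop = times == 0, measure = measure, value = values
  )
}

# A deterministic two-patient dataset with hand-checkable rates.
manual_cohort <- function() {
  patients <- dplyr::bind_rows(
    blank_patient("P1", "aTSA"),
    blank_patient("P2", "rTSA")
  )
  visits <- dplyr::bind_rows(
    visit_rows("P1", "abduction", c(0, 6, 12, 30, 110), c(90, 120, 90, 110, 100)),
    visit_rows("P1", "ir_score", c(0, 6), c(3, 5)),
    visit_rows("P2", "abduction", c(0, 3, 24, 36, 100), c(60, 80, 100, 105, 95)),
    # P2 forward elevation has no preoperative value -> ROI must skip it
    visit_rows("P2", "forward_elevation", c(6), c(100))
  )
  cohort_dataset(patients, visits)
}

# Independent re-statement of the voting rule, deliberately written as plain
# arithmetic so it cannot share code with the classifier.
brute_force_label <- function(n_votes, n_exceed, fast = 2 / 3, slow = 1 / 3,
                              min_votes = 4) {
  if (n_votes < min_votes) {
    "UNCLASSIFIED"
  } else if (n_exceed / n_votes > fast) {
    "FAST"
  } else if (n_exceed / n_votes < slow) {
    "SLOW"
  } else {
    "AVERAGE"
  }
}

# Build a single-cell ROD baseline and a matching rate set with a given vote
# tally, for exercising the rule in isolation.
vote_fixture <- function(n_votes, n_exceed) {
  baseline <- tibble::tibble(
    prosthesis = "aTSA", measure = "abduction", mean_rate = 0, n = 100L
  )
  attr(baseline, "kind") <- "ROD"
  rates <- tibble::tibble(
    patient_id = "P1", prosthesis = "aTSA", measure = "abduction",
    visit_time_months = 100, interval_bin = NA_real_, kind = "ROD",
    rate = c(rep(1, n_exceed), rep(-1, n_votes - n_exceed))
  )
  list(rates = rates, baseline = baseline)
}

# Cohort of patients with preop-only visits plus externally assigned labels,
# used to exercise the risk screen with a known outcome model.
screen_fixture <- function(n, or = 2.2, exposure_prev = 0.2, base_rate = 0.25,
                           prosthesis = "rTSA") {
  diabetes <- runif(n) < exposure_prev
  eta <- log(base_rate / (1 - base_rate)) + log(or) * diabetes
  slow <- runif(n) < 1 / (1 + exp(-eta))
  patients <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    blank_patient(sprintf("S%04d", i), prosthesis)
  }))
  patients$age_years <- rnorm(n, 70, 7)
  patients$bmi <- rnorm(n, 29, 6)
  patients$sex <- ifelse(runif(n) < 0.6, "F", "M")
  patients$injections <- runif(n) < 0.35
  patients$cm_hypertension <- runif(n) < 0.45
  patients$cm_diabetes <- diabetes
  patients$cm_none <- !(patients$cm_hypertension | patients$cm_diabetes)
  preop <- dplyr::bind_rows(lapply(rom_measures(), function(m) {
    mu <- c(abduction = 75, forward_elevation = 90,
            external_rotation = 18, ir_score = 3)[[m]]
    sdv <- c(abduction = 30, forward_elevation = 32,
             external_rotation = 15, ir_score = 1.5)[[m]]
    v <- rnorm(n, mu, sdv)
    v <- pmin(pmax(v, 0), if (m == "ir_score") 6 else 200)
    visit_rows(patients$patient_id, m, rep(0, n), v)
  }))
  labels <- tibble::tibble(
    patient_id = patients$patient_id,
    prosthesis = prosthesis,
    kind = "ROI",
    label = ifelse(slow, "SLOW", ifelse(runif(n) < 0.4, "FAST", "AVERAGE")),
    n_votes = 8L, n_exceed = 4L, fraction = 0.5
  )
  list(dataset = cohort_dataset(patients, preop), labels = labels)
}
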