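#' Trajectory model parameters
#'
#' The generator draws each patient's ROM trajectory from a six-parameter
#' mean curve (see [trajectory_mean()]): saturating exponential recovery from
#' the preoperative value toward a peak, an early transient dip whose depth
#' grows with preoperative ROM above a threshold, and a late linear decline
#' after `decline_start` months. Per-measure, per-prosthesis calibration
#' (preoperative and peak distributions, dip coefficients, noise) lives in
#' `measures`; see [default_measure_table()].
#'
#' @param tau_recovery recovery time constant in months (default 4: most of
#'   the improvement is realised within the first year).
#' @param tau_dip time-to-trough of the early dip in months (default 3,
#'   matching the first scheduled follow-up).
#' @param decline_start months after surgery when the late linear decline
#'   begins (default 36, the end of the peak window).
#' @param peak_preop_cor correlation between a patient's preoperative value
#'   and their peak (default 0.2; peaks are only weakly tied to where a
#'   patient starts).
#' @param preop_cross_cor correlation between a patient's preoperative values
#'   across measures (default 0.6): a stiff shoulder is stiff in every plane,
#'   so class contrasts separate on all preoperative measures at once.
#' @param measures calibration table, see [default_measure_table()].
#' @return a `trajectory_params` list.
#' @export
trajectory_params <- function(tau_recovery = 4, tau_dip = 3,
                              decline_start = 36, peak_preop_cor = 0.2,
                              preop_cross_cor = 0.6,
                              measures = default_measure_table()) {
  if (tau_recovery <= 0 || tau_dip <= 0) {
    rt_abort("tau_recovery and tau_dip must be positive", "romtraj_domain_error")
  }
  if (any(measures$noise_sd < 0)) {
    rt_abort("noise_sd must be non-negative", "romtraj_domain_error")
  }
  structure(
    list(
      tau_recovery = tau_recovery, tau_dip = tau_dip,
      decline_start = decline_start, peak_preop_cor = peak_preop_cor,
      preop_cross_cor = preop_cross_cor,
      measures = measures
    ),
    class = "trajectory_params"
  )
}

#' Per-measure, per-prosthesis trajectory calibration
#'
#' Preoperative and peak means/SDs are set to the full-cohort summary
#' statistics typical of long-term anatomic (aTSA) and reverse (rTSA) total
#' shoulder arthroplasty series. Dip coefficients control how strongly
#' patients with preoperative ROM above `dip_threshold` lose motion over the
#' first months; late decline slopes are in units per month and are drawn per
#' patient (truncated at zero). The IR score (ordinal 0-6) uses a smaller
#' noise SD and a much smaller decline slope than the angle measures so the
#' scale is not exhausted over a decade of follow-up.
#'
#' @return tibble with one row per (measure, prosthesis).
#' @export
default_measure_table <- function() {
  tibble::tribble(
    ~measure, ~prosthesis, ~preop_mean, ~preop_sd, ~peak_mean, ~peak_sd,
    ~dip_coefficient, ~dip_threshold, ~noise_sd, ~decline_slope_mean, ~decline_slope_sd,
    "abduction",         "aTSA",  84.8, 29.7, 131.9, 28.4, 0.75, 90, 5,   0.08,  0.05,
    "forward_elevation", "aTSA",  99.2, 31.5, 150.5, 22.8, 0.75, 90, 5,   0.08,  0.05,
    "external_rotation", "aTSA",  17.6, 20.1,  53.3, 17.6, 0.25, 90, 5,   0.08,  0.05,
    "ir_score",          "aTSA",   3.1,  1.6,   5.4,  1.2, 0.05,  3, 0.5, 0.012, 0.008,
    "abduction",         "rTSA",  72.6, 34.5, 121.1, 25.9, 0.75, 90, 5,   0.08,  0.05,
    "forward_elevation", "rTSA",  88.0, 38.9, 142.4, 21.3, 0.75, 90, 5,   0.08,  0.05,
    "external_rotation", "rTSA",  18.2, 21.6,  35.7, 17.4, 0.25, 90, 5,   0.08,  0.05,
    "ir_score",          "rTSA",   3.1,  1.9,   4.9,  1.6, 0.05,  3, 0.5, 0.012, 0.008
  )
}

#' Mean ROM trajectory
#'
#' Deterministic mean curve for one measure of one patient:
#' \deqn{\mu(t) = P - (P - R_0)\,e^{-t/\tau} - D\,\frac{t}{\tau_d}\,e^{1 - t/\tau_d}
#'   - s\,\max(0, t - t_{dec})}
#' where \eqn{R_0} is the preoperative value, \eqn{P} the peak target,
#' \eqn{\tau} the recovery time constant, and the dip depth
#' \eqn{D = c \,\max(0, R_0 - \theta)} grows linearly with preoperative ROM
#' above the threshold \eqn{\theta}. The dip term is a gamma-shaped transient
#' with trough exactly \eqn{D} at \eqn{t = \tau_d}. \eqn{\mu(0) = R_0}
#' exactly.
#'
#' @param t months since surgery (vectorized, `t >= 0`).
#' @param preop_value,peak_value \eqn{R_0} and \eqn{P}.
#' @param tau_recovery,tau_dip time constants in months.
#' @param dip_coefficient,dip_threshold dip depth per unit of preoperative
#'   excess, and the preoperative value above which the dip appears.
#' @param decline_start months at which the late linear decline begins.
#' @param slope late decline slope in units per month (decline-positive).
#' @return numeric vector of mean values.
#' @export
trajectory_mean <- function(t, preop_value, peak_value,
                            tau_recovery = 4, tau_dip = 3,
                            dip_coefficient = 0.75, dip_threshold = 90,
                            decline_start = 36, slope = 0) {
  if (any(t < 0)) rt_abort("t must be non-negative", "romtraj_domain_error")
  dip_depth <- dip_coefficient * max(0, preop_value - dip_threshold)
  peak_value -
    (peak_value - preop_value) * exp(-t / tau_recovery) -
    dip_depth * (t / tau_dip) * exp(1 - t / tau_dip) -
    slope * pmax(0, t - decline_start)
}

#' Covariate effect on simulated trajectories
#'
#' Plants an association between a patient covariate and trajectory shape:
#' `early_rate_multiplier` scales the recovery amplitude \eqn{P - R_0}
#' (values < 1 slow early improvement), `decline_slope_add` adds to the late
#' decline slope (stated in degrees per month and rescaled to each measure's
#' own decline scale, so the IR score is not drained; drives fast rate of
#' decline), and
#' `class_probability` multiplies the odds that a carrier receives a latent
#' slowed-recovery modifier (recovery tau tripled, amplitude x0.7).
#'
#' @param covariate a patient-table column name (e.g. `"cm_diabetes"`,
#'   `"injections"`) or `"any_comorbidity"` (true when `cm_none` is false).
#' @param target one of `"early_rate_multiplier"`, `"decline_slope_add"`,
#'   `"class_probability"`.
#' @param magnitude effect size; multipliers must be positive.
#' @param prosthesis `"aTSA"`, `"rTSA"` or `"both"`.
#' @return one-row tibble.
#' @export
effect_spec <- function(covariate, target, magnitude, prosthesis = "both") {
  target <- match.arg(target,
                      c("early_rate_multiplier", "decline_slope_add", "class_probability"))
  prosthesis <- match.arg(prosthesis, c("both", "aTSA", "rTSA"))
  if (target %in% c("early_rate_multiplier", "class_probability") && magnitude <= 0) {
    rt_abort("multiplier magnitudes must be positive", "romtraj_domain_error")
  }
  tibble::tibble(covariate = covariate, target = target,
                 magnitude = magnitude, prosthesis = prosthesis)
}

#' Default planted covariate effects
#'
#' Mirrors the qualitative risk-factor structure the analysis is designed to
#' detect: diabetes and prior injections slow early recovery after rTSA;
#' heart disease accelerates late decline after aTSA; carrying any
#' comorbidity mildly accelerates late decline after rTSA. Magnitudes are
#' generator inputs, not estimates.
#'
#' @return tibble of effect specs.
#' @export
default_effects <- function() {
  dplyr::bind_rows(
    effect_spec("cm_diabetes", "early_rate_multiplier", 0.80, "rTSA"),
    effect_spec("injections", "early_rate_multiplier", 0.85, "rTSA"),
    effect_spec("cm_heart_disease", "decline_slope_add", 0.15, "aTSA"),
    effect_spec("any_comorbidity", "decline_slope_add", 0.05, "rTSA")
  )
}

#' Default covariate prevalences
#'
#' Per-prosthesis prevalences of the binary covariates and the age/BMI
#' distributions, set to values typical of long-term primary aTSA/rTSA
#' cohorts (reverse patients are older, more often female, and carry more
#' cuff pathology). `cm_none` is derived (true when no comorbidity flag is
#' drawn), which keeps the flag set internally consistent.
#'
#' @return named list with one entry per prosthesis.
#' @export
default_prevalences <- function() {
  list(
    aTSA = list(
      sex_female = 0.49, sex_unknown = 0.005,
      age_mean = 65.0, age_sd = 8.2, bmi_mean = 30.0, bmi_sd = 6.5,
      previous_surgery = 0.12, injections = 0.40,
      dx_osteoarthritis = 0.92, dx_osteonecrosis = 0.025,
      dx_rotator_cuff_tear = 0.035, dx_cuff_tear_arthropathy = 0.007,
      dx_rheumatoid_arthritis = 0.033,
      cm_hypertension = 0.48, cm_heart_disease = 0.12, cm_diabetes = 0.11,
      cm_tobacco = 0.06, cm_renal_failure = 0.005,
      humeral_rll = 0.21, glenoid_rll = 0.40, scapular_notching = 0,
      complication = 0.06, revision = 0.05
    ),
    rTSA = list(
      sex_female = 0.65, sex_unknown = 0.002,
      age_mean = 70.7, age_sd = 6.8, bmi_mean = 28.9, bmi_sd = 6.4,
      previous_surgery = 0.27, injections = 0.32,
      dx_osteoarthritis = 0.54, dx_osteonecrosis = 0.025,
      dx_rotator_cuff_tear = 0.40, dx_cuff_tear_arthropathy = 0.37,
      dx_rheumatoid_arthritis = 0.055,
      cm_hypertension = 0.45, cm_heart_disease = 0.10, cm_diabetes = 0.09,
      cm_tobacco = 0.06, cm_renal_failure = 0.006,
      humeral_rll = 0.31, glenoid_rll = 0.05, scapular_notching = 0.14,
      complication = 0.01, revision = 0.015
    )
  )
}

#' Simulation configuration
#'
#' @param n_atsa,n_rtsa patients per prosthesis.
#' @param schedule nominal postoperative visit months (strictly increasing);
#'   a preoperative visit at month 0 is always present.
#' @param jitter_sd SD in months of Gaussian jitter on postoperative visit
#'   times (default 0.8; clinic visits rarely land on the nominal date).
#' @param missingness probability a scheduled postoperative (visit, measure)
#'   observation is missing (default 0.15); the preoperative visit is never
#'   missing.
#' @param params [trajectory_params()].
#' @param prevalences [default_prevalences()].
#' @param effects tibble of [effect_spec()] rows (may have zero rows).
#' @param revision_step_angle,revision_step_ir instantaneous ROM loss applied
#'   from the revision time onward (30 degrees / 1.5 IR points).
#' @param seed integer seed used by [simulate_cohort()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_atsa = 100, n_rtsa = 100,
                              schedule = c(3, 6, 12, 24, 36, 60, 84, 96, 108, 120),
                              jitter_sd = 0.8, missingness = 0.15,
                              params = trajectory_params(),
                              prevalences = default_prevalences(),
                              effects = default_effects(),
                              revision_step_angle = 30, revision_step_ir = 1.5,
                              seed = NULL) {
  if (is.unsorted(schedule, strictly = TRUE)) {
    rt_abort("visit schedule must be strictly increasing", "romtraj_domain_error")
  }
  if (missingness < 0 || missingness > 1) {
    rt_abort("missingness must be a probability", "romtraj_domain_error")
  }
  if (jitter_sd < 0) rt_abort("jitter_sd must be non-negative", "romtraj_domain_error")
  structure(
    list(
      n_atsa = n_atsa, n_rtsa = n_rtsa, schedule = schedule,
      jitter_sd = jitter_sd, missingness = missingness,
      params = params, prevalences = prevalences, effects = effects,
      revision_step_angle = revision_step_angle, revision_step_ir = revision_step_ir,
      seed = seed
    ),
    class = "simulation_config"
  )
}

rbern <- function(n, p) runif(n) < p

empty_patients <- function() {
  tibble::tibble(
    patient_id = character(), prosthesis = character(),
    age_years = double(), sex = character(), bmi = double(),
    previous_surgery = logical(), injections = logical(),
    dx_osteoarthritis = logical(), dx_osteonecrosis = logical(),
    dx_rotator_cuff_tear = logical(), dx_cuff_tear_arthropathy = logical(),
    dx_rheumatoid_arthritis = logical(),
    cm_none = logical(), cm_hypertension = logical(), cm_heart_disease = logical(),
    cm_diabetes = logical(), cm_tobacco = logical(), cm_renal_failure = logical(),
    humeral_rll = logical(), glenoid_rll = logical(), glenoid_rll_grade = double(),
    scapular_notching = logical(), notching_grade = double(),
    complication = logical(), revision = logical(), revision_time_months = double()
  )
}

empty_visits <- function() {
  tibble::tibble(
    patient_id = character(), time_months = double(),
    is_preop = logical(), measure = character(), value = double()
  )
}

draw_patients <- function(n, prosthesis, config) {
  if (n == 0) return(empty_patients())
  pv <- config$prevalences[[prosthesis]]
  prefix <- if (prosthesis == "aTSA") "A" else "R"
  u_sex <- runif(n)
  sex <- ifelse(u_sex < pv$sex_unknown, "unknown",
                ifelse(u_sex < pv$sex_unknown + pv$sex_female, "F", "M"))
  cm <- list(
    cm_hypertension = rbern(n, pv$cm_hypertension),
    cm_heart_disease = rbern(n, pv$cm_heart_disease),
    cm_diabetes = rbern(n, pv$cm_diabetes),
    cm_tobacco = rbern(n, pv$cm_tobacco),
    cm_renal_failure = rbern(n, pv$cm_renal_failure)
  )
  glenoid_rll <- rbern(n, pv$glenoid_rll)
  scapular_notching <- rbern(n, pv$scapular_notching)
  revision <- rbern(n, pv$revision)
  grade_if <- function(flag, grades, probs) {
    g <- numeric(length(flag))
    k <- sum(flag)
    if (k > 0) g[flag] <- sample(grades, k, replace = TRUE, prob = probs)
    g
  }
  tibble::tibble(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    prosthesis = prosthesis,
    age_years = rnorm(n, pv$age_mean, pv$age_sd),
    sex = sex,
    bmi = pmax(15, rnorm(n, pv$bmi_mean, pv$bmi_sd)),
    previous_surgery = rbern(n, pv$previous_surgery),
    injections = rbern(n, pv$injections),
    dx_osteoarthritis = rbern(n, pv$dx_osteoarthritis),
    dx_osteonecrosis = rbern(n, pv$dx_osteonecrosis),
    dx_rotator_cuff_tear = rbern(n, pv$dx_rotator_cuff_tear),
    dx_cuff_tear_arthropathy = rbern(n, pv$dx_cuff_tear_arthropathy),
    dx_rheumatoid_arthritis = rbern(n, pv$dx_rheumatoid_arthritis),
    cm_none = !(cm$cm_hypertension | cm$cm_heart_disease | cm$cm_diabetes |
                  cm$cm_tobacco | cm$cm_renal_failure),
    cm_hypertension = cm$cm_hypertension,
    cm_heart_disease = cm$cm_heart_disease,
    cm_diabetes = cm$cm_diabetes,
    cm_tobacco = cm$cm_tobacco,
    cm_renal_failure = cm$cm_renal_failure,
    humeral_rll = rbern(n, pv$humeral_rll),
    glenoid_rll = glenoid_rll,
    glenoid_rll_grade = grade_if(glenoid_rll, 1:5, c(0.35, 0.30, 0.20, 0.10, 0.05)),
    scapular_notching = scapular_notching,
    notching_grade = grade_if(scapular_notching, 1:4, c(0.50, 0.30, 0.15, 0.05)),
    complication = rbern(n, pv$complication),
    revision = revision,
    revision_time_months = ifelse(
      revision,
      runif(n, config$params$decline_start, 96),
      NA_real_
    )
  )
}

# Effects that apply to this patient, split by target.
patient_effects <- function(patient, config) {
  eff <- config$effects
  if (is.null(eff) || nrow(eff) == 0) {
    return(list(amp = 1, slope_add = 0, class_odds = NULL))
  }
  scope <- eff$prosthesis %in% c("both", patient$prosthesis)
  carrier <- vapply(eff$covariate, function(cv) {
    if (cv == "any_comorbidity") !patient$cm_none else isTRUE(patient[[cv]])
  }, logical(1))
  active <- eff[scope & carrier, , drop = FALSE]
  amp <- prod(active$magnitude[active$target == "early_rate_multiplier"], 1)
  slope_add <- sum(active$magnitude[active$target == "decline_slope_add"])
  class_odds <- NULL
  if (any(eff$target == "class_probability" & scope)) {
    class_odds <- 0.25 * prod(active$magnitude[active$target == "class_probability"], 1)
  }
  list(amp = amp, slope_add = slope_add, class_odds = class_odds)
}

#' Simulate one patient's visit records
#'
#' Draws preoperative and peak values per ROM measure, applies any planted
#' covariate effects, generates jittered visit times with missingness, and
#' evaluates [trajectory_mean()] plus Gaussian noise at each retained
#' (time, measure). Values are clamped to the valid range after noise; IR
#' scores are rounded half-up. Patients flagged for revision lose a fixed
#' step of ROM from their revision time onward. Identical
#' (covariates, config, seed) give identical output.
#'
#' @param patient one-row patient tibble (as produced inside
#'   [simulate_cohort()]).
#' @param config a [simulation_config()].
#' @param seed optional integer; when supplied the RNG is seeded before
#'   drawing, making the call self-contained.
#' @return tibble of visit rows for this patient.
#' @export
simulate_patient <- function(patient, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  par <- config$params
  mt <- par$measures[par$measures$prosthesis == patient$prosthesis, ]
  eff <- patient_effects(patient, config)

  sched <- config$schedule
  times <- pmax(0.5, sched + rnorm(length(sched), 0, config$jitter_sd))

  amp <- eff$amp
  tau_r <- par$tau_recovery
  if (!is.null(eff$class_odds)) {
    slowed <- runif(1) < eff$class_odds / (1 + eff$class_odds)
    if (slowed) {
      tau_r <- tau_r * 3
      amp <- amp * 0.7
    }
  }

  # latent per-patient stiffness shared across measures: preoperative values
  # are correlated between planes of motion
  rho <- par$preop_cross_cor
  z_shared <- rnorm(1)

  rows <- vector("list", length(rom_measures()))
  for (i in seq_along(rom_measures())) {
    m <- rom_measures()[i]
    row <- mt[mt$measure == m, ]
    is_ir <- m == "ir_score"
    lo <- if (is_ir) IR_RANGE[1] else ANGLE_RANGE[1]
    hi <- if (is_ir) IR_RANGE[2] else ANGLE_RANGE[2]

    z_pre <- rho * z_shared + sqrt(1 - rho^2) * rnorm(1)
    preop <- min(max(row$preop_mean + row$preop_sd * z_pre, lo), hi)
    z <- rnorm(1)
    cor_term <- if (row$preop_sd > 0) {
      par$peak_preop_cor * (row$peak_sd / row$preop_sd) * (preop - row$preop_mean)
    } else {
      0
    }
    peak <- row$peak_mean + cor_term +
      sqrt(1 - par$peak_preop_cor^2) * row$peak_sd * z
    # planted decline effects are stated in degrees/month; rescale them to
    # each measure's own decline scale (0.15x for the 0-6 IR score) so an
    # angle-sized effect cannot drain the ordinal scale
    slope_scale <- row$decline_slope_mean / max(mt$decline_slope_mean)
    slope <- max(0, rnorm(1, row$decline_slope_mean, row$decline_slope_sd)) +
      eff$slope_add * slope_scale
    peak_eff <- preop + amp * (peak - preop)

    keep <- !rbern(length(times), config$missingness)
    noise <- rnorm(length(times), 0, row$noise_sd)
    mu <- trajectory_mean(
      times, preop, peak_eff,
      tau_recovery = tau_r, tau_dip = par$tau_dip,
      dip_coefficient = row$dip_coefficient, dip_threshold = row$dip_threshold,
      decline_start = par$decline_start, slope = slope
    )
    if (isTRUE(patient$revision)) {
      step <- if (is_ir) config$revision_step_ir else config$revision_step_angle
      mu <- mu - step * (times >= patient$revision_time_months)
    }
    val <- pmin(pmax(mu + noise, lo), hi)
    preop_rec <- if (is_ir) min(max(round_half_up(preop), lo), hi) else preop
    if (is_ir) val <- pmin(pmax(round_half_up(val), lo), hi)

    rows[[i]] <- tibble::tibble(
      patient_id = patient$patient_id,
      time_months = c(0, times[keep]),
      is_preop = c(TRUE, rep(FALSE, sum(keep))),
      measure = m,
      value = c(preop_rec, val[keep])
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a longitudinal cohort
#'
#' Draws `n_atsa` + `n_rtsa` patients with covariates at the configured
#' prevalences and simulates every patient's visit records. The result passes
#' full [validate_cohort()] validation, and identical (config, seed) yield an
#' identical dataset.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [cohort_dataset()].
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (is.null(seed)) {
    rt_abort("simulate_cohort() needs a seed (argument or config$seed)",
             "romtraj_domain_error")
  }
  set.seed(seed)
  patients <- dplyr::bind_rows(
    draw_patients(config$n_atsa, "aTSA", config),
    draw_patients(config$n_rtsa, "rTSA", config)
  )
  if (nrow(patients) == 0) {
    return(cohort_dataset(empty_patients(), empty_visits()))
  }
  visits <- dplyr::bind_rows(lapply(seq_len(nrow(patients)), function(i) {
    simulate_patient(patients[i, ], config)
  }))
  cohort_dataset(patients, visits)
}
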