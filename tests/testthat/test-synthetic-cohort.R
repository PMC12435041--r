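test_that("trajectory mean passes through the preoperative value at t = 0", {
  set.seed(21)
  for (i in 1:20) {
    r0 <- runif(1, 0, 180)
    p <- runif(1, 0, 180)
    expect_equal(
      trajectory_mean(0, r0, p, tau_recovery = runif(1, 1, 10),
                      tau_dip = runif(1, 1, 6),
                      dip_coefficient = runif(1, 0, 1),
                      dip_threshold = runif(1, 0, 120),
                      slope = runif(1, 0, 0.2)),
      r0
    )
  }
})

test_that("trajectory mean matches direct evaluation of the model", {
  # R0 = 130, P = 135, tau = 4, dip depth 0.75 * (130 - 90) = 30, trough at
  # t = tau_d = 3: mu(3) = 135 - 5 e^(-3/4) - 30
  expected <- 135 - 5 * exp(-0.75) - 30
  expect_equal(expected, 102.6382, tolerance = 1e-4)
  expect_equal(
    trajectory_mean(3, 130, 135, tau_recovery = 4, tau_dip = 3,
                    dip_coefficient = 0.75, dip_threshold = 90, slope = 0),
    expected,
    tolerance = 1e-12
  )
})

test_that("without a dip or decline the trajectory rises monotonically to the peak", {
  t <- seq(0, 36, by = 0.1)
  mu <- trajectory_mean(t, 60, 120, tau_recovery = 4, dip_threshold = 90,
                        slope = 0)
  expect_true(all(diff(mu) >= 0))
  expect_lt(abs(trajectory_mean(24, 60, 120, tau_recovery = 4,
                                dip_threshold = 90) - 120),
            0.01 * 60 + 0.1)
})

degenerate_config <- function(...) {
  mt <- default_measure_table()
  mt$preop_sd <- 0
  mt$peak_sd <- 0
  mt$noise_sd <- 0
  mt$decline_slope_sd <- 0
  simulation_config(
    params = trajectory_params(peak_preop_cor = 0, measures = mt),
    jitter_sd = 0, missingness = 0, effects = default_effects()[0, ], ...
  )
}

test_that("in the noiseless limit visit values equal the trajectory mean exactly", {
  cfg <- degenerate_config(n_atsa = 1, n_rtsa = 0)
  d <- simulate_cohort(cfg, seed = 5)
  mt <- cfg$params$measures
  for (m in c("abduction", "forward_elevation", "external_rotation")) {
    row <- mt[mt$measure == m & mt$prosthesis == "aTSA", ]
    got <- d$visits[d$visits$measure == m & !d$visits$is_preop, ]
    expected <- trajectory_mean(
      got$time_months, row$preop_mean, row$peak_mean,
      tau_recovery = cfg$params$tau_recovery, tau_dip = cfg$params$tau_dip,
      dip_coefficient = row$dip_coefficient, dip_threshold = row$dip_threshold,
      decline_start = cfg$params$decline_start, slope = row$decline_slope_mean
    )
    expect_equal(got$value, expected, tolerance = 1e-12)
    preop <- d$visits[d$visits$measure == m & d$visits$is_preop, ]
    expect_equal(preop$value, row$preop_mean)
  }
  # IR score is rounded half-up to the ordinal scale
  ir <- d$visits[d$visits$measure == "ir_score" & d$visits$is_preop, ]
  expect_equal(ir$value, round(3.1))
})

test_that("identical seeds reproduce the dataset; different seeds do not", {
  cfg <- simulation_config(n_atsa = 5, n_rtsa = 5)
  d1 <- simulate_cohort(cfg, seed = 99)
  d2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(d1$patients, d2$patients)
  expect_identical(d1$visits, d2$visits)
  d3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(d1$visits, d3$visits))
})

test_that("full postoperative missingness leaves only preoperative rows", {
  cfg <- simulation_config(n_atsa = 3, n_rtsa = 3, missingness = 1)
  d <- simulate_cohort(cfg, seed = 2)
  expect_true(all(d$visits$is_preop))
  expect_equal(nrow(d$visits), 6 * length(rom_measures()))
})

test_that("an empty configuration yields a valid empty dataset", {
  d <- simulate_cohort(simulation_config(n_atsa = 0, n_rtsa = 0), seed = 1)
  expect_s3_class(d, "cohort_dataset")
  expect_equal(nrow(d$patients), 0)
  expect_equal(nrow(d$visits), 0)
})

test_that("covariate prevalences are honoured to binomial accuracy", {
  cfg <- simulation_config(n_atsa = 0, n_rtsa = 500, schedule = 3)
  d <- simulate_cohort(cfg, seed = 31)
  p <- cfg$prevalences$rTSA$cm_diabetes
  emp <- mean(d$patients$cm_diabetes)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 500))
  # derived flag consistency
  others <- with(d$patients, cm_hypertension | cm_heart_disease |
                   cm_diabetes | cm_tobacco | cm_renal_failure)
  expect_identical(d$patients$cm_none, !others)
})

test_that("patients planted with high preoperative abduction dip by 3 months", {
  mt <- default_measure_table()
  # shift the preoperative distribution so ~30% of patients start >= 120
  mt$preop_mean[mt$measure == "abduction"] <- 102
  mt$preop_sd[mt$measure == "abduction"] <- 34
  cfg <- simulation_config(
    n_atsa = 200, n_rtsa = 0, schedule = 3, jitter_sd = 0,
    params = trajectory_params(measures = mt)
  )
  d <- simulate_cohort(cfg, seed = 17)
  ab <- d$visits[d$visits$measure == "abduction", ]
  wide <- merge(ab[ab$is_preop, c("patient_id", "value")],
                ab[!ab$is_preop, c("patient_id", "value")],
                by = "patient_id", suffixes = c("_pre", "_3mo"))
  hi <- wide$value_pre >= 120
  expect_gt(sum(hi), 30)
  expect_lt(mean(wide$value_3mo[hi] - wide$value_pre[hi]), 0)
})

test_that("a larger planted decline-slope effect increases carrier ROD", {
  pv <- default_prevalences()
  pv$aTSA$cm_heart_disease <- 0.5
  base_cfg <- function(mag) {
    simulation_config(
      n_atsa = 250, n_rtsa = 0, schedule = c(3, 30, 110),
      jitter_sd = 0, missingness = 0, prevalences = pv,
      effects = effect_spec("cm_heart_disease", "decline_slope_add", mag, "aTSA")
    )
  }
  mean_carrier_rod <- function(mag) {
    d <- simulate_cohort(base_cfg(mag), seed = 55)
    rod <- compute_rod_records(d, find_peak(d))
    carriers <- d$patients$patient_id[d$patients$cm_heart_disease]
    mean(rod$rate[rod$patient_id %in% carriers])
  }
  expect_gt(mean_carrier_rod(0.2), mean_carrier_rod(0.1))
})

test_that("revision plants a step loss in post-revision visits", {
  cfg <- degenerate_config(n_atsa = 1, n_rtsa = 0)
  d0 <- simulate_cohort(cfg, seed = 8)
  # same degenerate draws, but with a revision forced at 50 months: late
  # values drop by exactly the configured step
  pat <- d0$patients
  pat$revision <- TRUE
  pat$revision_time_months <- 50
  visits <- simulate_patient(pat[1, ], cfg, seed = 8)
  ab0 <- d0$visits[d0$visits$measure == "abduction", ]
  ab1 <- visits[visits$measure == "abduction", ]
  late <- ab0$time_months >= 50
  expect_equal(ab0$value[late] - ab1$value[late],
               rep(cfg$revision_step_angle, sum(late)))
  expect_equal(ab0$value[!late], ab1$value[!late])
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(schedule = c(3, 3, 6)),
               class = "romtraj_domain_error")
  expect_error(simulation_config(missingness = 1.5),
               class = "romtraj_domain_error")
  expect_error(trajectory_params(tau_recovery = 0),
               class = "romtraj_domain_error")
  expect_error(effect_spec("cm_diabetes", "early_rate_multiplier", -1),
               class = "romtraj_domain_error")
  expect_error(simulate_cohort(simulation_config()),
               class = "romtraj_domain_error") # no seed anywhere
})
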