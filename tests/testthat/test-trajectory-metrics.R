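test_that("ROI is the preop-to-visit change divided by months since surgery", {
  d <- manual_cohort()
  roi <- compute_roi_records(d)

  p1 <- roi[roi$patient_id == "P1" & roi$measure == "abduction", ]
  expect_equal(p1$rate[p1$visit_time_months == 6], (120 - 90) / 6) # 5 deg/mo
  expect_equal(p1$rate[p1$visit_time_months == 12], 0)
  # visits at 30 and 110 months are outside the recovery window
  expect_false(any(roi$visit_time_months >= 24))

  expect_equal(roi$interval_bin[roi$patient_id == "P2" &
                                  roi$visit_time_months == 3], 3)
  # P2 forward elevation has no preoperative value -> skipped and logged
  expect_false(any(roi$measure == "forward_elevation"))
  expect_equal(unname(attr(roi, "skips")["missing_preop"]), 1)
})

test_that("a postoperative visit recorded at time zero is a data error", {
  d <- manual_cohort()
  d$visits$is_preop[d$visits$time_months == 0][1] <- FALSE
  d$visits$time_months[!d$visits$is_preop & d$visits$time_months == 0] <- 0
  expect_error(compute_roi_records(d), class = "romtraj_data_error")
})

test_that("ROI records match a brute-force recomputation on a random cohort", {
  d <- simulate_cohort(simulation_config(n_atsa = 25, n_rtsa = 25), seed = 73)
  roi <- compute_roi_records(d)

  v <- as.data.frame(d$visits)
  expected <- list()
  for (pid in unique(v$patient_id)) {
    for (m in rom_measures()) {
      rows <- v[v$patient_id == pid & v$measure == m, ]
      pre <- rows$value[rows$is_preop]
      if (length(pre) != 1 || is.na(pre)) next
      post <- rows[!rows$is_preop & rows$time_months > 0 &
                     rows$time_months < 24 & !is.na(rows$value), ]
      if (nrow(post) == 0) next
      expected[[length(expected) + 1]] <- data.frame(
        patient_id = pid, measure = m, visit_time_months = post$time_months,
        rate = (post$value - pre) / post$time_months
      )
    }
  }
  expected <- do.call(rbind, expected)
  key <- function(df) order(df$patient_id, df$measure, df$visit_time_months)
  got <- as.data.frame(roi[, c("patient_id", "measure", "visit_time_months", "rate")])
  got <- got[key(got), ]
  expected <- expected[key(expected), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # reconstruction: preop + rate * t reproduces the visit value
  joined <- merge(
    roi,
    v[v$is_preop, c("patient_id", "measure", "value")],
    by = c("patient_id", "measure")
  )
  joined <- merge(
    joined,
    v[!v$is_preop, c("patient_id", "measure", "time_months", "value")],
    by.x = c("patient_id", "measure", "visit_time_months"),
    by.y = c("patient_id", "measure", "time_months")
  )
  expect_equal(joined$value.x + joined$rate * joined$visit_time_months,
               joined$value.y, tolerance = 1e-9)
})

test_that("peak extraction takes the in-window maximum, earliest on ties", {
  mk <- function(times, values) {
    cohort_dataset(blank_patient(), visit_rows("P1", "abduction", times, values))
  }
  p <- find_peak(mk(c(0, 24, 30, 36), c(80, 100, 110, 105)))
  expect_equal(p$peak_value, 110)
  expect_equal(p$peak_time_months, 30)

  p <- find_peak(mk(c(0, 30), c(80, 95)))
  expect_equal(p$peak_value, 95)
  expect_equal(p$peak_time_months, 30)

  p <- find_peak(mk(c(0, 24, 36), c(80, 110, 110)))
  expect_equal(p$peak_time_months, 24)

  # no in-window visit -> no record
  p <- find_peak(mk(c(0, 12, 48), c(80, 100, 120)))
  expect_equal(nrow(p), 0)
})

test_that("peak dominates all in-window values on random cohorts", {
  d <- simulate_cohort(simulation_config(n_atsa = 20, n_rtsa = 20), seed = 41)
  peaks <- find_peak(d)
  w <- d$visits[!d$visits$is_preop & d$visits$time_months >= 24 &
                  d$visits$time_months <= 36 &
                  d$visits$measure %in% rom_measures(), ]
  joined <- merge(w, peaks, by = c("patient_id", "measure"))
  expect_true(all(joined$peak_value >= joined$value))
  expect_true(all(peaks$peak_time_months >= 24 & peaks$peak_time_months <= 36))
})

test_that("ROD divides the loss since peak by time since the peak visit", {
  d <- manual_cohort()
  peaks <- find_peak(d) # P1 abduction: 110 at 30; P2 abduction: 105 at 36
  rod <- compute_rod_records(d, peaks)
  p1 <- rod[rod$patient_id == "P1", ]
  expect_equal(p1$rate, (110 - 100) / (110 - 30)) # 0.125 deg/mo
  p2 <- rod[rod$patient_id == "P2", ]
  expect_equal(p2$rate, (105 - 95) / (100 - 36))

  # value equal to peak -> rate exactly 0; value above peak -> negative
  d2 <- cohort_dataset(
    blank_patient(),
    visit_rows("P1", "abduction", c(0, 30, 100, 110), c(80, 110, 110, 115))
  )
  rod2 <- compute_rod_records(d2, find_peak(d2))
  expect_equal(rod2$rate[rod2$visit_time_months == 100], 0)
  expect_lt(rod2$rate[rod2$visit_time_months == 110], 0)

  # alternative denominator: months since surgery
  rod_s <- compute_rod_records(d, peaks, time_base = "surgery")
  expect_equal(rod_s$rate[rod_s$patient_id == "P1"], (110 - 100) / 110)
})

test_that("long-term visits at or before the peak are excluded and logged", {
  w <- analysis_windows(longterm_start = 36)
  d <- cohort_dataset(
    blank_patient(),
    visit_rows("P1", "abduction", c(0, 30, 36, 100), c(80, 100, 110, 90))
  )
  peaks <- find_peak(d, w) # peak 110 at 36
  # the 36-month visit is in the long-term window but not after the peak
  rod <- compute_rod_records(d, peaks, w)
  expect_equal(rod$visit_time_months, 100)
  expect_equal(rod$rate, (110 - 90) / (100 - 36))
  expect_equal(unname(attr(rod, "skips")["at_or_before_peak"]), 1)
})

test_that("ROD records match brute force and respect window discipline", {
  d <- simulate_cohort(simulation_config(n_atsa = 25, n_rtsa = 25), seed = 74)
  peaks <- find_peak(d)
  rod <- compute_rod_records(d, peaks)
  expect_true(all(rod$visit_time_months >= 96))

  v <- as.data.frame(d$visits)
  pk <- as.data.frame(peaks)
  expected <- list()
  for (i in seq_len(nrow(pk))) {
    rows <- v[v$patient_id == pk$patient_id[i] & v$measure == pk$measure[i] &
                !v$is_preop & v$time_months >= 96 &
                v$time_months > pk$peak_time_months[i] & !is.na(v$value), ]
    if (nrow(rows) == 0) next
    expected[[length(expected) + 1]] <- data.frame(
      patient_id = pk$patient_id[i], measure = pk$measure[i],
      visit_time_months = rows$time_months,
      rate = (pk$peak_value[i] - rows$value) /
        (rows$time_months - pk$peak_time_months[i])
    )
  }
  expected <- do.call(rbind, expected)
  key <- function(df) order(df$patient_id, df$measure, df$visit_time_months)
  got <- as.data.frame(rod[, c("patient_id", "measure", "visit_time_months", "rate")])
  got <- got[key(got), ]
  expected <- expected[key(expected), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
})
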