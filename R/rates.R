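#' Per-visit rates of improvement (ROI)
#'
#' For every ROM measure and every recovery-window visit, the ROI is the
#' preoperative-to-postoperative change divided by months since surgery:
#' `(value - preop) / time_months`, in degrees (or IR points) per month.
#' Visits whose (patient, measure) lacks a preoperative value are skipped and
#' counted in the skip log (attribute `"skips"`). Each record carries the
#' patient's prosthesis and the interval bin of the visit so cohort baselines
#' can be formed per (prosthesis, measure, interval).
#'
#' @param dataset a [cohort_dataset()].
#' @param windows [analysis_windows()].
#' @param bins [interval_bins()].
#' @return tibble of ROI records: `patient_id, prosthesis, measure,
#'   visit_time_months, interval_bin, kind, rate`, with a `"skips"` attribute
#'   (named counts of skipped visits by reason).
#' @export
compute_roi_records <- function(dataset, windows = analysis_windows(),
                                bins = interval_bins()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  v <- dataset$visits
  rom <- v[v$measure %in% rom_measures(), ]

  bad <- !rom$is_preop & rom$time_months == 0
  if (any(bad)) {
    rt_abort("postoperative visit recorded at time 0", "romtraj_data_error")
  }

  preop <- rom[rom$is_preop, c("patient_id", "measure", "value")]
  names(preop)[names(preop) == "value"] <- "preop_value"

  post <- rom[!rom$is_preop &
                rom$time_months > windows$recovery_start &
                rom$time_months < windows$recovery_end, ]
  merged <- dplyr::left_join(post, preop, by = c("patient_id", "measure"))
  no_preop <- is.na(merged$preop_value) & !is.na(merged$value)
  skips <- c(missing_preop = sum(no_preop), missing_value = sum(is.na(merged$value)))
  merged <- merged[!is.na(merged$preop_value) & !is.na(merged$value), ]

  out <- tibble::tibble(
    patient_id = merged$patient_id,
    measure = merged$measure,
    visit_time_months = merged$time_months,
    interval_bin = bin_interval(merged$time_months, bins),
    kind = "ROI",
    rate = (merged$value - merged$preop_value) / merged$time_months
  )
  out <- dplyr::left_join(
    out, dataset$patients[, c("patient_id", "prosthesis")], by = "patient_id"
  )
  out <- out[, c("patient_id", "prosthesis", "measure", "visit_time_months",
                 "interval_bin", "kind", "rate")]
  attr(out, "skips") <- skips
  out
}

#' Peak improvement within the peak window
#'
#' A patient's peak for each ROM measure is the highest observed value among
#' visits inside the (closed) peak window; ties take the earliest visit,
#' which keeps the subsequent decline denominator conservative. Patients with
#' no in-window visit for a measure yield no record and are thereby excluded
#' from the rate-of-decline computation for that measure.
#'
#' @inheritParams compute_roi_records
#' @return tibble of peak records: `patient_id, prosthesis, measure,
#'   peak_value, peak_time_months`.
#' @export
find_peak <- function(dataset, windows = analysis_windows()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  v <- dataset$visits
  w <- v[v$measure %in% rom_measures() & !v$is_preop &
           v$time_months >= windows$peak_start &
           v$time_months <= windows$peak_end &
           !is.na(v$value), ]
  out <- w |>
    dplyr::arrange(.data$patient_id, .data$measure,
                   dplyr::desc(.data$value), .data$time_months) |>
    dplyr::distinct(.data$patient_id, .data$measure, .keep_all = TRUE) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      measure = .data$measure,
      peak_value = .data$value,
      peak_time_months = .data$time_months
    )
  dplyr::left_join(out, dataset$patients[, c("patient_id", "prosthesis")],
                   by = "patient_id")[
    , c("patient_id", "prosthesis", "measure", "peak_value", "peak_time_months")
  ]
}

#' Per-visit rates of decline (ROD)
#'
#' For every long-term visit (at or after `longterm_start`), the ROD is the
#' loss since the peak divided by the elapsed time:
#' `(peak_value - value) / (visit_time - peak_time)` by default, so declining
#' patients have positive rates and patients still improving after their peak
#' have negative rates. `time_base = "surgery"` divides by months since
#' surgery instead (the alternative reading of "follow-up duration").
#' Long-term visits at or before the peak time are excluded and logged.
#'
#' @inheritParams compute_roi_records
#' @param peaks peak records from [find_peak()].
#' @param time_base denominator: months since the peak visit (default) or
#'   months since surgery.
#' @return tibble of ROD records (same columns as ROI; `interval_bin` is
#'   `NA`), with a `"skips"` attribute.
#' @export
compute_rod_records <- function(dataset, peaks, windows = analysis_windows(),
                                time_base = c("peak", "surgery")) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  time_base <- match.arg(time_base)
  v <- dataset$visits
  lt <- v[v$measure %in% rom_measures() & !v$is_preop &
            v$time_months >= windows$longterm_start & !is.na(v$value), ]
  merged <- dplyr::inner_join(
    lt, peaks[, c("patient_id", "measure", "peak_value", "peak_time_months")],
    by = c("patient_id", "measure")
  )
  n_no_peak <- nrow(lt) - nrow(merged)
  pre_peak <- merged$time_months <= merged$peak_time_months
  skips <- c(no_peak = n_no_peak, at_or_before_peak = sum(pre_peak))
  merged <- merged[!pre_peak, ]

  denom <- if (time_base == "peak") {
    merged$time_months - merged$peak_time_months
  } else {
    merged$time_months
  }
  out <- tibble::tibble(
    patient_id = merged$patient_id,
    measure = merged$measure,
    visit_time_months = merged$time_months,
    interval_bin = NA_real_,
    kind = "ROD",
    rate = (merged$peak_value - merged$value) / denom
  )
  out <- dplyr::left_join(
    out, dataset$patients[, c("patient_id", "prosthesis")], by = "patient_id"
  )
  out <- out[, c("patient_id", "prosthesis", "measure", "visit_time_months",
                 "interval_bin", "kind", "rate")]
  attr(out, "skips") <- skips
  out
}
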