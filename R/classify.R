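#' Cohort-average rate baselines
#'
#' The reference the voting classifier compares against: the arithmetic mean
#' rate per (prosthesis, measure, interval bin) for ROI records, or per
#' (prosthesis, measure) for ROD records. Cells with no records are absent.
#'
#' @param rate_records tibble from [compute_roi_records()] or
#'   [compute_rod_records()] (a single `kind`).
#' @param kind `"ROI"` or `"ROD"`; inferred from the records when omitted.
#' @return tibble with the grouping keys, `mean_rate` and `n`, with a
#'   `"kind"` attribute.
#' @export
compute_baseline <- function(rate_records, kind = NULL) {
  if (is.null(kind)) kind <- unique(rate_records$kind)
  if (length(kind) != 1) {
    rt_abort("rate records must be of a single kind (ROI or ROD)",
             "romtraj_domain_error")
  }
  keys <- if (kind == "ROI") {
    c("prosthesis", "measure", "interval_bin")
  } else {
    c("prosthesis", "measure")
  }
  out <- rate_records |>
    dplyr::filter(.data$kind == !!kind) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_rate = mean(.data$rate), n = dplyr::n(), .groups = "drop")
  attr(out, "kind") <- kind
  out
}

#' Classifier configuration
#'
#' The two-thirds/one-third voting rule: each of a patient's rate records
#' casts one vote against the matching baseline cell; a record "exceeds" when
#' its rate is strictly greater than the cell mean. A patient is FAST when
#' the exceedance fraction is strictly above `fast_threshold`, SLOW when
#' strictly below `slow_threshold`, AVERAGE otherwise, and UNCLASSIFIED with
#' fewer than `min_votes` votes. For ROD records (stored decline-positive)
#' exceeding means declining faster than the cohort, so FAST ROD = fast
#' decline.
#'
#' @param fast_threshold,slow_threshold exceedance fractions (strict
#'   inequalities); defaults 2/3 and 1/3.
#' @param min_votes minimum matched records required to classify (default 4,
#'   about one vote per measure).
#' @param vote_unit `"per_visit"` (default: one vote per rate record) or
#'   `"per_measure_mean"` (one vote per measure, comparing the patient's mean
#'   rate for the measure against the mean of that measure's cell means).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(fast_threshold = 2 / 3, slow_threshold = 1 / 3,
                              min_votes = 4,
                              vote_unit = c("per_visit", "per_measure_mean")) {
  if (!(slow_threshold >= 0 && slow_threshold < fast_threshold &&
        fast_threshold <= 1)) {
    rt_abort("need 0 <= slow_threshold < fast_threshold <= 1",
             "romtraj_domain_error")
  }
  structure(
    list(
      fast_threshold = fast_threshold, slow_threshold = slow_threshold,
      min_votes = min_votes, vote_unit = match.arg(vote_unit)
    ),
    class = "classifier_config"
  )
}

label_from_votes <- function(n_votes, n_exceed, config) {
  if (n_votes < config$min_votes) return("UNCLASSIFIED")
  frac <- n_exceed / n_votes
  if (frac > config$fast_threshold) "FAST"
  else if (frac < config$slow_threshold) "SLOW"
  else "AVERAGE"
}

# Join one patient's records to baseline cells and tally exceedance votes.
tally_votes <- function(patient_rates, baseline, config) {
  kind <- attr(baseline, "kind")
  keys <- if (identical(kind, "ROI")) {
    c("prosthesis", "measure", "interval_bin")
  } else {
    c("prosthesis", "measure")
  }
  joined <- dplyr::inner_join(patient_rates, baseline, by = keys)
  if (config$vote_unit == "per_measure_mean") {
    joined <- joined |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(rate = mean(.data$rate), mean_rate = mean(.data$mean_rate),
                       .groups = "drop")
  }
  list(
    n_votes = nrow(joined),
    n_exceed = sum(joined$rate > joined$mean_rate),
    n_skipped = nrow(patient_rates) - nrow(joined)
  )
}

#' Classify one patient
#'
#' @param patient_rates rate records belonging to a single patient and kind.
#' @param baseline baseline from [compute_baseline()] for the same kind.
#' @param config a [classifier_config()].
#' @return one-row tibble: `patient_id, kind, label, n_votes, n_exceed,
#'   fraction`.
#' @export
classify_patient <- function(patient_rates, baseline, config = classifier_config()) {
  pid <- unique(patient_rates$patient_id)
  kind <- unique(patient_rates$kind)
  if (length(pid) != 1 || length(kind) != 1) {
    rt_abort("classify_patient() takes records of one patient and one kind",
             "romtraj_domain_error")
  }
  votes <- tally_votes(patient_rates, baseline, config)
  tibble::tibble(
    patient_id = pid,
    kind = kind,
    label = label_from_votes(votes$n_votes, votes$n_exceed, config),
    n_votes = votes$n_votes,
    n_exceed = votes$n_exceed,
    fraction = ifelse(votes$n_votes > 0, votes$n_exceed / votes$n_votes, NA_real_)
  )
}

#' Classify every patient in a cohort
#'
#' Builds the cohort baseline from the supplied records (the baseline
#' includes each patient's own records; no leave-one-out) and labels every
#' patient with at least one rate record.
#'
#' @param dataset a [cohort_dataset()] (provides prosthesis per patient).
#' @param rate_records records of one kind, from [compute_roi_records()] or
#'   [compute_rod_records()].
#' @param kind `"ROI"` or `"ROD"`; inferred when omitted.
#' @param config a [classifier_config()].
#' @return tibble with one row per patient: `patient_id, prosthesis, kind,
#'   label, n_votes, n_exceed, fraction`, with a `"label_counts"` attribute.
#' @export
classify_cohort <- function(dataset, rate_records, kind = NULL,
                            config = classifier_config()) {
  baseline <- compute_baseline(rate_records, kind)
  kind <- attr(baseline, "kind")
  keys <- if (kind == "ROI") {
    c("prosthesis", "measure", "interval_bin")
  } else {
    c("prosthesis", "measure")
  }
  per_visit <- config$vote_unit == "per_visit"
  tallied <- dplyr::inner_join(rate_records, baseline, by = keys)
  if (!per_visit) {
    tallied <- tallied |>
      dplyr::group_by(.data$patient_id, .data$prosthesis, .data$measure) |>
      dplyr::summarise(rate = mean(.data$rate), mean_rate = mean(.data$mean_rate),
                       .groups = "drop")
  }
  votes <- tallied |>
    dplyr::group_by(.data$patient_id, .data$prosthesis) |>
    dplyr::summarise(
      n_votes = dplyr::n(),
      n_exceed = sum(.data$rate > .data$mean_rate),
      .groups = "drop"
    )
  # patients with records but no baseline-matched votes still get a row
  all_pat <- dplyr::distinct(rate_records, .data$patient_id, .data$prosthesis)
  votes <- dplyr::left_join(all_pat, votes, by = c("patient_id", "prosthesis")) |>
    dplyr::mutate(
      n_votes = dplyr::coalesce(.data$n_votes, 0L),
      n_exceed = dplyr::coalesce(.data$n_exceed, 0L)
    )
  out <- votes |>
    dplyr::mutate(
      kind = kind,
      label = purrr::map2_chr(.data$n_votes, .data$n_exceed,
                              ~ label_from_votes(.x, .y, config)),
      fraction = ifelse(.data$n_votes > 0, .data$n_exceed / .data$n_votes, NA_real_)
    ) |>
    dplyr::select("patient_id", "prosthesis", "kind", "label",
                  "n_votes", "n_exceed", "fraction") |>
    dplyr::arrange(.data$patient_id)
  attr(out, "label_counts") <- table(out$label)
  out
}
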