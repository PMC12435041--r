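#' Group summary tables
#'
#' Cohort-style summary of outcome measures by trajectory class: mean ± SD
#' per (prosthesis, label, measure) at a chosen time point, with per-patient
#' improvement over the preoperative value where applicable, and a Welch
#' p-value between the FAST and SLOW classes.
#'
#' Time points: `"preop"` uses the preoperative visit; `"latest"` uses each
#' patient's maximum-time visit per measure, restricted to visits at or after
#' `min_latest_months` (set it to 0 to use the latest visit of any time);
#' `"peak"` uses the peak-window maximum from [find_peak()].
#'
#' @param dataset a [cohort_dataset()].
#' @param labels classification results from [classify_cohort()].
#' @param timepoint one of `"preop"`, `"latest"`, `"peak"`.
#' @param measures which measures to tabulate (default: all present).
#' @param min_latest_months minimum follow-up for a "latest" visit (default
#'   96; long-term tables should not be diluted by short follow-up).
#' @param windows [analysis_windows()] (used for `"peak"`).
#' @return tibble: `prosthesis, label, measure, n, mean, sd,
#'   improvement_mean, improvement_sd, p_fast_vs_slow` (p repeated within
#'   prosthesis x measure; `NA` when either extreme class is too small).
#' @export
summarize_groups <- function(dataset, labels,
                             timepoint = c("preop", "latest", "peak"),
                             measures = NULL, min_latest_months = 96,
                             windows = analysis_windows()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  timepoint <- match.arg(timepoint)
  v <- dataset$visits
  if (is.null(measures)) measures <- unique(v$measure)

  values <- switch(
    timepoint,
    preop = v |>
      dplyr::filter(.data$is_preop, .data$measure %in% measures,
                    !is.na(.data$value)) |>
      dplyr::select("patient_id", "measure", "value"),
    latest = v |>
      dplyr::filter(!.data$is_preop, .data$measure %in% measures,
                    .data$time_months >= min_latest_months,
                    !is.na(.data$value)) |>
      dplyr::group_by(.data$patient_id, .data$measure) |>
      dplyr::slice_max(.data$time_months, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "measure", "value"),
    peak = find_peak(dataset, windows) |>
      dplyr::filter(.data$measure %in% measures) |>
      dplyr::transmute(patient_id = .data$patient_id, measure = .data$measure,
                       value = .data$peak_value)
  )

  preop <- v |>
    dplyr::filter(.data$is_preop, !is.na(.data$value)) |>
    dplyr::select("patient_id", "measure", preop_value = "value")
  values <- values |>
    dplyr::left_join(preop, by = c("patient_id", "measure")) |>
    dplyr::mutate(improvement = .data$value - .data$preop_value)

  joined <- values |>
    dplyr::inner_join(labels[, c("patient_id", "prosthesis", "label")],
                      by = "patient_id")

  out <- joined |>
    dplyr::group_by(.data$prosthesis, .data$label, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      improvement_mean = mean(.data$improvement, na.rm = TRUE),
      improvement_sd = sd(.data$improvement, na.rm = TRUE),
      .groups = "drop"
    )

  pvals <- joined |>
    dplyr::group_by(.data$prosthesis, .data$measure) |>
    dplyr::summarise(
      p_fast_vs_slow = {
        f <- .data$value[.data$label == "FAST"]
        s <- .data$value[.data$label == "SLOW"]
        if (length(f) >= 2 && length(s) >= 2) {
          two_sample_t_test(f, s)$p_value
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )
  dplyr::left_join(out, pvals, by = c("prosthesis", "measure")) |>
    dplyr::arrange(.data$prosthesis, .data$measure, .data$label)
}

#' Peak-to-long-term decline summary
#'
#' Difference between mean peak improvement and mean latest long-term value
#' per ROM measure, reported at clinical precision: angles are rounded half
#' up to the nearest degree, the IR score to the nearest half point. The
#' unrounded difference is kept alongside.
#'
#' @param peak_means,latest_means named numeric vectors keyed by measure
#'   name; both must cover the same measures.
#' @param rounding apply the reporting precision (default `TRUE`).
#' @return tibble: `measure, peak_mean, latest_mean, decline_raw, decline`.
#' @export
decline_from_peak <- function(peak_means, latest_means, rounding = TRUE) {
  if (!setequal(names(peak_means), names(latest_means)) ||
      is.null(names(peak_means))) {
    rt_abort("peak_means and latest_means must be named by the same measures",
             "romtraj_key_error")
  }
  measures <- names(peak_means)
  latest_means <- latest_means[measures]
  raw <- unname(peak_means - latest_means)
  rounded <- ifelse(
    measures == "ir_score", round_to_half(raw), round_half_up(raw)
  )
  tibble::tibble(
    measure = measures,
    peak_mean = unname(peak_means),
    latest_mean = unname(latest_means),
    decline_raw = raw,
    decline = if (rounding) rounded else raw
  )
}

#' Pipeline configuration
#'
#' @param out_dir directory for output artifacts (created if absent).
#' @param patients_path,visits_path CSV inputs; when `NULL` a cohort is
#'   simulated from `sim_config`.
#' @param sim_config a [simulation_config()] used when no input files are
#'   given.
#' @param seed integer seed for the simulation.
#' @param windows [analysis_windows()].
#' @param bins [interval_bins()].
#' @param classifier [classifier_config()].
#' @param rod_time_base `"peak"` or `"surgery"` (see
#'   [compute_rod_records()]).
#' @param alpha significance level for the risk screens.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, patients_path = NULL, visits_path = NULL,
                            sim_config = simulation_config(), seed = 1,
                            windows = analysis_windows(), bins = interval_bins(),
                            classifier = classifier_config(),
                            rod_time_base = "peak", alpha = 0.05) {
  structure(
    list(out_dir = out_dir, patients_path = patients_path,
         visits_path = visits_path, sim_config = sim_config, seed = seed,
         windows = windows, bins = bins, classifier = classifier,
         rod_time_base = rod_time_base, alpha = alpha),
    class = "pipeline_config"
  )
}

write_stage <- function(df, out_dir, file) {
  readr::write_csv(df, file.path(out_dir, file), na = "", progress = FALSE)
}

#' Run the full trajectory pipeline
#'
#' Executes every stage over a real or simulated cohort: per-visit ROI
#' records, peak extraction, ROD records, cohort baselines, fast/average/slow
#' classification for both kinds, the per-prosthesis risk screens, group
#' summary tables and the peak-to-long-term decline summary. All outputs are
#' CSV files under `config$out_dir`, plus a deterministic run log
#' (`run_log.txt`) recording the seed, package version, row counts and skip
#' reasons. Identical config and seed produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("romtraj %s", as.character(packageVersion("romtraj"))),
    sprintf("seed: %d", config$seed)
  )

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      rt_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)),
               "romtraj_pipeline_error", parent = e)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  dataset <- stage("load", {
    if (!is.null(config$patients_path)) {
      read_cohort(config$patients_path, config$visits_path)
    } else {
      simulate_cohort(config$sim_config, seed = config$seed)
    }
  })
  write_cohort(dataset, file.path(config$out_dir, "patients.csv"),
               file.path(config$out_dir, "visits.csv"))
  log_lines <- c(log_lines,
                 sprintf("patients: %d", nrow(dataset$patients)),
                 sprintf("visit rows: %d", nrow(dataset$visits)))

  roi <- stage("roi", compute_roi_records(dataset, config$windows, config$bins))
  peaks <- stage("peaks", find_peak(dataset, config$windows))
  rod <- stage("rod", compute_rod_records(dataset, peaks, config$windows,
                                          time_base = config$rod_time_base))
  if (nrow(rod) == 0) {
    warn("no long-term visits beyond the peak: ROD outputs are empty",
         class = "romtraj_empty_rod_warning")
  }
  write_stage(roi, config$out_dir, "roi_records.csv")
  write_stage(peaks, config$out_dir, "peaks.csv")
  write_stage(rod, config$out_dir, "rod_records.csv")
  log_lines <- c(
    log_lines,
    sprintf("roi records: %d (skips: %s)", nrow(roi),
            paste(names(attr(roi, "skips")), attr(roi, "skips"),
                  sep = "=", collapse = ", ")),
    sprintf("peak records: %d", nrow(peaks)),
    sprintf("rod records: %d (skips: %s)", nrow(rod),
            paste(names(attr(rod, "skips")), attr(rod, "skips"),
                  sep = "=", collapse = ", "))
  )

  roi_baseline <- stage("baselines", compute_baseline(roi, "ROI"))
  rod_baseline <- compute_baseline(rod, "ROD")
  write_stage(roi_baseline, config$out_dir, "roi_baseline.csv")
  write_stage(rod_baseline, config$out_dir, "rod_baseline.csv")

  roi_labels <- stage("classify",
                      classify_cohort(dataset, roi, "ROI", config$classifier))
  rod_labels <- if (nrow(rod) > 0) {
    classify_cohort(dataset, rod, "ROD", config$classifier)
  } else {
    roi_labels[0, ]
  }
  write_stage(roi_labels, config$out_dir, "roi_labels.csv")
  write_stage(rod_labels, config$out_dir, "rod_labels.csv")
  log_lines <- c(
    log_lines,
    sprintf("roi labels: %s",
            paste(names(table(roi_labels$label)), table(roi_labels$label),
                  sep = "=", collapse = ", ")),
    sprintf("rod labels: %s",
            paste(names(table(rod_labels$label)), table(rod_labels$label),
                  sep = "=", collapse = ", "))
  )

  screens <- stage("screen", {
    combos <- list(
      list(comparison = "roi-slow", labels = roi_labels),
      list(comparison = "rod-fast", labels = rod_labels)
    )
    res <- list()
    for (cb in combos) {
      for (pr in c("aTSA", "rTSA")) {
        key <- paste0(cb$comparison, "_", pr)
        res[[key]] <- tryCatch(
          run_screen(dataset, cb$labels, cb$comparison, pr,
                     alpha = config$alpha),
          romtraj_class_size_error = function(e) {
            warn(sprintf("screen %s skipped: %s", key, conditionMessage(e)))
            NULL
          }
        )
        if (!is.null(res[[key]])) {
          write_stage(res[[key]], config$out_dir,
                      paste0("screen_", gsub("-", "_", key), ".csv"))
        }
      }
    }
    res
  })

  tables <- stage("tables", {
    list(
      preop = summarize_groups(dataset, roi_labels, "preop"),
      latest_roi = summarize_groups(dataset, roi_labels, "latest",
                                    windows = config$windows),
      peak = summarize_groups(dataset, roi_labels, "peak",
                              windows = config$windows),
      latest_rod = if (nrow(rod_labels) > 0) {
        summarize_groups(dataset, rod_labels, "latest",
                         windows = config$windows)
      } else {
        NULL
      }
    )
  })
  write_stage(tables$preop, config$out_dir, "table_preop_by_roi.csv")
  write_stage(tables$latest_roi, config$out_dir, "table_latest_by_roi.csv")
  write_stage(tables$peak, config$out_dir, "table_peak_by_roi.csv")
  if (!is.null(tables$latest_rod)) {
    write_stage(tables$latest_rod, config$out_dir, "table_latest_by_rod.csv")
  }

  decline <- stage("decline", {
    res <- list()
    for (pr in c("aTSA", "rTSA")) {
      pk <- peaks[peaks$prosthesis == pr, ] |>
        dplyr::group_by(.data$measure) |>
        dplyr::summarise(mean = mean(.data$peak_value), .groups = "drop")
      lt <- dataset$visits |>
        dplyr::inner_join(dataset$patients[, c("patient_id", "prosthesis")],
                          by = "patient_id") |>
        dplyr::filter(.data$prosthesis == pr, !.data$is_preop,
                      .data$measure %in% rom_measures(),
                      .data$time_months >= config$windows$longterm_start,
                      !is.na(.data$value)) |>
        dplyr::group_by(.data$patient_id, .data$measure) |>
        dplyr::slice_max(.data$time_months, n = 1, with_ties = FALSE) |>
        dplyr::group_by(.data$measure) |>
        dplyr::summarise(mean = mean(.data$value), .groups = "drop")
      common <- intersect(pk$measure, lt$measure)
      if (length(common) > 0) {
        d <- decline_from_peak(
          setNames(pk$mean[match(common, pk$measure)], common),
          setNames(lt$mean[match(common, lt$measure)], common)
        )
        d$prosthesis <- pr
        res[[pr]] <- d
      }
    }
    dplyr::bind_rows(res)
  })
  if (nrow(decline) > 0) write_stage(decline, config$out_dir, "decline_summary.csv")

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(
    dataset = dataset, roi = roi, peaks = peaks, rod = rod,
    roi_baseline = roi_baseline, rod_baseline = rod_baseline,
    roi_labels = roi_labels, rod_labels = rod_labels,
    screens = screens, tables = tables, decline = decline
  ))
}
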