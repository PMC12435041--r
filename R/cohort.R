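#' Cohort dataset: patients and visits
#'
#' A cohort dataset pairs a patient table (one row per patient: demographics,
#' prosthesis, diagnosis and comorbidity flags, radiographic/complication
#' fields) with a long-format visit table (one row per patient, time point and
#' measure). All downstream stages operate on this container.
#'
#' @name cohort_dataset
NULL

PATIENT_COLUMNS <- c(
  "patient_id", "prosthesis", "age_years", "sex", "bmi",
  "previous_surgery", "injections",
  "dx_osteoarthritis", "dx_osteonecrosis", "dx_rotator_cuff_tear",
  "dx_cuff_tear_arthropathy", "dx_rheumatoid_arthritis",
  "cm_none", "cm_hypertension", "cm_heart_disease", "cm_diabetes",
  "cm_tobacco", "cm_renal_failure",
  "humeral_rll", "glenoid_rll", "glenoid_rll_grade",
  "scapular_notching", "notching_grade",
  "complication", "revision", "revision_time_months"
)

PATIENT_FLAGS <- c(
  "previous_surgery", "injections",
  "dx_osteoarthritis", "dx_osteonecrosis", "dx_rotator_cuff_tear",
  "dx_cuff_tear_arthropathy", "dx_rheumatoid_arthritis",
  "cm_none", "cm_hypertension", "cm_heart_disease", "cm_diabetes",
  "cm_tobacco", "cm_renal_failure",
  "humeral_rll", "glenoid_rll", "scapular_notching",
  "complication", "revision"
)

VISIT_COLUMNS <- c("patient_id", "time_months", "is_preop", "measure", "value")

#' Construct a validated cohort dataset
#'
#' @param patients tibble conforming to the patient schema (see
#'   [read_cohort()] for column list).
#' @param visits long-format visit tibble with columns `patient_id`,
#'   `time_months`, `is_preop`, `measure`, `value`.
#' @param validate run full validation (default `TRUE`).
#' @return a `cohort_dataset` object.
#' @export
cohort_dataset <- function(patients, visits, validate = TRUE) {
  patients <- tibble::as_tibble(patients)
  visits <- tibble::as_tibble(visits)
  if (validate) {
    validate_cohort(patients, visits)
    visits$value <- normalize_values(visits$measure, visits$value)
  }
  structure(list(patients = patients, visits = visits), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d patients (%d aTSA, %d rTSA), %d visit rows, %d measures\n",
    nrow(x$patients),
    sum(x$patients$prosthesis == "aTSA"),
    sum(x$patients$prosthesis == "rTSA"),
    nrow(x$visits),
    length(unique(x$visits$measure))
  ))
  invisible(x)
}

# IR scores arrive possibly non-integer (means of repeat measurements, data
# entry); convention is half-up rounding before range checks.
normalize_values <- function(measure, value) {
  ir <- measure == "ir_score" & !is.na(value)
  value[ir] <- round_half_up(value[ir])
  value
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rt_abort(
      sprintf("%s table is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "romtraj_schema_error"
    )
  }
}

#' Validate a cohort dataset
#'
#' Checks schema, value ranges, key uniqueness and referential integrity.
#' Validation is total: malformed input raises a typed condition
#' (`romtraj_schema_error`, `romtraj_validation_error`,
#' `romtraj_uniqueness_error`, `romtraj_integrity_error`), never a silent
#' coercion.
#'
#' @inheritParams cohort_dataset
#' @return invisibly `TRUE`.
#' @export
validate_cohort <- function(patients, visits) {
  check_columns(patients, PATIENT_COLUMNS, "patients")
  check_columns(visits, VISIT_COLUMNS, "visits")

  bad_prost <- !patients$prosthesis %in% c("aTSA", "rTSA")
  if (any(bad_prost)) {
    rt_abort(
      sprintf("prosthesis must be 'aTSA' or 'rTSA'; bad row(s): %s",
              paste(utils::head(which(bad_prost), 5), collapse = ", ")),
      "romtraj_validation_error"
    )
  }
  bad_sex <- !patients$sex %in% c("F", "M", "unknown")
  if (any(bad_sex)) {
    rt_abort(
      sprintf("sex must be 'F', 'M' or 'unknown'; bad row(s): %s",
              paste(utils::head(which(bad_sex), 5), collapse = ", ")),
      "romtraj_validation_error"
    )
  }
  for (fl in PATIENT_FLAGS) {
    v <- patients[[fl]]
    if (!is.logical(v) && !all(v %in% c(0, 1, NA))) {
      rt_abort(sprintf("patient flag '%s' must be boolean (0/1)", fl),
               "romtraj_validation_error")
    }
  }
  if (anyDuplicated(patients$patient_id) > 0) {
    rt_abort("duplicate patient_id in patient table", "romtraj_uniqueness_error")
  }

  flags <- function(col) as.logical(patients[[col]])
  other_cm <- c("cm_hypertension", "cm_heart_disease", "cm_diabetes",
                "cm_tobacco", "cm_renal_failure")
  any_other <- Reduce(`|`, lapply(other_cm, flags))
  bad_none <- flags("cm_none") & any_other
  if (any(bad_none, na.rm = TRUE)) {
    rt_abort(
      sprintf("cm_none = 1 with another comorbidity flag set; row(s): %s",
              paste(utils::head(which(bad_none), 5), collapse = ", ")),
      "romtraj_validation_error"
    )
  }
  rev_mismatch <- xor(flags("revision"), !is.na(patients$revision_time_months))
  if (any(rev_mismatch, na.rm = TRUE)) {
    rt_abort(
      sprintf("revision_time_months must be present iff revision = 1; row(s): %s",
              paste(utils::head(which(rev_mismatch), 5), collapse = ", ")),
      "romtraj_validation_error"
    )
  }
  if (any(!patients$glenoid_rll_grade %in% 0:5, na.rm = TRUE)) {
    rt_abort("glenoid_rll_grade must be an integer in 0-5", "romtraj_validation_error")
  }
  if (any(!patients$notching_grade %in% 0:4, na.rm = TRUE)) {
    rt_abort("notching_grade must be an integer in 0-4", "romtraj_validation_error")
  }

  # --- visit table ---
  bad_measure <- !visits$measure %in% all_measures()
  if (any(bad_measure)) {
    rt_abort(
      sprintf("unknown measure '%s' at visit row %d",
              visits$measure[which(bad_measure)[1]], which(bad_measure)[1]),
      "romtraj_validation_error"
    )
  }
  if (any(visits$time_months < 0, na.rm = TRUE)) {
    rt_abort("time_months must be non-negative", "romtraj_validation_error")
  }
  preop_flag <- as.logical(visits$is_preop)
  mismatch <- xor(preop_flag, visits$time_months == 0)
  if (any(mismatch, na.rm = TRUE)) {
    rt_abort(
      sprintf("is_preop must be 1 exactly when time_months = 0; visit row(s): %s",
              paste(utils::head(which(mismatch), 5), collapse = ", ")),
      "romtraj_validation_error"
    )
  }

  key <- paste(visits$patient_id, visits$time_months, visits$measure, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- which(duplicated(key))[1]
    rt_abort(
      sprintf("duplicate (patient_id, time_months, measure) at visit row %d", dup),
      "romtraj_uniqueness_error"
    )
  }

  orphan <- !visits$patient_id %in% patients$patient_id
  if (any(orphan)) {
    rt_abort(
      sprintf("visit row %d references unknown patient_id '%s'",
              which(orphan)[1], visits$patient_id[which(orphan)[1]]),
      "romtraj_integrity_error"
    )
  }

  val <- normalize_values(visits$measure, visits$value)
  angle <- is_angle_measure(visits$measure) & !is.na(val)
  bad_angle <- angle & (val < ANGLE_RANGE[1] | val > ANGLE_RANGE[2])
  if (any(bad_angle)) {
    rt_abort(
      sprintf("angle value %g outside valid range [0, 200] at visit row %d",
              val[which(bad_angle)[1]], which(bad_angle)[1]),
      "romtraj_validation_error"
    )
  }
  ir <- visits$measure == "ir_score" & !is.na(val)
  bad_ir <- ir & (val < IR_RANGE[1] | val > IR_RANGE[2])
  if (any(bad_ir)) {
    rt_abort(
      sprintf("ir_score value %g outside valid range [0, 6] at visit row %d",
              val[which(bad_ir)[1]], which(bad_ir)[1]),
      "romtraj_validation_error"
    )
  }
  invisible(TRUE)
}

patient_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    prosthesis = readr::col_character(),
    age_years = readr::col_double(),
    sex = readr::col_character(),
    bmi = readr::col_double(),
    glenoid_rll_grade = readr::col_double(),
    notching_grade = readr::col_double(),
    revision_time_months = readr::col_double(),
    .default = readr::col_double()
  )
}

#' Read a cohort from CSV files
#'
#' Reads and validates the two tabular inputs. `patients.csv` carries one row
#' per patient with 0/1-coded flags; `visits.csv` is long format with columns
#' `patient_id, time_months, is_preop, measure, value`. Missing values are
#' empty cells. Files are UTF-8, comma-separated with a header row.
#'
#' @param patients_path,visits_path file paths.
#' @return a validated [cohort_dataset()].
#' @export
read_cohort <- function(patients_path, visits_path) {
  patients <- readr::read_csv(patients_path, col_types = patient_col_types(),
                              na = c(""), progress = FALSE)
  visits <- readr::read_csv(
    visits_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      time_months = readr::col_double(),
      is_preop = readr::col_double(),
      measure = readr::col_character(),
      value = readr::col_double()
    ),
    na = c(""), progress = FALSE
  )
  check_columns(patients, PATIENT_COLUMNS, "patients")
  check_columns(visits, VISIT_COLUMNS, "visits")
  patients <- dplyr::mutate(
    patients,
    dplyr::across(dplyr::all_of(PATIENT_FLAGS), ~ as.logical(.x))
  )
  visits$is_preop <- as.logical(visits$is_preop)
  cohort_dataset(patients, visits)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort()` after `write_cohort()` is the
#' identity on valid datasets. Booleans are written as 0/1, missing values as
#' empty cells.
#'
#' @param dataset a [cohort_dataset()].
#' @param patients_path,visits_path output file paths.
#' @return invisibly the dataset.
#' @export
write_cohort <- function(dataset, patients_path, visits_path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  patients <- dplyr::mutate(
    dataset$patients,
    dplyr::across(dplyr::all_of(PATIENT_FLAGS), ~ as.integer(.x))
  )
  visits <- dplyr::mutate(dataset$visits, is_preop = as.integer(.data$is_preop))
  readr::write_csv(patients[, PATIENT_COLUMNS], patients_path, na = "", progress = FALSE)
  readr::write_csv(visits[, VISIT_COLUMNS], visits_path, na = "", progress = FALSE)
  invisible(dataset)
}
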