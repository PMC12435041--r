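#' Outcome measures and analysis windows
#'
#' Active range of motion (ROM) is tracked as four measures: abduction,
#' forward elevation and external rotation in degrees, and internal rotation
#' as the ordinal IR score (integer 0-6, hand position reached behind the
#' back). Patient-reported composite scores (VAS pain, global function, ASES,
#' Constant, SAS) are carried as opaque numeric columns for reporting only.
#'
#' @name measures
NULL

#' @rdname measures
#' @export
rom_measures <- function() {
  c("abduction", "forward_elevation", "external_rotation", "ir_score")
}

#' @rdname measures
#' @export
pro_measures <- function() {
  c("vas_pain", "function", "ases", "constant", "sas")
}

all_measures <- function() c(rom_measures(), pro_measures())

is_angle_measure <- function(measure) {
  measure %in% c("abduction", "forward_elevation", "external_rotation")
}

# Valid ranges used by validation: [0, 200] degrees for angles, integer
# [0, 6] for the IR score after half-up rounding.
ANGLE_RANGE <- c(0, 200)
IR_RANGE <- c(0, 6)

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reporting conventions here round half
#' up (away from zero), e.g. a 9.5 degree decline prints as 10.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

round_to_half <- function(x) round_half_up(2 * x) / 2

#' Analysis windows along the months-since-surgery axis
#'
#' Three windows drive the pipeline: the recovery window over which per-visit
#' rates of improvement (ROI) are computed, the peak window within which the
#' highest value of each ROM measure is taken as a patient's peak improvement,
#' and the long-term window whose visits contribute rates of decline (ROD).
#'
#' @param recovery_start,recovery_end recovery window, half-open
#'   `[recovery_start, recovery_end)` months; default 0-24.
#' @param peak_start,peak_end closed peak window in months; default 24-36
#'   (the 2-3 year interval, read inclusively).
#' @param longterm_start left edge (inclusive) of the unbounded long-term
#'   window; default 96 months (8+ years).
#' @return an `analysis_windows` list.
#' @export
analysis_windows <- function(recovery_start = 0, recovery_end = 24,
                             peak_start = 24, peak_end = 36,
                             longterm_start = 96) {
  if (!(recovery_end <= peak_start && peak_start <= peak_end &&
        peak_end <= longterm_start)) {
    rt_abort(
      "analysis windows must be ordered: recovery_end <= peak_start <= peak_end <= longterm_start",
      "romtraj_window_error"
    )
  }
  structure(
    list(
      recovery_start = recovery_start, recovery_end = recovery_end,
      peak_start = peak_start, peak_end = peak_end,
      longterm_start = longterm_start
    ),
    class = "analysis_windows"
  )
}

#' Postoperative interval bins for the recovery period
#'
#' Recovery visits are assigned to nominal follow-up intervals (3, 6, 12 and
#' 24 months) so cohort-average ROI baselines can be computed per interval.
#' Edges sit at the midpoints between scheduled visits, and the 24-month bin
#' extends to 30 months so late "2-year" visits are not orphaned:
#' 3 -> (0, 4.5), 6 -> \[4.5, 9), 12 -> \[9, 18), 24 -> \[18, 30).
#'
#' @return a tibble with columns `nominal_months`, `lower` (inclusive,
#'   except the first bin which is open at 0) and `upper` (exclusive).
#' @export
interval_bins <- function() {
  tibble::tibble(
    nominal_months = c(3, 6, 12, 24),
    lower = c(0, 4.5, 9, 18),
    upper = c(4.5, 9, 18, 30)
  )
}

#' Map visit times to interval bins
#'
#' @param time_months vector of positive months since surgery.
#' @param bins bin table as from [interval_bins()].
#' @return integer-valued vector of nominal bin months; `NA` where the time
#'   falls outside every bin.
#' @export
bin_interval <- function(time_months, bins = interval_bins()) {
  if (any(time_months <= 0, na.rm = TRUE)) {
    rt_abort("bin_interval() requires strictly positive times", "romtraj_domain_error")
  }
  out <- rep(NA_real_, length(time_months))
  for (i in seq_len(nrow(bins))) {
    hit <- !is.na(time_months) &
      time_months >= bins$lower[i] & time_months < bins$upper[i]
    out[hit] <- bins$nominal_months[i]
  }
  out
}
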