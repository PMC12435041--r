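#' Two-sample t-test for continuous factors
#'
#' Two-tailed, unpaired comparison of a continuous factor between trajectory
#' classes. The default is the Welch (unequal-variance) form; set
#' `var_equal = TRUE` for the pooled-variance variant. Degenerate input where
#' both samples are constant returns p = 1 when the means agree (no evidence
#' of a difference) and p = 0 when they differ.
#'
#' @param x,y numeric samples (NAs dropped); each needs n >= 2.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `t_statistic`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    rt_abort("two_sample_t_test() needs at least 2 observations per sample",
             "romtraj_insufficient_data_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t_statistic = if (same) 0 else Inf,
                df = length(x) + length(y) - 2,
                p_value = if (same) 1 else 0))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Ties are accepted within a
#' relative slack of 1e-7 (the conventional tolerance), which makes exact
#' ties robust to floating-point evaluation order. No continuity correction.
#'
#' @param a,b,c,d nonnegative integer cell counts, table rows `(a, b)` and
#'   `(c, d)`.
#' @return the two-sided p-value.
#' @export
fisher_exact_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    rt_abort("cell counts must be nonnegative integers", "romtraj_domain_error")
  }
  if (sum(cells) == 0) {
    rt_abort("table total must be positive", "romtraj_domain_error")
  }
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  support <- max(0, col1 - row2):min(col1, row1)
  probs <- dhyper(support, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on a design matrix
#' that includes an intercept column. Fitting is delegated to the IRLS
#' engine in `stats::glm.fit()`; convergence is declared on the relative
#' deviance change falling below `tol` within `max_iter` iterations. The
#' coefficient covariance is the inverse observed information. Coefficients
#' larger than 15 in absolute value signal (quasi-)separation: the fit is
#' flagged non-converged with a warning, since Wald intervals are then
#' meaningless.
#'
#' @param design numeric design matrix with named columns, intercept included.
#' @param outcome binary (0/1 or logical) response.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return a `logistic_fit` list: `coefficients`, `cov`, `converged`,
#'   `n_iterations`, `n`.
#' @export
fit_logistic_irls <- function(design, outcome, tol = 1e-8, max_iter = 100) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) {
    rt_abort("outcome must be binary (0/1)", "romtraj_domain_error")
  }
  if (!any(apply(design, 2, function(col) all(col == 1)))) {
    rt_abort("design matrix must include an intercept column of ones",
             "romtraj_domain_error")
  }
  if (any(apply(design, 2, function(col) all(col == 0)))) {
    rt_abort("design matrix has a constant-zero column", "romtraj_domain_error")
  }
  fit <- suppressWarnings(glm.fit(
    x = design, y = outcome, family = binomial(),
    control = glm.control(epsilon = tol, maxit = max_iter)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(design, design * w)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, nrow(info), ncol(info),
           dimnames = dimnames(info))
  })
  converged <- isTRUE(fit$converged)
  if (any(abs(beta) > 15, na.rm = TRUE)) {
    warn("logistic fit shows signs of separation (|coefficient| > 15)",
         class = "romtraj_separation_warning")
    converged <- FALSE
  }
  structure(
    list(coefficients = beta, cov = cov, converged = converged,
         n_iterations = fit$iter, n = length(outcome)),
    class = "logistic_fit"
  )
}

#' Wald odds ratios with confidence intervals
#'
#' Per-factor odds ratio `exp(beta)`, Wald `100*(1 - alpha)%` interval
#' `exp(beta +/- z * se)` and two-sided Wald p-value, for every non-intercept
#' coefficient of a converged logistic fit.
#'
#' @param fit a `logistic_fit` from [fit_logistic_irls()].
#' @param alpha significance level (default 0.05).
#' @param reference_group label naming the class the odds are relative to.
#' @return tibble: `factor, odds_ratio, ci_low, ci_high, p_value,
#'   reference_group`.
#' @export
wald_odds_ratios <- function(fit, alpha = 0.05, reference_group = "") {
  if (!isTRUE(fit$converged)) {
    rt_abort("logistic fit did not converge; odds ratios are not interpretable",
             "romtraj_fit_error")
  }
  beta <- fit$coefficients
  se <- sqrt(diag(fit$cov))
  keep <- names(beta) != "(Intercept)"
  nm <- names(beta)[keep]
  beta <- unname(beta[keep])
  se <- unname(se[keep])
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(
    factor = nm,
    odds_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = 2 * pnorm(-abs(beta / se)),
    reference_group = reference_group
  )
}

#' Factor specification for the risk screen
#'
#' @param name display name (unique within a screen).
#' @param type `"continuous"` or `"binary"`.
#' @param source column of the factor frame (defaults to `name`).
#' @return one-row tibble.
#' @export
factor_spec <- function(name, type = c("continuous", "binary"), source = name) {
  type <- match.arg(type)
  tibble::tibble(name = name, type = type, source = source)
}

#' Default factor sets for the two screens
#'
#' The recovery-period screen (`"roi-slow"`) tests demographics, diagnoses,
#' comorbidities, injections and the four preoperative ROM measures. The
#' long-term screen (`"rod-fast"`) tests the same patient factors plus the
#' radiographic/complication fields, without preoperative ROM.
#'
#' @param comparison `"roi-slow"` or `"rod-fast"`.
#' @return tibble of factor specs.
#' @export
default_screen_factors <- function(comparison = c("roi-slow", "rod-fast")) {
  comparison <- match.arg(comparison)
  base <- dplyr::bind_rows(
    factor_spec("age", "continuous", "age_years"),
    factor_spec("female", "binary", "sex_female"),
    factor_spec("bmi", "continuous"),
    factor_spec("previous_surgery", "binary"),
    factor_spec("injections", "binary"),
    factor_spec("osteoarthritis", "binary", "dx_osteoarthritis"),
    factor_spec("osteonecrosis", "binary", "dx_osteonecrosis"),
    factor_spec("rotator_cuff_tear", "binary", "dx_rotator_cuff_tear"),
    factor_spec("cuff_tear_arthropathy", "binary", "dx_cuff_tear_arthropathy"),
    factor_spec("rheumatoid_arthritis", "binary", "dx_rheumatoid_arthritis"),
    factor_spec("no_comorbidity", "binary", "cm_none"),
    factor_spec("hypertension", "binary", "cm_hypertension"),
    factor_spec("heart_disease", "binary", "cm_heart_disease"),
    factor_spec("diabetes", "binary", "cm_diabetes"),
    factor_spec("tobacco_use", "binary", "cm_tobacco"),
    factor_spec("chronic_renal_failure", "binary", "cm_renal_failure")
  )
  if (comparison == "roi-slow") {
    dplyr::bind_rows(
      base,
      factor_spec("preop_abduction", "continuous"),
      factor_spec("preop_forward_elevation", "continuous"),
      factor_spec("preop_ir_score", "continuous"),
      factor_spec("preop_external_rotation", "continuous")
    )
  } else {
    dplyr::bind_rows(
      base,
      factor_spec("humeral_rll", "binary"),
      factor_spec("glenoid_rll", "binary"),
      factor_spec("glenoid_rll_grade", "continuous"),
      factor_spec("scapular_notching", "binary"),
      factor_spec("notching_grade", "continuous"),
      factor_spec("complication", "binary"),
      factor_spec("revision", "binary")
    )
  }
}

#' One row per patient with every screenable covariate
#'
#' Joins the patient table with derived columns: `sex_female`,
#' `any_comorbidity`, and the preoperative value of each ROM measure spread
#' wide as `preop_<measure>`.
#'
#' @param dataset a [cohort_dataset()].
#' @return tibble keyed by `patient_id`.
#' @export
build_factor_frame <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  preop <- dataset$visits |>
    dplyr::filter(.data$is_preop, .data$measure %in% rom_measures()) |>
    dplyr::select("patient_id", "measure", "value") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value",
                       names_prefix = "preop_")
  dataset$patients |>
    dplyr::mutate(
      sex_female = .data$sex == "F",
      any_comorbidity = !.data$cm_none
    ) |>
    dplyr::left_join(preop, by = "patient_id")
}

summarise_factor <- function(values, type) {
  if (type == "continuous") {
    sprintf("%.1f ± %.1f", mean(values), sd(values))
  } else {
    sprintf("%.1f%%", 100 * mean(values))
  }
}

#' Univariate-to-multivariate risk-factor screen
#'
#' Reproduces the two-stage screen used to find factors associated with slow
#' recovery or fast long-term decline, run separately per prosthesis:
#'
#' 1. Univariate comparison of each factor between the index class and the
#'    pooled remainder -- Welch t-test for continuous factors, Fisher's exact
#'    test for binary factors. No multiple-testing adjustment is applied.
#' 2. Factors with univariate p < `alpha` enter a single multivariate
#'    logistic regression of class membership (complete cases across the
#'    entered factors); odds ratios carry Wald 95% confidence intervals.
#'    Binary factors with an empty cell in either class are completely
#'    separated (their maximum-likelihood odds ratio is infinite), so they
#'    are reported univariate-only and listed in the
#'    `"excluded_zero_cell"` attribute.
#'
#' `comparison = "roi-slow"` contrasts SLOW-ROI patients against fast/average
#' ROI; `comparison = "rod-fast"` contrasts FAST-ROD patients against
#' slow/average ROD. UNCLASSIFIED patients are excluded.
#'
#' @param dataset a [cohort_dataset()].
#' @param labels classification results from [classify_cohort()] of the
#'   matching kind.
#' @param comparison `"roi-slow"` or `"rod-fast"`.
#' @param prosthesis `"aTSA"` or `"rTSA"` (the screen is fit per prosthesis).
#' @param factors factor specs; defaults to
#'   [default_screen_factors()]`(comparison)`.
#' @param alpha significance level for univariate entry and the CIs.
#' @return tibble mirroring a risk-factor table: `factor, type,
#'   group1_summary, group2_summary, p_univariate, p_multivariate,
#'   odds_ratio, ci_low, ci_high, reference_group`; attributes `"fit"` (the
#'   logistic fit or `NULL`) and `"n_groups"`.
#' @export
run_screen <- function(dataset, labels, comparison = c("roi-slow", "rod-fast"),
                       prosthesis = c("aTSA", "rTSA"), factors = NULL,
                       alpha = 0.05) {
  comparison <- match.arg(comparison)
  prosthesis <- match.arg(prosthesis)
  if (is.null(factors)) factors <- default_screen_factors(comparison)
  if (anyDuplicated(factors$name) > 0) {
    rt_abort("factor names must be unique within a screen", "romtraj_domain_error")
  }

  index_label <- if (comparison == "roi-slow") "SLOW" else "FAST"
  reference_group <- if (comparison == "roi-slow") {
    "fast/average ROI"
  } else {
    "slow/average ROD"
  }

  lab <- labels[labels$label != "UNCLASSIFIED" &
                  labels$prosthesis == prosthesis, ]
  frame <- build_factor_frame(dataset)
  frame <- dplyr::inner_join(frame, lab[, c("patient_id", "label")],
                             by = "patient_id")
  frame$outcome <- as.integer(frame$label == index_label)
  n1 <- sum(frame$outcome == 1)
  n0 <- sum(frame$outcome == 0)
  if (n1 < 2 || n0 < 2) {
    rt_abort(
      sprintf("risk screen needs >= 2 patients per class (index %d, rest %d)",
              n1, n0),
      "romtraj_class_size_error"
    )
  }

  uni <- purrr::pmap_dfr(factors, function(name, type, source) {
    v <- frame[[source]]
    if (is.null(v)) {
      rt_abort(sprintf("factor source column '%s' not found", source),
               "romtraj_schema_error")
    }
    v <- if (type == "binary") as.logical(v) else as.numeric(v)
    ok <- !is.na(v)
    g1 <- v[ok & frame$outcome == 1]
    g0 <- v[ok & frame$outcome == 0]
    p <- if (type == "continuous") {
      two_sample_t_test(g0, g1)$p_value
    } else {
      fisher_exact_test(sum(g1), sum(!g1), sum(g0), sum(!g0))
    }
    tibble::tibble(
      factor = name, type = type, source = source,
      group1_summary = summarise_factor(g1, type),
      group2_summary = summarise_factor(g0, type),
      p_univariate = p
    )
  })

  sig <- uni[uni$p_univariate < alpha, ]
  # binary factors with an empty cell in either class separate completely:
  # their ML odds ratio is inestimable, so they stay univariate-only
  zero_cell <- vapply(seq_len(nrow(sig)), function(i) {
    if (sig$type[i] != "binary") return(FALSE)
    v <- as.logical(frame[[sig$source[i]]])
    any(vapply(split(v, frame$outcome), function(z) {
      length(unique(z[!is.na(z)])) < 2
    }, logical(1)))
  }, logical(1))
  excluded <- sig$factor[zero_cell]
  sig <- sig[!zero_cell, , drop = FALSE]
  fit <- NULL
  multi <- tibble::tibble(factor = character(), p_multivariate = double(),
                          odds_ratio = double(), ci_low = double(),
                          ci_high = double())
  if (nrow(sig) > 0) {
    cols <- sig$source
    sub <- frame[, c("outcome", cols)]
    sub <- sub[complete.cases(sub), ]
    design <- cbind(`(Intercept)` = 1,
                    as.matrix(dplyr::mutate(sub[, cols, drop = FALSE],
                                            dplyr::across(dplyr::everything(),
                                                          as.numeric))))
    colnames(design) <- c("(Intercept)", sig$factor)
    fit <- fit_logistic_irls(design, sub$outcome)
    if (fit$converged) {
      ors <- wald_odds_ratios(fit, alpha = alpha,
                              reference_group = reference_group)
      multi <- dplyr::transmute(
        ors,
        factor = .data$factor, p_multivariate = .data$p_value,
        odds_ratio = .data$odds_ratio, ci_low = .data$ci_low,
        ci_high = .data$ci_high
      )
    }
  }

  out <- dplyr::left_join(uni, multi, by = "factor") |>
    dplyr::mutate(reference_group = reference_group) |>
    dplyr::select("factor", "type", "group1_summary", "group2_summary",
                  "p_univariate", "p_multivariate", "odds_ratio",
                  "ci_low", "ci_high", "reference_group")
  attr(out, "fit") <- fit
  attr(out, "n_groups") <- c(index = n1, rest = n0)
  attr(out, "excluded_zero_cell") <- excluded
  out
}
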