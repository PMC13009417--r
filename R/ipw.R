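# Inverse-probability weights for informative outcome measurement and
# adherence censoring. Both models are pooled logistic regressions across
# person-months with a restricted cubic spline in month; measurement weights
# are per-month (missingness is intermittent, not monotone), censoring
# weights are cumulative (artificial censoring is monotone).

#' Weight-model specification
#'
#' @param baseline cohort covariate columns entering both weight models.
#' @param time_varying panel covariate columns (default the last measured
#'   weight change entering the month, `"lwc"`).
#' @param use_arm include arm indicators in the weight models.
#' @param time_trend `"spline"` (restricted cubic spline in month, default)
#'   or `"factor"` (a dummy per month).
#' @param n_knots spline knots for the time trend.
#' @param stabilized use a stabilized numerator (arm + time trend model)
#'   instead of 1 (default unstabilized, relying on percentile truncation).
#' @return object of class `ipw_spec`.
#' @export
ipw_spec <- function(baseline = c("obesity", "age10", "sexF"),
                     time_varying = "lwc", use_arm = TRUE,
                     time_trend = c("spline", "factor"), n_knots = 4L,
                     stabilized = FALSE) {
  structure(list(baseline = baseline, time_varying = time_varying,
                 use_arm = use_arm, time_trend = match.arg(time_trend),
                 n_knots = n_knots, stabilized = stabilized),
            class = "ipw_spec")
}

# Newton/IRLS logistic solver on a frozen design matrix via normal
# equations; with a warm start it converges in 1-3 iterations, which keeps
# bootstrap replicates cheap. Falls back to glm.fit when it fails.
logit_irls <- function(X, y, w = NULL, start = NULL, tol = 1e-7,
                       maxit = 30L, label = "weight model", guard = TRUE) {
  if (is.null(w)) w <- rep(1, length(y))
  beta <- start %||% c(qlogis(clip(sum(w * y) / sum(w), 0.01, 0.99)),
                       numeric(ncol(X) - 1L))
  fit <- cpp_logit_irls(X, y, w, beta, tol, maxit)
  if (!isTRUE(fit$ok)) {
    return(fast_logit(X, y, w, start = NULL, label = label, guard = guard))
  }
  beta <- drop(fit$beta)
  # inverted-probability models must not drift toward separation; outcome
  # models (guard = FALSE) may legitimately carry huge logits in empty cells
  if (guard && max(abs(beta)) > 30) {
    stop2(label, ": did not converge (possible separation); ",
          "largest coefficient on '", colnames(X)[which.max(abs(beta))], "'")
  }
  names(beta) <- colnames(X)
  beta
}

# logistic IRLS with explicit design matrix; errors are descriptive because
# weight models failing silently would corrupt every downstream estimate
fast_logit <- function(X, y, w = NULL, start = NULL, label = "weight model",
                       guard = TRUE) {
  if (is.null(w)) w <- rep(1, length(y))
  keep <- w > 0
  fit <- suppressWarnings(
    stats::glm.fit(X[keep, , drop = FALSE], y[keep], weights = w[keep],
                   family = stats::binomial(), start = start,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  co <- fit$coefficients
  if (anyNA(co)) {
    stop2(label, ": design matrix rank-deficient; aliased column(s): ",
          paste(colnames(X)[is.na(co)], collapse = ", "))
  }
  if (!fit$converged || (guard && max(abs(co)) > 30)) {
    worst <- colnames(X)[which.max(abs(co))]
    stop2(label, ": did not converge (possible separation); ",
          "largest coefficient on '", worst, "'")
  }
  co
}

# design matrix for the weight models on a set of person-month rows that
# already carry both cohort and panel columns
ipw_design <- function(rows, spec, arms, knots = NULL) {
  n <- nrow(rows)
  parts <- list(`(Intercept)` = rep(1, n))
  if (spec$use_arm && length(arms) > 1L) {
    for (a in arms[-1L]) parts[[paste0("arm", a)]] <- as.numeric(rows$arm == a)
  }
  for (nm in c(spec$baseline, spec$time_varying)) {
    v <- rows[[nm]]
    if (is.null(v)) stop2("weight-model covariate '", nm, "' not found in panel")
    parts[[nm]] <- as.numeric(v)
  }
  if (spec$time_trend == "spline") {
    tb <- rcs_basis(rows$month, knots = knots, n_knots = spec$n_knots)
    knots <- attr(tb, "knots")
    for (j in seq_len(ncol(tb))) parts[[paste0("t_", colnames(tb)[j])]] <- tb[, j]
  } else {
    mo <- sort(unique(rows$month))
    for (m in mo[-1L]) parts[[paste0("month", m)]] <- as.numeric(rows$month == m)
    knots <- NULL
  }
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  attr(X, "knots") <- knots
  X
}

# columns of the numerator (stabilizing) model: intercept, arm, time trend
ipw_numerator_cols <- function(X, spec) {
  drop <- c(spec$baseline, spec$time_varying)
  setdiff(colnames(X), drop)
}

#' Fit inverse-probability-of-measurement weights
#'
#' One pooled logistic model for `P(measured | baseline covariates,
#' time-varying covariates, time trend)` across person-months; measured rows
#' get `w_meas = 1 / p` (or the stabilized ratio). Fitted probabilities are
#' floored away from 0/1 before inversion; percentile truncation downstream
#' governs the extremes.
#'
#' @param panel person-month panel joined with the cohort covariates (or a
#'   raw panel plus `cohort`).
#' @param cohort cohort table (ignored when `panel` already carries the
#'   covariates).
#' @param spec an [ipw_spec()].
#' @param case_w optional per-row case weights (bootstrap multiplicities).
#' @return list of class `meas_weights`: `table` (`patient_id`, `month`,
#'   `p_meas`, `w_meas`), `coef`, `knots`.
#' @export
fit_measurement_weights <- function(panel, cohort = NULL, spec = ipw_spec(),
                                    case_w = NULL) {
  rows <- join_covariates(panel, cohort, spec)
  arms <- levels(factor(rows$arm))
  X <- ipw_design(rows, spec, arms)
  empty <- setdiff(unique(rows$month), rows[measured == 1L, unique(month)])
  if (length(empty)) {
    warning("no measured rows in month(s) ", paste(empty, collapse = ", "),
            "; the pooled time trend interpolates there")
  }
  co <- fast_logit(X, rows$measured, w = case_w, label = "measurement model")
  p <- clip(plogis(drop(X %*% co)), PROB_FLOOR, 1 - PROB_FLOOR)
  num <- rep(1, nrow(rows))
  co_num <- NULL
  if (spec$stabilized) {
    Xn <- X[, ipw_numerator_cols(X, spec), drop = FALSE]
    co_num <- fast_logit(Xn, rows$measured, w = case_w,
                         label = "measurement numerator model")
    num <- clip(plogis(drop(Xn %*% co_num)), PROB_FLOOR, 1 - PROB_FLOOR)
  }
  tab <- data.table(patient_id = rows$patient_id, month = rows$month,
                    measured = rows$measured, p_meas = p, w_meas = num / p)
  list(table = tab, coef = co, coef_num = co_num,
       knots = attr(X, "knots"), spec = spec)
}

# at-risk person-months for the stop hazard: patient is at risk in month k
# while still adherent entering k (k <= event month) and still in the panel
at_risk_rows <- function(panel, censor_info) {
  ci <- copy(as.data.table(censor_info))
  ci[, stop_month := fifelse(is.na(censor_month), NA_integer_,
                             pmax(0L, month_of_day(exhaustion_day)))]
  p <- ci[, .(patient_id, stop_month)][panel, on = "patient_id"]
  p[is.na(stop_month) | month <= stop_month]
}

#' Fit inverse-probability-of-censoring (adherence) weights
#'
#' Pooled logistic model for the monthly hazard of deviating from the
#' assigned strategy, fit on person-months at risk (still adherent entering
#' the month), using covariates known entering the month. A row at month `t`
#' stays in the per-protocol analysis iff the patient survived the stop
#' hazard in months `1..t-1`, so its weight is the inverse cumulative
#' product of the fitted continuation probabilities through `t - 1`
#' (`w = 1` at month 1). When no one deviates the model is skipped and all
#' weights are exactly 1.
#'
#' @param panel person-month panel (joined or join-able with `cohort`).
#' @param censor_info per-patient censor table from `compute_censor_info()`.
#' @param cohort cohort table.
#' @param spec an [ipw_spec()].
#' @param case_w optional per-row case weights, aligned with the panel rows.
#' @return list of class `cens_weights`: `table` (`patient_id`, `month`,
#'   `p_cont`, `w_cens`) for rows retained in the per-protocol analysis,
#'   `coef`, `n_events`.
#' @export
fit_adherence_weights <- function(panel, censor_info, cohort = NULL,
                                  spec = ipw_spec(), case_w = NULL) {
  rows <- join_covariates(panel, cohort, spec)
  if (!is.null(case_w)) set(rows, j = "case_w", value = case_w)
  ci <- as.data.table(censor_info)
  ar <- at_risk_rows(rows, ci)
  ar[, event := as.integer(!is.na(stop_month) & month == stop_month)]
  n_events <- sum(ar$event)
  arms <- levels(factor(rows$arm))
  co <- NULL
  co_num <- NULL
  if (n_events > 0L) {
    X <- ipw_design(ar, spec, arms)
    co <- fast_logit(X, ar$event, w = ar$case_w, label = "adherence model")
    h <- clip(plogis(drop(X %*% co)), PROB_FLOOR, 1 - PROB_FLOOR)
    hn <- rep(0, nrow(ar))
    if (spec$stabilized) {
      Xn <- X[, ipw_numerator_cols(X, spec), drop = FALSE]
      co_num <- fast_logit(Xn, ar$event, w = ar$case_w,
                           label = "adherence numerator model")
      hn <- clip(plogis(drop(Xn %*% co_num)), PROB_FLOOR, 1 - PROB_FLOOR)
    }
    ar[, `:=`(p_cont = 1 - h, p_cont_num = 1 - hn)]
  } else {
    ar[, `:=`(p_cont = 1, p_cont_num = 1)]
  }
  setorder(ar, patient_id, month)
  # inclusion of month t requires surviving hazards 1..t-1: lagged cumprod
  ar[, w_cens := {
    surv <- cumprod(p_cont)
    surv_num <- cumprod(p_cont_num)
    lag_s <- shift(surv, fill = 1)
    lag_n <- shift(surv_num, fill = 1)
    lag_n / lag_s
  }, by = patient_id]
  # retained rows: strictly before the censor month (and all rows when none)
  keep <- ci[, .(patient_id, censor_month)][ar, on = "patient_id"]
  keep <- keep[is.na(censor_month) | month < censor_month]
  list(table = keep[, .(patient_id, month, p_cont, w_cens)],
       coef = co, coef_num = co_num, n_events = n_events, spec = spec)
}

#' Combine measurement and censoring weights and truncate
#'
#' `w = w_meas * w_cens` over the measured (and, per-protocol, uncensored)
#' person-month rows; values above the empirical `percentile` (an inverse-
#' ECDF order statistic of the combined weights over those rows) are capped
#' at it. `percentile = 100` disables truncation.
#'
#' @param meas a `meas_weights` fit.
#' @param cens optional `cens_weights` fit (per-protocol mode).
#' @param percentile truncation percentile (default 99).
#' @param case_w optional named-by-row case weights: a `data.table`
#'   (`patient_id`, `case_w`) used when truncating under bootstrap
#'   multiplicities.
#' @return `data.table` (`patient_id`, `month`, `w_meas`, `w_cens`,
#'   `w_comb`, `w_trunc`) for outcome-model rows, with the cap in
#'   `attr(, "cap")`.
#' @export
combine_and_truncate <- function(meas, cens = NULL, percentile = 99,
                                 case_w = NULL) {
  stopifnot(percentile > 0, percentile <= 100)
  wt <- meas$table[measured == 1L, .(patient_id, month, w_meas)]
  if (!is.null(cens)) {
    wt <- wt[cens$table[, .(patient_id, month, w_cens)],
             on = .(patient_id, month), nomatch = NULL]
  } else {
    wt[, w_cens := 1]
  }
  wt[, w_comb := w_meas * w_cens]
  cw <- NULL
  if (!is.null(case_w)) {
    wt <- as.data.table(case_w)[wt, on = "patient_id"]
    wt <- wt[case_w > 0]
    cw <- wt$case_w
  }
  cap <- if (percentile >= 100) max(wt$w_comb) else
    quantile_type1(wt$w_comb, percentile / 100, w = cw)
  wt[, w_trunc := pmin(w_comb, cap)]
  if (!is.null(case_w)) wt[, case_w := NULL]
  setattr(wt, "cap", cap)
  setattr(wt, "percentile", percentile)
  wt[]
}

# join cohort covariates onto panel rows once (no-op if already joined)
join_covariates <- function(panel, cohort, spec) {
  p <- as.data.table(panel)
  need <- unique(c("arm", spec$baseline))
  have <- need %in% names(p)
  if (all(have)) return(copy(p))
  if (is.null(cohort)) {
    stop2("panel lacks column(s) ", paste(need[!have], collapse = ", "),
          " and no cohort was supplied")
  }
  coh <- as.data.table(cohort)
  cols <- unique(c("patient_id", need[need %in% names(coh)]))
  coh[, ..cols][p, on = "patient_id"]
}
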