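# Weighted repeated-outcomes marginal structural model: weight change on
# arm, restricted cubic spline in month, arm-by-spline interactions and
# baseline covariates, fit by weighted least squares; standardized per-arm
# means by g-computation over the cohort's baseline-covariate distribution.
# Point estimation ignores within-patient correlation; interval estimation
# is by patient-level bootstrap.

#' Time-spline specification for the outcome model
#' @param n_knots number of restricted-cubic-spline knots (default 4).
#' @param knot_quantiles quantiles of the fitted rows' months at which knots
#'   are placed.
#' @param time_trend `"spline"` (default) or `"factor"` (dummy per month).
#' @return object of class `spline_spec`.
#' @export
spline_spec <- function(n_knots = 4L, knot_quantiles = c(0.05, 0.35, 0.65, 0.95),
                        time_trend = c("spline", "factor")) {
  structure(list(n_knots = n_knots, knot_quantiles = knot_quantiles,
                 time_trend = match.arg(time_trend)),
            class = "spline_spec")
}

# time basis for the outcome model (shared by fit and prediction)
msm_time_basis <- function(month, spec, knots = NULL, month_levels = NULL) {
  if (spec$time_trend == "spline") {
    tb <- rcs_basis(month, knots = knots, n_knots = spec$n_knots,
                    knot_quantiles = spec$knot_quantiles)
  } else {
    lev <- month_levels %||% sort(unique(month))
    tb <- vapply(lev[-1L], function(m) as.numeric(month == m),
                 numeric(length(month)))
    tb <- matrix(tb, nrow = length(month),
                 dimnames = list(NULL, paste0("month", lev[-1L])))
    attr(tb, "levels") <- lev
  }
  tb
}

# full design: intercept | arm dummies | time basis | arm x time | covariates
msm_design <- function(arm, month, covmat, arms, spec, knots = NULL,
                       month_levels = NULL) {
  n <- length(month)
  tb <- msm_time_basis(month, spec, knots, month_levels)
  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  if (length(arms) > 1L) {
    A <- vapply(arms[-1L], function(a) as.numeric(arm == a), numeric(n))
    A <- matrix(A, nrow = n, dimnames = list(NULL, paste0("arm", arms[-1L])))
    blocks$arm <- A
  }
  blocks$time <- tb
  if (length(arms) > 1L) {
    inter <- do.call(cbind, lapply(arms[-1L], function(a) {
      ai <- as.numeric(arm == a)
      ib <- tb * ai
      colnames(ib) <- paste0("arm", a, ":", colnames(tb))
      ib
    }))
    blocks$inter <- inter
  }
  if (!is.null(covmat) && ncol(covmat)) blocks$cov <- covmat
  X <- do.call(cbind, blocks)
  attr(X, "knots") <- attr(tb, "knots")
  attr(X, "month_levels") <- attr(tb, "levels")
  X
}

cov_matrix <- function(dt, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(dt))
  if (length(miss)) stop2("covariate(s) not found: ", paste(miss, collapse = ", "))
  m <- as.matrix(as.data.table(dt)[, lapply(.SD, as.numeric), .SDcols = covariates])
  colnames(m) <- covariates
  m
}

#' Fit the weighted repeated-outcomes model
#'
#' Weighted least squares of monthly weight change on arm indicators
#' (reference = first arm), a restricted cubic spline in month,
#' arm-by-spline interactions and baseline covariates, over measured (and,
#' per-protocol, uncensored) person-month rows with truncated
#' inverse-probability weights.
#'
#' @param panel person-month panel rows carrying `y` (joined or join-able
#'   with the cohort covariates).
#' @param weights weight table from [combine_and_truncate()] (its `w_trunc`
#'   is used), or a numeric vector aligned with the fitted rows.
#' @param cohort cohort table supplying covariates and the arm labels.
#' @param covariates baseline covariate columns (default obesity, age/10,
#'   female sex).
#' @param spec a [spline_spec()].
#' @param arms arm levels (default: reference-first order from the cohort).
#' @return object of class `msm_fit`: coefficients, knots, arm levels,
#'   covariate names, and weighted-fit metadata.
#' @export
fit_msm <- function(panel, weights, cohort = NULL,
                    covariates = c("obesity", "age10", "sexF"),
                    spec = spline_spec(), arms = NULL) {
  rows <- join_msm_rows(panel, weights, cohort, covariates)
  arms <- arms %||% arm_levels(cohort %||% rows)
  core <- msm_core(rows, arms, covariates, spec)
  structure(core, class = "msm_fit")
}

# shared fitting core on a prepared row table (y, arm, month, covariates, w)
msm_core <- function(rows, arms, covariates, spec, knots = NULL,
                     month_levels = NULL) {
  if (any(!is.finite(rows$w))) stop2("non-finite weights in outcome fit")
  X <- msm_design(rows$arm, rows$month, cov_matrix(rows, covariates), arms,
                  spec, knots, month_levels)
  fit <- stats::lm.wfit(X, rows$y, rows$w)
  if (anyNA(fit$coefficients)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop2("outcome design matrix rank-deficient on the fitted rows; ",
          "aliased: ", paste(bad, collapse = ", "))
  }
  list(coef = fit$coefficients, arms = arms, covariates = covariates,
       spec = spec, knots = attr(X, "knots"),
       month_levels = attr(X, "month_levels"),
       n_rows = nrow(X), weight_range = range(rows$w))
}

join_msm_rows <- function(panel, weights, cohort, covariates) {
  p <- as.data.table(panel)
  need <- unique(c("arm", covariates))
  have <- need %in% names(p)
  if (!all(have)) {
    if (is.null(cohort)) stop2("panel lacks ", paste(need[!have], collapse = ", "))
    coh <- as.data.table(cohort)
    cols <- unique(c("patient_id", need[need %in% names(coh)]))
    p <- coh[, ..cols][p, on = "patient_id"]
  }
  if (is.data.frame(weights)) {
    w <- as.data.table(weights)
    wcol <- if ("w_trunc" %in% names(w)) "w_trunc" else "w"
    p <- w[, c("patient_id", "month", wcol), with = FALSE][
      p, on = .(patient_id, month), nomatch = NULL]
    setnames(p, wcol, "w")
  } else {
    p <- p[measured == 1L]
    set(p, j = "w", value = rep_len(weights %||% 1, nrow(p)))
  }
  p[measured == 1L & is.finite(y)]
}

arm_levels <- function(x) {
  a <- unique(as.character(x$arm))
  known <- default_arms()
  c(intersect(known, a), sort(setdiff(a, known)))
}

#' Standardized mean weight change under assignment to an arm
#'
#' G-computation: every cohort member's arm indicator is set to `arm`, the
#' fitted mean at `month` is evaluated, and predictions are averaged over
#' the cohort (optionally with per-patient weights, e.g. bootstrap
#' multiplicities). With no covariates in the model this collapses exactly
#' to the fitted arm-month value.
#'
#' @param fit an `msm_fit`.
#' @param cohort cohort whose baseline-covariate distribution to average
#'   over.
#' @param arm,month target arm(s) and month(s) (vectorized; months 1..24).
#' @param case_w optional per-cohort-row weights.
#' @return numeric vector of standardized means (kg).
#' @export
standardize <- function(fit, cohort, arm, month, case_w = NULL) {
  grid <- data.table(arm = arm, month = month)
  if (any(grid$month < 1L | grid$month > FOLLOWUP_MONTHS)) {
    stop2("month must be in 1..", FOLLOWUP_MONTHS)
  }
  covlin <- standardized_covlin(fit, cohort, case_w)
  vapply(seq_len(nrow(grid)), function(i) {
    eta_base(fit, grid$arm[i], grid$month[i]) + covlin
  }, numeric(1))
}

# mean linear contribution of the baseline covariates over the cohort
standardized_covlin <- function(fit, cohort, case_w = NULL) {
  if (!length(fit$covariates)) return(0)
  cm <- cov_matrix(cohort, fit$covariates)
  if (is.null(case_w)) case_w <- rep(1, nrow(cm))
  drop(crossprod(colSums(cm * case_w) / sum(case_w),
                 fit$coef[fit$covariates]))
}

# linear predictor at (arm, month) with covariates at zero
eta_base <- function(fit, arm, month) {
  X <- msm_design(arm, month, NULL, fit$arms, fit$spec, knots = fit$knots,
                  month_levels = fit$month_levels)
  nz <- intersect(colnames(X), names(fit$coef))
  drop(X[, nz, drop = FALSE] %*% fit$coef[nz])
}

#' Contrasts of standardized means versus the reference arm
#'
#' @param means `data.table` with `arm`, `month`, `mean_change`.
#' @param reference reference arm label (default `"lisinopril"`).
#' @return the table with a `contrast_vs_ref` column added (reference rows
#'   are exactly 0).
#' @export
arm_contrasts <- function(means, reference = "lisinopril") {
  m <- copy(as.data.table(means))
  ref <- m[arm == reference, .(month, ref_mean = mean_change)]
  m <- ref[m, on = "month"]
  m[, contrast_vs_ref := mean_change - ref_mean]
  m[, ref_mean := NULL]
  setorder(m, month, arm)
  m[]
}

#' Standardized risks of gaining >= 5% of baseline weight, and risk ratios
#'
#' Weighted pooled logistic regression of the 5%-gain flag on the same
#' design as the outcome model; risks are standardized by averaging
#' predicted probabilities over the cohort under each arm assignment;
#' `rr_vs_ref = risk(arm) / risk(reference)` (1 for the reference by
#' construction, `NA` with a warning when the reference risk is 0).
#'
#' @param panel person-month rows with `gain5`.
#' @param weights weight table (as in [fit_msm()]).
#' @param cohort cohort table.
#' @param months months at which to report (default 6, 12, 24).
#' @param covariates,spec as in [fit_msm()].
#' @param reference reference arm.
#' @param arms arm levels.
#' @param case_w optional per-patient bootstrap multiplicities
#'   (`data.table(patient_id, case_w)`).
#' @return `data.table` (`arm`, `month`, `risk5`, `rr_vs_ref`).
#' @export
risk_5pct_rr <- function(panel, weights, cohort, months = c(6L, 12L, 24L),
                         covariates = c("obesity", "age10", "sexF"),
                         spec = spline_spec(), reference = "lisinopril",
                         arms = NULL, case_w = NULL) {
  rows <- join_msm_rows(panel, weights, cohort, covariates)
  arms <- arms %||% arm_levels(cohort)
  if (sum(rows$gain5, na.rm = TRUE) == 0) {
    warning("no 5%-gain events anywhere; risks are 0 and RR undefined")
    out <- CJ(arm = arms, month = as.integer(months), sorted = FALSE)
    out[, `:=`(risk5 = 0,
               rr_vs_ref = fifelse(arm == reference, 1, NA_real_))]
    setorder(out, month, arm)
    return(out[])
  }
  rfit <- risk_core(rows, arms, covariates, spec)
  risk_standardize(rfit, cohort, arms, months, reference, case_w)
}

risk_core <- function(rows, arms, covariates, spec, knots = NULL,
                      month_levels = NULL, start = NULL) {
  X <- msm_design(rows$arm, rows$month, cov_matrix(rows, covariates), arms,
                  spec, knots, month_levels)
  co <- fast_logit(X, rows$gain5, w = rows$w, start = start,
                   label = "5%-gain model", guard = FALSE)
  list(coef = co, arms = arms, covariates = covariates, spec = spec,
       knots = attr(X, "knots"), month_levels = attr(X, "month_levels"))
}

risk_standardize <- function(rfit, cohort, arms, months, reference,
                             case_w = NULL) {
  covlin <- if (length(rfit$covariates)) {
    drop(cov_matrix(cohort, rfit$covariates) %*% rfit$coef[rfit$covariates])
  } else 0
  if (is.null(case_w)) case_w <- rep(1, nrow(as.data.table(cohort)))
  out <- CJ(arm = arms, month = as.integer(months), sorted = FALSE)
  out[, risk5 := vapply(seq_len(.N), function(i) {
    eta <- eta_base(rfit, arm[i], month[i]) + covlin
    sum(plogis(eta) * case_w) / sum(case_w)
  }, numeric(1))]
  ref <- out[arm == reference, .(month, ref_risk = risk5)]
  out <- ref[out, on = "month"]
  zero_ref <- out[arm != reference & ref_risk == 0, unique(month)]
  if (length(zero_ref)) {
    warning("reference risk is 0 at month(s) ",
            paste(zero_ref, collapse = ", "), "; RR undefined")
  }
  out[, rr_vs_ref := fifelse(arm == reference, 1,
                             fifelse(ref_risk > 0, risk5 / ref_risk, NA_real_))]
  out[, ref_risk := NULL]
  setorder(out, month, arm)
  out[]
}
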