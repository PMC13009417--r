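# End-to-end wiring: cohort -> adherence (PP) -> weights -> MSM ->
# standardization -> contrasts / 5%-gain risks. The pipeline is split into
# prepare_analysis() (build panel, censor info and all model matrices once)
# and fit_analysis() (fit weight models and the MSM given per-patient case
# weights), so the patient-level bootstrap can refit every model per
# replicate by reweighting rows instead of resampling tables.

#' Analysis run configuration
#'
#' @param mode `"pp"` (per-protocol: censor at deviation, measurement and
#'   adherence weights) or `"io"` (initiation-only: measurement weights
#'   only).
#' @param reference reference arm for contrasts and risk ratios.
#' @param months_of_interest report months (subset of 1..24; default 6, 12,
#'   24).
#' @param n_boot bootstrap replicates (production default 1000).
#' @param boot_seed master bootstrap seed.
#' @param truncation_percentile weight-truncation percentile (default 99).
#' @param grace_days adherence grace period in days (default 30).
#' @param censor_on_switch treat initiation of a second study drug as a
#'   deviation (default `FALSE`: deviation means discontinuation only).
#' @param stockpile end-to-end consumption of overlapping fills (default
#'   `FALSE`: coverage unions).
#' @param ipw an [ipw_spec()].
#' @param covariates baseline covariates for the outcome model.
#' @param spline a [spline_spec()] for the outcome model.
#' @param include_risk also fit the 5%-gain model (default `TRUE`).
#' @param arms study drug labels.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("pp", "io"), reference = "lisinopril",
                       months_of_interest = c(6L, 12L, 24L),
                       n_boot = 1000L, boot_seed = 20260101L,
                       truncation_percentile = 99, grace_days = 30L,
                       censor_on_switch = FALSE, stockpile = FALSE,
                       ipw = ipw_spec(),
                       covariates = c("obesity", "age10", "sexF"),
                       spline = spline_spec(), include_risk = TRUE,
                       arms = default_arms()) {
  mode <- match.arg(mode)
  months_of_interest <- as.integer(months_of_interest)
  if (any(months_of_interest < 1L | months_of_interest > FOLLOWUP_MONTHS)) {
    stop2("configuration error: 'months_of_interest' must lie in 1..24")
  }
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  if (truncation_percentile <= 0 || truncation_percentile > 100) {
    stop2("configuration error: 'truncation_percentile' must be in (0, 100]")
  }
  if (!reference %in% arms) {
    stop2("configuration error: reference arm '", reference,
          "' is not among the arms")
  }
  structure(list(mode = mode, reference = reference,
                 months_of_interest = months_of_interest, n_boot = n_boot,
                 boot_seed = as.integer(boot_seed),
                 truncation_percentile = truncation_percentile,
                 grace_days = grace_days, censor_on_switch = censor_on_switch,
                 stockpile = stockpile, ipw = ipw, covariates = covariates,
                 spline = spline, include_risk = include_risk, arms = arms),
            class = "run_config")
}

#' Prepare an analysis: cohort, panel, censoring, model matrices
#'
#' Runs eligibility, panel construction and (per-protocol) adherence
#' reconstruction, then freezes the design matrices of the measurement
#' model, the censoring model and the outcome model, together with
#' per-patient row maps. Everything downstream (point fit, bootstrap
#' replicates, subgroup re-runs) works from this object.
#'
#' @param bundle an `ehr_bundle`.
#' @param config a [run_config()].
#' @param cohort_filter optional subgroup filter applied to the eligible
#'   cohort before panel construction: a function `cohort -> logical` or a
#'   named list of required column values.
#' @return list of class `trial_prep`.
#' @export
prepare_analysis <- function(bundle, config = run_config(),
                             cohort_filter = NULL) {
  bc <- build_cohort(bundle, config$arms)
  coh <- bc$cohort
  if (!is.null(cohort_filter)) {
    keep <- if (is.function(cohort_filter)) {
      cohort_filter(coh)
    } else {
      Reduce(`&`, lapply(names(cohort_filter), function(nm) {
        coh[[nm]] %in% cohort_filter[[nm]]
      }))
    }
    coh <- coh[keep & !is.na(keep)]
  }
  if (!nrow(coh)) {
    stop2("empty cohort: no eligible patients ",
          if (!is.null(cohort_filter)) "after the subgroup filter" else "")
  }
  # covariates that are constant in the (possibly filtered) cohort are
  # aliased with the intercept; drop them from the model specifications
  const_cov <- Filter(function(nm) {
    v <- coh[[nm]]
    !is.null(v) && length(unique(v)) < 2L
  }, union(config$ipw$baseline, config$covariates))
  if (length(const_cov)) {
    message("dropping constant covariate(s) in this cohort: ",
            paste(const_cov, collapse = ", "))
    config$ipw$baseline <- setdiff(config$ipw$baseline, const_cov)
    config$covariates <- setdiff(config$covariates, const_cov)
  }
  panel <- build_panel(coh, bundle)
  arms <- intersect(config$arms, unique(coh$arm))
  if (!config$reference %in% arms) {
    stop2("reference arm '", config$reference, "' has no eligible patients")
  }
  arms <- c(config$reference, setdiff(arms, config$reference))
  spec <- config$ipw
  rows <- join_covariates(panel, coh, spec)
  for (nm in setdiff(config$covariates, names(rows))) {
    rows <- as.data.table(coh)[, c("patient_id", nm), with = FALSE][
      rows, on = "patient_id"]
  }
  setorder(rows, patient_id, month)
  pat_ids <- coh$patient_id
  pat_index <- function(ids) match(ids, pat_ids)

  X_meas <- ipw_design(rows, spec, arms)
  censor_info <- NULL
  ar <- NULL
  X_cens <- NULL
  ar_first <- NULL
  if (config$mode == "pp") {
    censor_info <- compute_censor_info(bundle$prescriptions, coh,
                                       grace_days = config$grace_days,
                                       censor_on_switch = config$censor_on_switch,
                                       stockpile = config$stockpile,
                                       study_arms = config$arms)
    ar <- at_risk_rows(rows, censor_info)
    ar[, event := as.integer(!is.na(stop_month) & month == stop_month)]
    setorder(ar, patient_id, month)
    X_cens <- if (sum(ar$event)) ipw_design(ar, spec, arms, knots = attr(X_meas, "knots"))
    # index of each at-risk row's group-first row (for vectorized lagged
    # cumulative products inside fit_models)
    ar_first <- ar[, rep(.I[1L], .N), by = patient_id]$V1
  }

  # outcome rows: measured with finite y; per-protocol additionally
  # uncensored (strictly before the censor month)
  rows[, row_id := .I]
  out_rows <- rows[measured == 1L & is.finite(y)]
  if (config$mode == "pp") {
    cm <- censor_info[, .(patient_id, censor_month)]
    out_rows <- cm[out_rows, on = "patient_id"]
    out_rows <- out_rows[is.na(censor_month) | month < censor_month]
  }
  msm_knots <- NULL
  if (config$spline$time_trend == "spline") {
    msm_knots <- unname(quantile(out_rows$month, config$spline$knot_quantiles,
                                 type = 7, names = FALSE))
  }
  X_msm <- msm_design(out_rows$arm, out_rows$month,
                      cov_matrix(out_rows, config$covariates), arms,
                      config$spline, knots = msm_knots)
  grid <- CJ(arm = arms, month = seq_len(FOLLOWUP_MONTHS), sorted = FALSE)
  X_grid <- msm_design(grid$arm, grid$month, NULL, arms, config$spline,
                       knots = attr(X_msm, "knots"),
                       month_levels = attr(X_msm, "month_levels"))
  cov_coh <- cov_matrix(coh, config$covariates)

  structure(list(
    config = config, cohort = coh, attrition = bc$attrition, panel = panel,
    censor_info = censor_info, arms = arms, pat_ids = pat_ids,
    rows = rows, X_meas = X_meas, pat_meas = pat_index(rows$patient_id),
    ar = ar, X_cens = X_cens,
    pat_cens = if (!is.null(ar)) pat_index(ar$patient_id),
    out_rows = out_rows, X_msm = X_msm, pat_msm = pat_index(out_rows$patient_id),
    ar_first = ar_first,
    cens_map = if (!is.null(ar)) {
      ar[out_rows[, .(patient_id, month)], on = .(patient_id, month),
         which = TRUE]
    },
    grid = grid, X_grid = X_grid, cov_coh = cov_coh,
    grid_idx = which(grid$month %in% config$months_of_interest),
    grid_cols = colnames(X_grid), warm = new.env(parent = emptyenv())
  ), class = "trial_prep")
}

#' Fit the weighted analysis from a prepared object
#'
#' Refits the measurement (and, per-protocol, censoring) weight models,
#' combines and truncates the weights, fits the weighted outcome model and
#' (optionally) the 5%-gain model, and standardizes over the cohort. With
#' `mult` (per-patient multiplicities) this is one bootstrap replicate;
#' `mult = NULL` is the point estimate.
#'
#' @param prep a `trial_prep`.
#' @param mult optional integer vector of per-patient multiplicities aligned
#'   with `prep$pat_ids`.
#' @return list with `effects` (`arm`, `month`, `mean_change`,
#'   `contrast_vs_ref`, and when configured `risk5`, `rr_vs_ref`), the full
#'   monthly `curve`, weight diagnostics, and model coefficients.
#' @export
fit_analysis <- function(prep, mult = NULL) {
  cfg <- prep$config
  core <- fit_models(prep, mult)
  base_cols <- setdiff(colnames(prep$X_grid), cfg$covariates)
  eta_grid <- drop(prep$X_grid[, base_cols, drop = FALSE] %*%
                     core$beta[base_cols])
  curve <- copy(prep$grid)
  set(curve, j = "mean_change", value = eta_grid + core$covlin_mean)
  curve <- arm_contrasts(curve, cfg$reference)

  effects <- curve[month %in% cfg$months_of_interest]
  if (cfg$include_risk) {
    rg <- prep$grid[prep$grid_idx]
    risk_tab <- copy(rg)
    set(risk_tab, j = "risk5", value = core$risk)
    ref <- risk_tab[arm == cfg$reference, .(month, ref_risk = risk5)]
    risk_tab <- ref[risk_tab, on = "month"]
    risk_tab[, rr_vs_ref := fifelse(arm == cfg$reference, 1,
                                    fifelse(ref_risk > 0, risk5 / ref_risk,
                                            NA_real_))]
    risk_tab[, ref_risk := NULL]
    effects <- risk_tab[effects, on = .(arm, month)]
  }
  setorder(effects, month, arm)

  list(effects = effects[], curve = curve,
       coef = list(measurement = core$co_m, adherence = core$co_c,
                   outcome = core$beta, risk = core$co_r),
       weights = core$wstats, n_cohort = core$n_cohort)
}

# fit every model once for a given set of per-patient multiplicities and
# return coefficients plus standardized quantities at the report months
fit_models <- function(prep, mult = NULL) {
  cfg <- prep$config
  warm <- prep$warm
  w_meas_case <- if (is.null(mult)) NULL else mult[prep$pat_meas]
  co_m <- logit_irls(prep$X_meas, prep$rows$measured, w = w_meas_case,
                     start = warm$meas, label = "measurement model")
  if (is.null(mult)) warm$meas <- co_m
  p_meas <- clip(plogis(drop(prep$X_meas %*% co_m)), PROB_FLOOR, 1 - PROB_FLOOR)

  w_cens_rows <- NULL
  co_c <- NULL
  if (cfg$mode == "pp" && !is.null(prep$X_cens)) {
    w_cens_case <- if (is.null(mult)) NULL else mult[prep$pat_cens]
    co_c <- logit_irls(prep$X_cens, prep$ar$event, w = w_cens_case,
                       start = warm$cens, label = "adherence model")
    if (is.null(mult)) warm$cens <- co_c
    h <- clip(plogis(drop(prep$X_cens %*% co_c)), PROB_FLOOR, 1 - PROB_FLOOR)
    # w(t) = 1 / prod_{k < t} p_cont(k) within patient, vectorized through
    # a global cumulative log-sum reset at each patient's first at-risk row
    lp <- log1p(-h)
    cl <- cumsum(lp)
    fi <- prep$ar_first
    log_before <- (cl - lp) - (cl[fi] - lp[fi])
    w_all <- exp(-log_before)
    w_cens_rows <- w_all[prep$cens_map]
    w_cens_rows[is.na(w_cens_rows)] <- 1
  }

  om <- prep$out_rows
  w_comb <- 1 / p_meas[om$row_id]
  if (!is.null(w_cens_rows)) w_comb <- w_comb * w_cens_rows
  case_msm <- if (is.null(mult)) NULL else mult[prep$pat_msm]
  active <- if (is.null(case_msm)) TRUE else case_msm > 0
  cap <- if (cfg$truncation_percentile >= 100) {
    max(w_comb[active])
  } else {
    quantile_type1(w_comb[active], cfg$truncation_percentile / 100,
                   w = if (is.null(case_msm)) NULL else case_msm[active])
  }
  w_trunc <- pmin(w_comb, cap)
  w_fit <- if (is.null(case_msm)) w_trunc else w_trunc * case_msm

  beta <- wls_solve(prep$X_msm, om$y, w_fit)

  mult_c <- if (is.null(mult)) rep(1, length(prep$pat_ids)) else mult
  covlin_mean <- if (length(cfg$covariates)) {
    drop(crossprod(colSums(prep$cov_coh * mult_c) / sum(mult_c),
                   beta[cfg$covariates]))
  } else 0
  risk <- NULL
  co_r <- NULL
  if (cfg$include_risk && sum(om$gain5 * (w_fit > 0)) == 0) {
    risk <- numeric(length(prep$grid_idx)) # no events anywhere: risks are 0
  } else if (cfg$include_risk) {
    co_r <- logit_irls(prep$X_msm, om$gain5, w = w_fit, guard = FALSE,
                       start = warm$risk, label = "5%-gain model")
    if (is.null(mult)) warm$risk <- co_r
    base_cols <- setdiff(colnames(prep$X_grid), cfg$covariates)
    covlin_r <- if (length(cfg$covariates)) {
      drop(prep$cov_coh %*% co_r[cfg$covariates])
    } else numeric(length(mult_c))
    eta_r <- drop(prep$X_grid[prep$grid_idx, base_cols, drop = FALSE] %*%
                    co_r[base_cols])
    sw <- sum(mult_c)
    risk <- vapply(eta_r, function(e) sum(plogis(e + covlin_r) * mult_c) / sw,
                   numeric(1))
  }
  list(beta = beta, co_m = co_m, co_c = co_c, co_r = co_r,
       covlin_mean = covlin_mean, risk = risk, mult_c = mult_c,
       n_cohort = sum(mult_c > 0),
       wstats = list(cap = cap, max = max(w_trunc), mean = mean(w_comb),
                     n_rows = nrow(om)))
}

# weighted least squares via normal equations (with a descriptive
# rank-deficiency error from the QR fallback)
wls_solve <- function(X, y, w) {
  if (any(!is.finite(w))) stop2("non-finite weights in outcome fit")
  fit <- cpp_wls(X, y, w)
  beta <- if (isTRUE(fit$ok)) drop(fit$beta)
  if (is.null(beta)) {
    fit <- stats::lm.wfit(X, y, w + 0)
    if (anyNA(fit$coefficients)) {
      stop2("outcome design matrix rank-deficient; aliased: ",
            paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
    }
    beta <- fit$coefficients
  }
  names(beta) <- colnames(X)
  beta
}

# slim replicate evaluator: estimand vectors aligned with
# prep$grid[prep$grid_idx] (used by the bootstrap; no table assembly)
fit_estimates <- function(prep, mult = NULL) {
  cfg <- prep$config
  core <- fit_models(prep, mult)
  base_cols <- setdiff(colnames(prep$X_grid), cfg$covariates)
  means <- drop(prep$X_grid[prep$grid_idx, base_cols, drop = FALSE] %*%
                  core$beta[base_cols]) + core$covlin_mean
  g <- prep$grid[prep$grid_idx]
  ref_means <- means[which(g$arm == cfg$reference)][match(
    g$month, g$month[g$arm == cfg$reference])]
  out <- c(means, means - ref_means)
  if (cfg$include_risk) {
    ref_risk <- core$risk[which(g$arm == cfg$reference)][match(
      g$month, g$month[g$arm == cfg$reference])]
    rr <- ifelse(g$arm == cfg$reference, 1,
                 ifelse(ref_risk > 0, core$risk / ref_risk, NA_real_))
    out <- c(out, core$risk, rr)
  }
  out
}

#' Run the full pipeline on a bundle
#'
#' Cohort construction, per-protocol censoring, weight fitting, the weighted
#' outcome model, standardization and contrasts, in one call.
#'
#' @param bundle an `ehr_bundle`.
#' @param config a [run_config()].
#' @param cohort_filter optional subgroup filter (see [prepare_analysis()]).
#' @return list of class `trial_result`: `effects` (the effect table),
#'   `curve` (all 24 months), `attrition`, `censor_info`, `diagnostics`,
#'   and the `prep` object for reuse.
#' @export
run_pipeline <- function(bundle, config = run_config(), cohort_filter = NULL) {
  prep <- prepare_analysis(bundle, config, cohort_filter)
  fit <- fit_analysis(prep)
  structure(list(effects = fit$effects, curve = fit$curve,
                 attrition = prep$attrition, censor_info = prep$censor_info,
                 diagnostics = list(coef = fit$coef, weights = fit$weights,
                                    n_cohort = nrow(prep$cohort),
                                    mode = config$mode),
                 prep = prep),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$diagnostics$mode, "analysis;",
      x$diagnostics$n_cohort, "eligible patients\n")
  print(x$effects)
  invisible(x)
}

#' Subgroup / sensitivity analysis
#'
#' Filters the eligible cohort before panel construction and re-runs the
#' identical pipeline. Named filters: `"obesity"` / `"non_obesity"` (BMI >=
#' 30 vs < 30), `"male"` / `"female"`, `"white"` / `"non_white"`,
#' `"female_under_55"` / `"female_55_plus"`, and `"hypertension"` (diagnosis
#' on or before baseline, or systolic >= 140 / diastolic >= 90 within 6
#' months).
#'
#' @param bundle an `ehr_bundle`.
#' @param config a [run_config()].
#' @param subgroup a filter name above, a named list of column values, or a
#'   function `cohort -> logical`.
#' @return a `trial_result` with `subgroup_n` in its diagnostics.
#' @export
subgroup_run <- function(bundle, config = run_config(), subgroup) {
  f <- if (is.character(subgroup)) subgroup_filter(subgroup) else subgroup
  res <- run_pipeline(bundle, config, cohort_filter = f)
  res$diagnostics$subgroup_n <- res$diagnostics$n_cohort
  res$diagnostics$subgroup <- if (is.character(subgroup)) subgroup else "custom"
  res
}

subgroup_filter <- function(name) {
  switch(name,
    obesity = function(coh) coh$obesity == 1L,
    non_obesity = function(coh) coh$obesity == 0L,
    male = function(coh) coh$sexF == 0L,
    female = function(coh) coh$sexF == 1L,
    white = function(coh) coh$race_white == 1L,
    non_white = function(coh) coh$race_white == 0L,
    female_under_55 = function(coh) coh$sexF == 1L & coh$age < 55,
    female_55_plus = function(coh) coh$sexF == 1L & coh$age >= 55,
    hypertension = function(coh) {
      coh$htn_dx == 1L | coh$systolic >= 140 | coh$diastolic >= 90
    },
    stop2("unknown subgroup filter '", name, "'")
  )
}
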