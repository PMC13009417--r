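# New-user identification, the eligibility/exclusion cascade, baseline
# weight and covariate assembly. Rejections are data, not errors: every
# candidate gets at most one exclusion reason, the first failed criterion in
# the documented order (age -> prior use -> polytherapy -> encounter ->
# cancer -> pregnancy -> bariatric -> heart failure -> weight-affecting
# medication -> baseline weight -> demographics -> blood pressure).

WEIGHT_AFFECTING <- c("anti_obesity", "steroid", "stimulant")

# Exclusion windows in days relative to initiation (closed ranges)
WINDOW_CANCER <- c(-365L, 30L)
WINDOW_PREGNANCY <- c(-365L, 0L)
WINDOW_BARIATRIC <- c(-1095L, 30L)
WINDOW_HF <- c(-365L, 30L)
WINDOW_CONMED <- c(-30L, 30L)
WINDOW_BASELINE_WEIGHT <- c(-90L, 0L)
WINDOW_BP <- c(-180L, 0L)

#' Plausibility filter for EHR weight records
#'
#' Desk-scale stand-in for a full EHR anthropometric cleaning pipeline:
#' drops weights outside 25-350 kg and, scanning each patient's records in
#' day order, drops any measurement implying a change of more than 30 kg per
#' 30 days relative to the last retained measurement.
#'
#' @param vitals `data.frame` with `patient_id`, `day`, `weight_kg`.
#' @return filtered `data.table` of the weight rows (BP-only rows dropped).
#' @export
clean_weights <- function(vitals) {
  v <- as.data.table(vitals)[!is.na(weight_kg)]
  v <- v[weight_kg >= 25 & weight_kg <= 350]
  setorder(v, patient_id, day)
  # fast path: flag patients with any consecutive-pair violation, and run
  # the sequential last-retained scan only for those (global shift with a
  # patient-boundary mask; no per-group evaluation)
  same <- v$patient_id == shift(v$patient_id)
  dd <- v$day - shift(v$day)
  dw <- abs(v$weight_kg - shift(v$weight_kg))
  # same-day repeats are duplicates to average later, not jumps; flag them
  # only when they disagree by more than the jump threshold itself
  rate <- ifelse(dd == 0, dw, dw / pmax(dd, 1) * DAYS_PER_MONTH)
  bad <- unique(v$patient_id[which(same & rate > 30)])
  if (!length(bad)) return(v)
  keep_run <- function(day, w) {
    keep <- rep(TRUE, length(w))
    last <- 1L
    if (length(w) > 1L) {
      for (i in 2L:length(w)) {
        dd <- day[i] - day[last]
        rate <- if (dd == 0) abs(w[i] - w[last]) else
          abs(w[i] - w[last]) / dd * DAYS_PER_MONTH
        if (rate > 30) keep[i] <- FALSE else last <- i
      }
    }
    keep
  }
  vb <- v[patient_id %in% bad]
  vb <- vb[vb[, keep_run(day, weight_kg), by = patient_id]$V1]
  rbind(v[!patient_id %in% bad], vb)[order(patient_id, day)]
}

#' Identify incident (new) users of the study drugs
#'
#' A candidate's baseline is the day of their first-ever fill of any study
#' drug. Candidates are flagged (not dropped) when rejected: two different
#' study drugs filled on the initiation day ("polytherapy at initiation"),
#' any `other_antihypertensive` fill on or before baseline ("prior
#' antihypertensive use"), or no encounter at least 180 days before baseline
#' ("no encounter >=6 months prior").
#'
#' @param prescriptions fill table (`patient_id`, `drug`, `fill_day`, ...).
#' @param encounters encounter table (`patient_id`, `day`).
#' @param arms study drug labels (default [default_arms()]).
#' @return `data.table` with `patient_id`, `arm`, `baseline_day`, `reason`
#'   (`NA` for candidates passing these three checks). Empty input gives an
#'   empty result.
#' @export
identify_new_users <- function(prescriptions, encounters, arms = default_arms()) {
  rx <- as.data.table(prescriptions)
  if (!nrow(rx)) {
    return(data.table(patient_id = integer(), arm = character(),
                      baseline_day = integer(), reason = character()))
  }
  study <- rx[drug %in% arms]
  first <- study[, .(baseline_day = min(fill_day)), by = patient_id]
  day1 <- study[first, on = .(patient_id, fill_day = baseline_day)]
  cand <- day1[, .(arm = drug[1L], n_drugs = uniqueN(drug),
                   baseline_day = fill_day[1L]), by = patient_id]
  cand[, reason := NA_character_]
  prior <- rx[drug == "other_antihypertensive"][
    cand, on = "patient_id", nomatch = NULL][fill_day <= baseline_day,
                                             unique(patient_id)]
  cand[patient_id %in% prior, reason := "prior antihypertensive use"]
  cand[is.na(reason) & n_drugs > 1L, reason := "polytherapy at initiation"]
  enc <- as.data.table(encounters)
  ok_enc <- enc[cand, on = "patient_id", nomatch = NULL][
    day <= baseline_day - 180L, unique(patient_id)]
  cand[is.na(reason) & !patient_id %in% ok_enc,
       reason := "no encounter >=6 months prior"]
  cand[, n_drugs := NULL]
  setorder(cand, patient_id)
  cand[]
}

#' Baseline weight selection
#'
#' Among plausible weight measurements in the closed window
#' `[baseline_day - 90, baseline_day]`, returns the one closest to (but not
#' after) initiation; same-day duplicates are averaged. `NA` when none.
#'
#' @param vitals one patient's vitals (`day`, `weight_kg`).
#' @param baseline_day initiation day.
#' @return baseline weight in kg, or `NA_real_`.
#' @export
select_baseline_weight <- function(vitals, baseline_day) {
  v <- as.data.table(vitals)
  if (!"patient_id" %in% names(v)) v[, patient_id := 1L]
  v <- clean_weights(v)
  v <- v[day >= baseline_day + WINDOW_BASELINE_WEIGHT[1L] & day <= baseline_day]
  if (!nrow(v)) return(NA_real_)
  v[day == max(day), mean(weight_kg)]
}

# internal vectorized version over a cleaned weight table and candidate set
baseline_weights_all <- function(weights, cand) {
  w <- weights[cand, on = "patient_id", nomatch = NULL]
  w <- w[day >= baseline_day + WINDOW_BASELINE_WEIGHT[1L] & day <= baseline_day]
  if (!nrow(w)) {
    return(data.table(patient_id = integer(), baseline_weight = numeric()))
  }
  w[, mday := max(day), by = patient_id]
  w[day == mday, .(baseline_weight = mean(weight_kg)), by = patient_id]
}

# recent weight change category: anchor measurement closest to day -180
# within [-270, -90] (ties toward the earlier day); gain/loss at +-0.5 kg of
# baseline weight; "stable" when no anchor exists
recent_weight_change <- function(weights, cand) {
  w <- weights[cand, on = "patient_id", nomatch = NULL]
  w <- w[day >= baseline_day - 270L & day <= baseline_day - 90L]
  if (!nrow(w)) return(data.table(patient_id = integer(), prior_weight = numeric()))
  w[, dist := abs(day - (baseline_day - 180L))]
  setorder(w, patient_id, dist, day)
  w[, .(prior_weight = data.table::first(weight_kg)), by = patient_id]
}

#' Apply the eligibility exclusion cascade
#'
#' Evaluates every criterion for every candidate and assigns the first
#' failure in the documented order; survivors become cohort records with
#' baseline covariates attached. All windows are closed day ranges relative
#' to initiation: cancer and heart failure `[-365, +30]`, pregnancy
#' `[-365, 0]`, bariatric surgery `[-1095, +30]`, anti-obesity / steroid /
#' stimulant fills `[-30, +30]`; baseline weight must exist in `[-90, 0]`,
#' a blood pressure in `[-180, 0]`, sex and race/ethnicity must be
#' non-missing, and age at initiation must be in `[20, 80]` years.
#'
#' @param candidates output of [identify_new_users()].
#' @param bundle an `ehr_bundle` (or any list with the five tables).
#' @return list with `cohort` (eligible records with covariates) and
#'   `attrition` (one row per candidate: `patient_id`, `eligible`, `reason`).
#' @export
apply_exclusions <- function(candidates, bundle) {
  cand <- copy(as.data.table(candidates))
  demo <- as.data.table(bundle$demographics)
  conds <- as.data.table(bundle$conditions)
  rx <- as.data.table(bundle$prescriptions)
  vit <- as.data.table(bundle$vitals)
  weights <- clean_weights(vit)

  cand <- demo[cand, on = "patient_id"]
  cand[, age := (baseline_day - birth_day) / 365.25]

  in_window <- function(categories, window, table = conds) {
    ev <- table[category %in% categories][cand, on = "patient_id", nomatch = NULL]
    ev[day >= baseline_day + window[1L] & day <= baseline_day + window[2L],
       unique(patient_id)]
  }
  conmed_hits <- {
    ev <- rx[drug %in% WEIGHT_AFFECTING][cand, on = "patient_id", nomatch = NULL]
    ev[fill_day >= baseline_day + WINDOW_CONMED[1L] &
         fill_day <= baseline_day + WINDOW_CONMED[2L], unique(patient_id)]
  }
  bw <- baseline_weights_all(weights, cand)
  bp <- vit[!is.na(systolic) & !is.na(diastolic)][cand, on = "patient_id",
                                                  nomatch = NULL]
  bp <- bp[day >= baseline_day + WINDOW_BP[1L] & day <= baseline_day]
  bp_latest <- if (nrow(bp)) {
    setorder(bp, patient_id, -day)
    unique(bp, by = "patient_id")[, .(patient_id, systolic, diastolic)]
  } else data.table(patient_id = integer(), systolic = numeric(),
                    diastolic = numeric())

  # first failed criterion, documented order
  fail <- function(cond, label) {
    cand[is.na(reason) & cond, reason := label]
  }
  # age precedes the reasons identify_new_users already planted in `reason`
  # (prior use, polytherapy, encounter), so overwrite those for under/over-age
  cand[age < 20 | age > 80, reason := "age"]
  fail(cand$patient_id %in% in_window("cancer", WINDOW_CANCER), "cancer")
  fail(cand$patient_id %in% in_window("pregnancy", WINDOW_PREGNANCY), "pregnancy")
  fail(cand$patient_id %in% in_window("bariatric_surgery", WINDOW_BARIATRIC),
       "bariatric surgery")
  fail(cand$patient_id %in% in_window("heart_failure", WINDOW_HF), "heart failure")
  fail(cand$patient_id %in% conmed_hits, "weight-affecting medication")
  fail(!cand$patient_id %in% bw$patient_id, "no baseline weight")
  fail(is.na(cand$sex) | is.na(cand$race) | is.na(cand$ethnicity),
       "missing sex or race/ethnicity")
  fail(!cand$patient_id %in% bp_latest$patient_id, "no baseline blood pressure")

  attrition <- cand[, .(patient_id, eligible = is.na(reason), reason)]
  coh <- cand[is.na(reason)]
  coh <- bw[coh, on = "patient_id"]
  coh <- bp_latest[coh, on = "patient_id"]
  pw <- recent_weight_change(weights, coh)
  coh <- pw[coh, on = "patient_id"]
  death <- as.data.table(bundle$death %||% NULL)
  if (!nrow(death)) { # canonical empty table (column types survive CSV IO)
    death <- data.table(patient_id = integer(), death_day = numeric())
  }
  coh <- death[coh, on = "patient_id"]
  htn <- conds[category == "hypertension"][coh, on = "patient_id", nomatch = NULL]
  htn_ids <- htn[day <= baseline_day, unique(patient_id)]
  conmed_base <- rx[drug %in% WEIGHT_AFFECTING][coh, on = "patient_id",
                                                nomatch = NULL]
  conmed_ids <- conmed_base[fill_day >= baseline_day - 365L &
                              fill_day < baseline_day + WINDOW_CONMED[1L],
                            unique(patient_id)]

  coh[, `:=`(
    bmi = baseline_weight / (height_cm / 100)^2,
    sexF = as.integer(sex == "F"),
    race_white = as.integer(race == "White"),
    init_year = 2010L + as.integer(baseline_day %/% 365L),
    htn_dx = as.integer(patient_id %in% htn_ids),
    conmed_flag = as.integer(patient_id %in% conmed_ids),
    recent_wc = fifelse(is.na(prior_weight), "stable",
                        fifelse(baseline_weight - prior_weight >= 0.5, "gain",
                                fifelse(baseline_weight - prior_weight <= -0.5,
                                        "loss", "stable")))
  )]
  coh[, obesity := as.integer(bmi >= 30)]
  # derived model-ready columns (age in decades; recent-change dummies)
  coh[, `:=`(age10 = age / 10,
             recent_gain = as.integer(recent_wc == "gain"),
             recent_loss = as.integer(recent_wc == "loss"))]
  coh[, `:=`(reason = NULL, prior_weight = NULL)]
  setorder(coh, patient_id)
  list(cohort = coh[], attrition = attrition[])
}

#' Build the eligible cohort from a bundle
#'
#' Convenience wrapper: [identify_new_users()] then [apply_exclusions()].
#'
#' @param bundle an `ehr_bundle`.
#' @param arms study drug labels.
#' @return list with `cohort` and `attrition` (one row per candidate).
#' @export
build_cohort <- function(bundle, arms = default_arms()) {
  cand <- identify_new_users(bundle$prescriptions, bundle$encounters, arms)
  apply_exclusions(cand, bundle)
}
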