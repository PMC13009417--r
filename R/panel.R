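# Person-month outcome panel: months t = 1..24 cover days
# [30t, 30(t+1)) from the baseline day; month 0 is the baseline itself
# (weight change identically zero) and never enters outcome fitting.

#' Build the 30-day person-month panel
#'
#' One row per cohort patient and month 1..24, truncated at death
#' (the last retained month is `floor(death_rel_day / 30)`). `measured` is 1
#' when at least one plausible weight falls in the month window; `y` is the
#' within-month mean weight minus baseline weight. `lwc` carries the last
#' measured weight change *entering* the month (the most recent measured
#' `y` from strictly earlier months, 0 before any follow-up measurement),
#' which is the information set available when that month's measurement and
#' adherence processes fire. `n_enc` counts encounters in the month and
#' `new_conmed` flags a weight-affecting fill in the month.
#'
#' @param cohort eligible cohort from [build_cohort()].
#' @param bundle the `ehr_bundle` the cohort came from.
#' @param months follow-up horizon in months (default 24).
#' @return `data.table` keyed by (`patient_id`, `month`).
#' @export
build_panel <- function(cohort, bundle, months = FOLLOWUP_MONTHS) {
  coh <- as.data.table(cohort)
  w <- clean_weights(bundle$vitals)
  w <- w[coh[, .(patient_id, baseline_day, baseline_weight)], on = "patient_id",
         nomatch = NULL]
  w[, rel := day - baseline_day]
  w <- w[rel >= DAYS_PER_MONTH & rel < DAYS_PER_MONTH * (months + 1L)]
  w[, month := month_of_day(rel)]
  mw <- w[, .(wt_mean = mean(weight_kg)), by = .(patient_id, month)]

  panel <- CJ(patient_id = coh$patient_id, month = seq_len(months))
  panel <- coh[, .(patient_id, baseline_day, baseline_weight, death_day)][
    panel, on = "patient_id"]
  panel <- panel[is.na(death_day) |
                   month <= month_of_day(death_day - baseline_day)]
  panel <- mw[panel, on = .(patient_id, month)]
  panel[, measured := as.integer(!is.na(wt_mean))]
  panel[, y := wt_mean - baseline_weight]

  enc <- as.data.table(bundle$encounters)[
    coh[, .(patient_id, baseline_day)], on = "patient_id", nomatch = NULL]
  enc[, month := month_of_day(day - baseline_day)]
  enc <- enc[month >= 1L & month <= months,
             .(n_enc = .N), by = .(patient_id, month)]
  panel <- enc[panel, on = .(patient_id, month)]
  panel[is.na(n_enc), n_enc := 0L]

  cm <- as.data.table(bundle$prescriptions)[drug %in% WEIGHT_AFFECTING][
    coh[, .(patient_id, baseline_day)], on = "patient_id", nomatch = NULL]
  cm[, month := month_of_day(fill_day - baseline_day)]
  cm <- unique(cm[month >= 1L & month <= months, .(patient_id, month)])
  cm[, new_conmed := 1L]
  panel <- cm[panel, on = .(patient_id, month)]
  panel[is.na(new_conmed), new_conmed := 0L]

  setorder(panel, patient_id, month)
  # last measured change entering the month: for each row, the most recent
  # measured y from a strictly earlier row of the same patient (0 if none);
  # vectorized via a running index of the last measured row
  panel[, lwc := {
    ym <- fifelse(measured == 1L, y, NA_real_)
    src <- cummax(fifelse(!is.na(ym), .I, 0L))
    srcl <- shift(src, fill = 0L)
    out <- numeric(.N)
    pos <- which(srcl > 0L)
    if (length(pos)) {
      take <- srcl[pos]
      okp <- patient_id[take] == patient_id[pos]
      out[pos[okp]] <- ym[take[okp]]
    }
    out
  }]
  panel[, `:=`(baseline_day = NULL, death_day = NULL)]
  setkey(panel, patient_id, month)
  flag_5pct_gain(panel, coh)
}

#' Flag weight gain of at least 5% of baseline
#'
#' For measured rows, `gain5 = 1` iff `y >= 0.05 * baseline_weight`
#' (boundary inclusive); unmeasured rows carry `NA`.
#'
#' @param panel person-month panel.
#' @param cohort cohort carrying `baseline_weight` (ignored if the panel
#'   already has a `baseline_weight` column).
#' @return the panel with a `gain5` column added.
#' @export
flag_5pct_gain <- function(panel, cohort) {
  p <- as.data.table(panel)
  if (!"baseline_weight" %in% names(p)) {
    p <- as.data.table(cohort)[, .(patient_id, baseline_weight)][
      p, on = "patient_id"]
  }
  p[, gain5 := fifelse(measured == 1L,
                       as.integer(y >= 0.05 * baseline_weight), NA_integer_)]
  p[]
}
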