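# Medication-on-hand reconstruction from prescription fills, nearest-fill
# imputation of missing supply fields, and per-protocol censoring with a
# grace period. Day arithmetic is exact: every covered span is a half-open
# integer interval [start, end) in days.

#' Coverage interval implied by one prescription fill
#'
#' Converts a fill record into the half-open day interval during which the
#' patient has medication on hand. Covered length is
#' `days_supply * (1 + refills)` when `days_supply` is present (`refills`
#' defaults to 0 when blank); otherwise `quantity / daily_dose * (1 + refills)`
#' when `quantity` is present (a constant daily dose of `daily_dose` units is
#' assumed); otherwise a default minimum of `default_days` per dispensing
#' (one month) is used.
#'
#' @param fill_day integer day of the fill (vectorized).
#' @param days_supply,quantity,refills supply fields; `NA` means blank.
#' @param daily_dose assumed units consumed per day when only `quantity` is
#'   known (default 1).
#' @param default_days fallback covered days per dispensing when all supply
#'   fields are blank (default 30, the one-month minimum).
#' @return `data.table` with columns `start`, `end` (half-open day interval).
#' @export
coverage_from_fill <- function(fill_day, days_supply = NA, quantity = NA,
                               refills = NA, daily_dose = 1,
                               default_days = DAYS_PER_MONTH) {
  n <- length(fill_day)
  days_supply <- rep_len(as.numeric(days_supply), n)
  quantity <- rep_len(as.numeric(quantity), n)
  refills <- rep_len(as.numeric(refills), n)
  bad <- which(days_supply < 0 | quantity < 0 | refills < 0)
  if (length(bad)) {
    stop2("negative supply fields in fill record(s): ",
          paste(bad, collapse = ", "))
  }
  r <- fifelse(is.na(refills), 0, refills)
  len <- fifelse(!is.na(days_supply), days_supply * (1 + r),
                 fifelse(!is.na(quantity), quantity / daily_dose * (1 + r),
                         default_days * (1 + r)))
  data.table(start = as.numeric(fill_day), end = fill_day + len)
}

#' Impute blank supply fields from the nearest same-drug fill
#'
#' For each fill with a blank `days_supply`, `quantity` or `refills`, copies
#' the field from the same-patient, same-drug fill with the smallest
#' absolute fill-day difference that has the field populated; ties are broken
#' toward the earlier donor. Fills with no donor keep the blank and fall back
#' to the one-month default in [coverage_from_fill()]. A `supply_source`
#' column records `observed`, `imputed` or `default`.
#'
#' @param fills `data.frame` with `patient_id`, `drug`, `fill_day`,
#'   `days_supply`, `quantity`, `refills`.
#' @return `data.table` of the fills with blanks imputed where possible.
#' @export
impute_missing_supply <- function(fills) {
  f <- as.data.table(fills)
  need <- c("patient_id", "drug", "fill_day", "days_supply", "quantity", "refills")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop2("fills table lacks column(s): ", paste(miss, collapse = ", "))
  f[, supply_source := fifelse(is.na(days_supply) & is.na(quantity) & is.na(refills),
                               "blank", "observed")]
  setorder(f, patient_id, drug, fill_day)
  # nearest donor in fill-day distance is always the previous or the next
  # populated fill once sorted; ties go to the earlier (previous) donor
  impute_one <- function(v, day) {
    if (!anyNA(v) || all(is.na(v))) return(v)
    dv <- fifelse(is.na(v), NA_real_, as.numeric(day))
    pv <- nafill(v, type = "locf")
    pd <- nafill(dv, type = "locf")
    nv <- nafill(v, type = "nocb")
    nd <- nafill(dv, type = "nocb")
    take_prev <- !is.na(pv) & (is.na(nv) | (day - pd) <= (nd - day))
    out <- fifelse(take_prev, pv, nv)
    fifelse(is.na(v), out, v)
  }
  f[, `:=`(days_supply = impute_one(days_supply, fill_day),
           quantity = impute_one(quantity, fill_day),
           refills = impute_one(refills, fill_day)),
    by = .(patient_id, drug)]
  f[supply_source == "blank",
    supply_source := fifelse(is.na(days_supply) & is.na(quantity), "default", "imputed")]
  f[]
}

#' Supply episodes (union of coverage intervals) per patient and drug
#'
#' Imputes blank supply fields, converts fills to coverage intervals, and
#' merges overlapping intervals into sorted, non-overlapping episodes. With
#' `stockpile = TRUE`, a fill obtained while a previous supply is still on
#' hand is consumed after it (its start shifts to the running coverage end,
#' preserving its length); by default overlapping supply simply unions.
#'
#' @param fills prescription table (see [impute_missing_supply()]).
#' @param daily_dose,default_days passed to [coverage_from_fill()].
#' @param stockpile logical; shift overlapping fills to end-to-end use.
#' @return `data.table` with `patient_id`, `drug`, `start`, `end`.
#' @export
supply_episodes <- function(fills, daily_dose = 1,
                            default_days = DAYS_PER_MONTH, stockpile = FALSE) {
  f <- impute_missing_supply(fills)
  iv <- coverage_from_fill(f$fill_day, f$days_supply, f$quantity, f$refills,
                           daily_dose = daily_dose, default_days = default_days)
  f[, `:=`(start = iv$start, end = iv$end)]
  setorder(f, patient_id, drug, start, end)
  if (stockpile) {
    f[, c("start", "end") := {
      s <- start
      e <- end
      if (length(s) > 1L) {
        run <- e[1L]
        for (i in 2L:length(s)) {
          len <- e[i] - s[i]
          if (s[i] < run) s[i] <- run
          e[i] <- s[i] + len
          run <- max(run, e[i])
        }
      }
      list(s, e)
    }, by = .(patient_id, drug)]
  }
  # vectorized interval union: a row starts a new episode when its start
  # exceeds the running coverage maximum of its (patient, drug) group
  f[, cme := shift(cummax(end)), by = .(patient_id, drug)]
  f[, grp := cumsum(is.na(cme) | start > cme)]
  ep <- f[, .(patient_id = data.table::first(patient_id),
              drug = data.table::first(drug),
              start = min(start), end = max(end)), by = grp]
  ep[, grp := NULL]
  ep[]
}

#' Per-protocol deviation time with a grace period
#'
#' Scans the coverage episodes of one patient's assigned drug, in days since
#' baseline, for the first uncovered spell lasting at least `grace_days`
#' days. If the first uncovered day is `E` and coverage does not resume
#' strictly before `E + grace_days`, the deviation day is
#' `D = E + grace_days` and the censor month is `floor(D / 30)` (clamped to
#' at least 1); otherwise scanning continues from the resumed coverage. No
#' deviation day strictly before `followup_days` means the patient completes
#' follow-up adherent.
#'
#' @param episodes `data.frame` with `start`, `end` in days since baseline
#'   (pre-baseline coverage is clipped at day 0), optionally a `drug` column
#'   which must then match `arm` when given.
#' @param arm optional assigned drug label used to validate `episodes$drug`.
#' @param grace_days allowed gap without medication on hand (default 30).
#' @param followup_days end of follow-up in days (default 720).
#' @return list with `censor_month` (integer or `NA`), `exhaustion_day`
#'   (first uncovered day `E`, or `NA`), `deviation_day` and `reason`
#'   (`"nonadherence"` or `"end-of-follow-up"`).
#' @export
censor_time <- function(episodes, arm = NULL, grace_days = DAYS_PER_MONTH,
                        followup_days = FOLLOWUP_DAYS) {
  ep <- as.data.table(episodes)
  if (!is.null(arm) && "drug" %in% names(ep)) {
    other <- setdiff(unique(ep$drug), arm)
    if (length(other)) {
      stop2("episodes contain drug(s) [", paste(other, collapse = ", "),
            "] different from the assigned arm '", arm, "'")
    }
  }
  none <- list(censor_month = NA_integer_, exhaustion_day = NA_real_,
               deviation_day = NA_real_, reason = "end-of-follow-up")
  dev <- function(E) {
    D <- E + grace_days
    if (E >= followup_days || D >= followup_days) return(none)
    list(censor_month = max(1L, month_of_day(D)), exhaustion_day = as.numeric(E),
         deviation_day = as.numeric(D), reason = "nonadherence")
  }
  keep <- ep$end > 0
  s <- pmax(ep$start[keep], 0)
  e <- ep$end[keep]
  if (!length(s)) return(dev(0))
  o <- order(s, e)
  s <- s[o]
  e <- e[o]
  E <- 0 # first day not yet known to be covered
  for (i in seq_along(s)) {
    if (s[i] > E && s[i] - E >= grace_days) return(dev(E))
    E <- max(E, e[i])
    if (E >= followup_days) return(none)
  }
  dev(E)
}

# Censor info for every cohort patient. One row per patient: censor_month
# (NA if adherent through follow-up), exhaustion_day, deviation_day, reason.
# Fills are restricted to the assigned arm's drug; the censor_on_switch flag
# additionally treats the first post-baseline fill of a *different* study
# drug as a deviation (no grace).
compute_censor_info <- function(prescriptions, cohort,
                                grace_days = DAYS_PER_MONTH,
                                followup_days = FOLLOWUP_DAYS,
                                censor_on_switch = FALSE,
                                stockpile = FALSE,
                                study_arms = default_arms()) {
  rx <- as.data.table(prescriptions)
  coh <- as.data.table(cohort)
  own <- rx[coh[, .(patient_id, arm)], on = .(patient_id, drug = arm), nomatch = NULL]
  ep <- supply_episodes(own[, .(patient_id, drug, fill_day, days_supply,
                                quantity, refills)],
                        stockpile = stockpile)
  b <- coh$baseline_day[match(ep$patient_id, coh$patient_id)]
  ep[, `:=`(start = start - b, end = end - b)]
  out <- ep[, censor_time(.SD, grace_days = grace_days,
                          followup_days = followup_days),
            by = patient_id]
  out <- out[coh[, .(patient_id)], on = "patient_id"]
  # a cohort patient with no reconstructable fills deviates once grace runs out
  out[is.na(reason), `:=`(censor_month = max(1L, month_of_day(grace_days)),
                          exhaustion_day = 0,
                          deviation_day = as.numeric(grace_days),
                          reason = "nonadherence")]
  # death before the deviation day is completed: the patient died adherent,
  # so follow-up truncation (not artificial censoring) applies
  if ("death_day" %in% names(coh)) {
    dd <- coh[, .(patient_id, death_day, baseline_day)]
    out <- dd[out, on = "patient_id"]
    out[!is.na(death_day) & !is.na(deviation_day) &
          deviation_day >= death_day - baseline_day,
        `:=`(censor_month = NA_integer_, exhaustion_day = NA_real_,
             deviation_day = NA_real_, reason = "death")]
    out[, c("death_day", "baseline_day") := NULL]
  }
  if (censor_on_switch) {
    arms <- unique(c(study_arms, coh$arm))
    sw <- rx[drug %in% arms][coh[, .(patient_id, arm, baseline_day)],
                             on = "patient_id", nomatch = NULL]
    sw <- sw[drug != arm & fill_day > baseline_day &
               fill_day < baseline_day + followup_days]
    if (nrow(sw)) {
      sw <- sw[, .(switch_month = max(1L, month_of_day(min(fill_day - baseline_day)))),
               by = patient_id]
      out <- sw[out, on = "patient_id"]
      out[!is.na(switch_month) & (is.na(censor_month) | switch_month < censor_month),
          `:=`(censor_month = switch_month, reason = "nonadherence")]
      out[, switch_month := NULL]
    }
  }
  out[]
}
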