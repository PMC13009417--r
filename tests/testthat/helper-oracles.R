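# Independent oracles used across the suite. These deliberately avoid the
# package's interval/scanning/design-matrix code paths: the censoring oracle
# walks calendar days one at a time, the spline oracle evaluates the
# truncated-power formula symbol by symbol, and the regression oracle solves
# the weighted normal equations directly.

# Day-by-day censoring oracle: marks each covered day from the fills'
# intervals, then walks days from baseline counting consecutive uncovered
# days; the deviation day is the day the grace allowance is exhausted.
oracle_censor_month <- function(intervals, grace_days = 30,
                                followup_days = 720) {
  horizon <- followup_days + grace_days + 60
  covered <- rep(FALSE, horizon + 1L) # index = day + 1
  for (i in seq_len(nrow(intervals))) {
    s <- max(0, intervals$start[i])
    e <- min(horizon + 1, intervals$end[i])
    if (e > s) covered[(s:(e - 1)) + 1L] <- TRUE
  }
  gap <- 0
  for (d in 0:horizon) {
    if (covered[d + 1L]) {
      gap <- 0
    } else {
      gap <- gap + 1
      if (gap >= grace_days && grace_days > 0) {
        D <- d + 1 - gap + grace_days # first day past the allowance
        if (D >= followup_days) return(NA_integer_)
        return(max(1L, as.integer(D %/% 30)))
      }
      if (grace_days == 0) {
        if (d >= followup_days) return(NA_integer_)
        return(max(1L, as.integer(d %/% 30)))
      }
    }
  }
  NA_integer_
}

# Truncated-power natural cubic spline, written out term by term
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in 1:(k - 2)) {
    tj <- knots[j]
    cub <- function(u) ifelse(u > 0, u^3, 0)
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - knots[1])^2
  }
  out
}

# Direct weighted normal-equations solve
oracle_wls <- function(X, y, w) {
  solve(t(X) %*% (X * w), t(X) %*% (w * y))
}

# Minimal single-patient bundle builder for cohort/panel unit tests
tiny_bundle <- function(weights_days = c(-10), weights_kg = c(85),
                        baseline_day = 2000, drug = "lisinopril",
                        extra_rx = NULL, conditions = NULL,
                        death_day = numeric(), sex = "M",
                        bp_day = baseline_day, enc_days = c(baseline_day - 200,
                                                            baseline_day)) {
  rx <- data.table::data.table(patient_id = 1L, drug = drug,
                               fill_day = baseline_day, days_supply = 30,
                               quantity = 30, refills = 0)
  if (!is.null(extra_rx)) rx <- rbind(rx, extra_rx)
  vit <- data.table::data.table(
    patient_id = 1L, day = baseline_day + weights_days,
    weight_kg = weights_kg, systolic = NA_real_, diastolic = NA_real_)
  if (!is.na(bp_day)) {
    vit <- rbind(vit, data.table::data.table(
      patient_id = 1L, day = bp_day, weight_kg = NA_real_,
      systolic = 140, diastolic = 85))
  }
  structure(list(
    demographics = data.table::data.table(
      patient_id = 1L, sex = sex, race = "White", ethnicity = "NonHispanic",
      site = "A", birth_day = baseline_day - round(50 * 365.25),
      height_cm = 175, medicaid = 0L, smoking = "never"),
    encounters = data.table::data.table(patient_id = 1L, day = enc_days),
    prescriptions = rx,
    vitals = vit,
    conditions = conditions %||%
      data.table::data.table(patient_id = integer(), category = character(),
                             day = integer()),
    death = data.table::data.table(
      patient_id = if (length(death_day)) 1L else integer(),
      death_day = death_day),
    truth = NULL, config = NULL), class = "ehr_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random fill sequence for the censoring-oracle equivalence tests
random_fills <- function(seed) {
  set.seed(seed)
  n <- sample(1:8, 1)
  day <- cumsum(c(0, sample(0:120, n - 1, replace = TRUE)))
  supply <- sample(c(NA_real_, 10, 30, 60, 90), n, replace = TRUE)
  qty <- ifelse(runif(n) < 0.4, NA_real_,
                sample(c(30, 60, 90), n, replace = TRUE))
  refills <- sample(c(NA_real_, 0, 1, 2), n, replace = TRUE)
  data.table::data.table(patient_id = 1L, drug = "lisinopril", fill_day = day,
                         days_supply = supply, quantity = qty,
                         refills = refills)
}
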