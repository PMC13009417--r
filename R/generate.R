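# Synthetic EHR generator and its closed-form ground truth.

#' Ground truth implied by a simulation configuration
#'
#' Closed-form per-arm mean weight change under full adherence
#' (`theta_d (1 - exp(-m / tau_d)) + covariate_effect * P(obesity)` for
#' months m >= 1, zero at month 0), contrasts versus the reference arm, and
#' the probability of gaining at least 5% of the measured baseline weight.
#' Risks integrate the exact normal-CDF expression for the measurement-noise
#' distribution over a large fixed-seed draw of the covariate and
#' baseline-weight distribution, so their only error is a negligible
#' Monte-Carlo term over covariates.
#'
#' @param config a [sim_config()].
#' @param n_integration draws used for the risk integral (default 200000).
#' @return object of class `ground_truth` with matrices `mean`, `contrast`,
#'   `risk` (arms x months 0..24).
#' @export
ground_truth <- function(config, n_integration = 200000L) {
  months <- 0:FOLLOWUP_MONTHS
  arms <- config$arms
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(104729L) # fixed: truth depends only on config parameters
  cv <- r_covariates(n_integration, config)
  px <- mean(cv$obesity)
  mean_m <- matrix(0, length(arms), length(months),
                   dimnames = list(arms, months))
  for (a in arms) {
    mean_m[a, ] <- trajectory_mean(config, a, months) +
      config$covariate_effect * px * (months >= 1)
  }
  contrast <- sweep(mean_m, 2L, mean_m[config$reference, ])
  # risk of >= 5% gain: a flagged month-t change satisfies
  # mu + delta x + e_t - e_0 >= 0.05 (T + e_0); conditioning on the drawn
  # (T, e_0, x) leaves only e_t ~ N(0, sigma^2), giving an exact normal CDF
  # averaged over the covariate draw
  risk <- matrix(0, length(arms), length(months), dimnames = list(arms, months))
  sig <- config$sigma_resid
  thr <- 0.05 * cv$w0 + cv$e0 - config$covariate_effect * cv$obesity
  for (a in arms) {
    for (j in seq_along(months)) {
      m <- months[j]
      if (m == 0) next
      mu <- trajectory_mean(config, a, m)
      risk[a, j] <- mean(pnorm((mu - thr) / sig))
    }
  }
  structure(list(arms = arms, reference = config$reference, months = months,
                 mean = mean_m, contrast = contrast, risk = risk,
                 p_obesity = px),
            class = "ground_truth")
}

#' Look up ground-truth values
#' @param truth a `ground_truth` object.
#' @param arm,month arm label(s) and month(s) in 0..24.
#' @param what one of `"mean"`, `"contrast"`, `"risk"`.
#' @return numeric vector of truths.
#' @export
true_value <- function(truth, arm, month, what = c("mean", "contrast", "risk")) {
  what <- match.arg(what)
  truth[[what]][cbind(arm, as.character(month))]
}

#' Generate a synthetic EHR bundle with known ground truth
#'
#' Emits the five raw tables (demographics, encounters, prescriptions,
#' vitals, conditions) plus death dates, shaped like a minimal EHR
#' common-data-model extract, together with the [ground_truth()] of the
#' configuration. Treatment assignment is confounded by baseline covariates;
#' discontinuation and weight measurement are monthly Bernoulli hazards
#' driven by baseline obesity, age, and the last measured weight change;
#' prescriptions are 30-day fills truncated at the simulated stop month with
#' the configured fraction of blank supply fields.
#'
#' @param config a [sim_config()].
#' @param truth optional precomputed [ground_truth()] for this configuration
#'   (the truth does not depend on the seed, so repeated-simulation studies
#'   can compute it once).
#' @return list of class `ehr_bundle` with elements `demographics`,
#'   `encounters`, `prescriptions`, `vitals`, `conditions`, `death`,
#'   `truth`, and `config`.
#' @export
generate_bundle <- function(config, truth = NULL) {
  if (!inherits(config, "sim_config")) stop2("'config' must be a sim_config")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  arms <- config$arms
  er <- config$exclusion_rates
  sig <- config$sigma_resid
  cv <- r_covariates(n, config)
  pid <- seq_len(n)
  b <- sample(365:3560, n, replace = TRUE) # initiation days, 2011..2019-ish

  # confounded multinomial-logit assignment (Gumbel-max draw)
  X <- cbind(intercept = 1, obesity = cv$obesity, age_z = cv$z_age,
             sexF = as.numeric(cv$sex == "F"))
  lin <- X %*% t(config$assignment_coefs)
  gumbel <- -log(-log(matrix(runif(n * length(arms)), n)))
  arm <- arms[max.col(lin + gumbel)]

  # planted exclusion events (days relative to initiation)
  plant <- function(rate) runif(n) < rate
  cond_list <- list(
    cancer = list(ind = plant(er[["cancer"]]), rel = sample(-800:100, n, TRUE)),
    pregnancy = list(ind = plant(er[["pregnancy"]]) & cv$sex == "F",
                     rel = sample(-600:50, n, TRUE)),
    bariatric_surgery = list(ind = plant(er[["bariatric"]]),
                             rel = sample(-1500:100, n, TRUE)),
    heart_failure = list(ind = plant(er[["heart_failure"]]),
                         rel = sample(-700:100, n, TRUE)))
  conmed <- list(
    anti_obesity = list(ind = plant(er[["conmed"]]), rel = sample(-120:120, n, TRUE)),
    steroid = list(ind = plant(er[["conmed"]]), rel = sample(-120:120, n, TRUE)),
    stimulant = list(ind = plant(er[["conmed"]]), rel = sample(-120:120, n, TRUE)),
    other_antihypertensive = list(ind = plant(er[["prior_antihypertensive"]]),
                                  rel = -sample(1:400, n, TRUE)))
  poly <- plant(er[["polytherapy"]])
  no_enc <- plant(er[["no_prior_encounter"]])
  no_w0 <- plant(er[["missing_baseline_weight"]])
  no_bp <- plant(er[["missing_bp"]])
  cv[plant(er[["missing_race"]]), race := NA_character_]
  cv[plant(er[["missing_sex"]]), sex := NA_character_]
  death_day <- rep(NA_real_, n)
  dies <- plant(er[["death"]])
  death_day[dies] <- b[dies] + sample(1:FOLLOWUP_DAYS, sum(dies), TRUE)

  # baseline measurements (e0 drawn inside r_covariates so the documented
  # obesity flag is consistent with the recorded baseline weight)
  u0 <- sample(0:89, n, TRUE)
  w0_day <- b - u0
  w0_val <- cv$w0
  sys0 <- rnorm(n, 138, 15) + 8 * cv$htn_dx
  dia0 <- rnorm(n, 84, 9) + 5 * cv$htn_dx
  has_prior_w <- runif(n) < config$population$p_prior_weight
  prior_day <- b - sample(150:250, n, TRUE)
  prior_val <- cv$tweight + rnorm(n, 0, sig)

  # monthly processes: stop hazard and weight measurement, both driven by
  # obesity, age, and the last *measured* weight change entering the month
  dc <- config$discontinuation_coefs
  mc <- config$measurement_coefs
  delta <- config$covariate_effect
  lwc <- numeric(n)
  adherent <- rep(TRUE, n)
  stop_month <- rep(NA_integer_, n)
  extra_enc <- vector("list", FOLLOWUP_MONTHS)
  meas_rows <- vector("list", FOLLOWUP_MONTHS)
  alive_at <- function(day) is.na(death_day) | day < death_day
  for (t in seq_len(FOLLOWUP_MONTHS)) {
    h <- plogis(dc[["intercept"]] + dc[["obesity"]] * cv$obesity +
                  dc[["age_z"]] * cv$z_age + dc[["lwc"]] * lwc)
    stops <- adherent & (runif(n) < h)
    stop_month[stops] <- t
    adherent[stops] <- FALSE
    pm <- plogis(mc[["intercept"]] + mc[["obesity"]] * cv$obesity +
                   mc[["age_z"]] * cv$z_age + mc[["lwc"]] * lwc)
    meas <- runif(n) < pm
    day_t <- b + DAYS_PER_MONTH * t
    w_t <- cv$tweight + trajectory_mean(config, arm, t) + delta * cv$obesity +
      rnorm(n, 0, sig)
    sel <- which(meas & alive_at(day_t))
    meas_rows[[t]] <- data.table(patient_id = pid[sel], day = day_t[sel],
                                 weight_kg = w_t[sel])
    lwc[sel] <- w_t[sel] - w0_val[sel]
    ext <- which(runif(n) < 0.1 & alive_at(day_t + 15L))
    extra_enc[[t]] <- data.table(patient_id = pid[ext], day = day_t[ext] + 15L)
  }

  # prescriptions: one 30-day fill per covered month, truncated at the stop
  # month (never-stoppers stay covered through month 24) and at death
  n_fills <- ifelse(is.na(stop_month), FOLLOWUP_MONTHS + 1L, stop_month)
  rx <- data.table(patient_id = rep(pid, n_fills),
                   drug = rep(arm, n_fills),
                   fill_day = rep(b, n_fills) +
                     DAYS_PER_MONTH * (sequence(n_fills) - 1L))
  rx <- rx[is.na(death_day[patient_id]) | fill_day < death_day[patient_id]]
  rx[, `:=`(days_supply = 30, quantity = 30, refills = 0)]
  blank <- runif(nrow(rx)) < config$p_missing_supply
  rx[blank, `:=`(days_supply = NA_real_, quantity = NA_real_, refills = NA_real_)]
  # planted polytherapy: a second study drug filled on the initiation day
  if (any(poly)) {
    second <- vapply(arm[poly], function(a) sample(setdiff(arms, a), 1L), "")
    rx <- rbind(rx, data.table(patient_id = pid[poly], drug = second,
                               fill_day = b[poly], days_supply = 30,
                               quantity = 30, refills = 0))
  }
  # concomitant / prior medications
  for (nm in names(conmed)) {
    sel <- conmed[[nm]]$ind
    if (any(sel)) {
      rx <- rbind(rx, data.table(patient_id = pid[sel], drug = nm,
                                 fill_day = b[sel] + conmed[[nm]]$rel[sel],
                                 days_supply = 30, quantity = 30, refills = 0))
    }
  }

  # encounters: one >= 6 months before initiation (unless planted away),
  # the initiation-day encounter, every measurement day, and noise visits
  enc <- rbindlist(c(
    list(data.table(patient_id = pid[!no_enc],
                    day = b[!no_enc] - 181L - sample(0:300, sum(!no_enc), TRUE)),
         data.table(patient_id = pid, day = b),
         data.table(patient_id = pid[has_prior_w], day = prior_day[has_prior_w]),
         data.table(patient_id = pid[!no_w0], day = w0_day[!no_w0])),
    lapply(meas_rows, function(d) d[, .(patient_id, day)]),
    extra_enc))
  setorder(enc, patient_id, day)
  enc <- unique(enc)

  vit_base <- data.table(patient_id = pid[!no_w0], day = w0_day[!no_w0],
                         weight_kg = w0_val[!no_w0],
                         systolic = NA_real_, diastolic = NA_real_)
  vit_bp <- data.table(patient_id = pid[!no_bp], day = b[!no_bp],
                       weight_kg = NA_real_, systolic = sys0[!no_bp],
                       diastolic = dia0[!no_bp])
  vit_prior <- data.table(patient_id = pid[has_prior_w],
                          day = prior_day[has_prior_w],
                          weight_kg = prior_val[has_prior_w],
                          systolic = NA_real_, diastolic = NA_real_)
  vit_fu <- rbindlist(meas_rows)
  vit_fu[, `:=`(systolic = NA_real_, diastolic = NA_real_)]
  vitals <- rbindlist(list(vit_base, vit_bp, vit_prior, vit_fu),
                      use.names = TRUE)
  setorder(vitals, patient_id, day)

  conds <- rbindlist(c(
    lapply(names(cond_list), function(nm) {
      sel <- cond_list[[nm]]$ind
      data.table(patient_id = pid[sel], category = nm,
                 day = b[sel] + cond_list[[nm]]$rel[sel])
    }),
    list(data.table(patient_id = pid[cv$htn_dx == 1L], category = "hypertension",
                    day = b[cv$htn_dx == 1L] - sample(1:400, sum(cv$htn_dx), TRUE)))))
  setorder(conds, patient_id, day)

  demo <- data.table(patient_id = pid, sex = cv$sex, race = cv$race,
                     ethnicity = cv$ethnicity, site = cv$site,
                     birth_day = b - as.integer(round(cv$age * 365.25)),
                     height_cm = cv$height_cm, medicaid = cv$medicaid,
                     smoking = cv$smoking)

  structure(list(
    demographics = demo,
    encounters = enc,
    prescriptions = rx[order(patient_id, fill_day, drug)],
    vitals = vitals,
    conditions = conds,
    death = data.table(patient_id = pid[dies], death_day = death_day[dies]),
    truth = truth %||% ground_truth(config),
    config = config
  ), class = "ehr_bundle")
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>", nrow(x$demographics), "patients;",
      nrow(x$prescriptions), "prescriptions;", nrow(x$vitals), "vitals rows\n")
  invisible(x)
}
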