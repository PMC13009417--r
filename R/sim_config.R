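# Simulation configuration for the synthetic EHR generator. The generator
# encodes a known causal structure: confounded arm assignment, a smooth
# saturating-exponential weight-change trajectory per arm plus a constant
# obesity shift, covariate-driven monthly discontinuation, and
# covariate-driven monthly weight measurement, so every downstream stage can
# be checked against closed-form ground truth.

#' Default study arms
#' @return character vector of the seven drug labels (reference first).
#' @export
default_arms <- function() {
  c("lisinopril", "amlodipine", "atenolol", "hydrochlorothiazide",
    "losartan", "metoprolol", "propranolol")
}

# Per-arm trajectory asymptotes (kg) and time constants (months):
# mu_d(t) = theta_d * (1 - exp(-t / tau_d)). Asymptotes chosen so six-month
# means sit near the reported per-arm absolute changes; tau = 6 months gives
# most of the change within the first year.
default_trajectory <- function(arms = default_arms()) {
  theta <- c(lisinopril = -1.10, amlodipine = -0.70, atenolol = 0.15,
             hydrochlorothiazide = 0.00, losartan = -0.25,
             metoprolol = 1.10, propranolol = 0.55)
  data.table(arm = arms,
             theta = unname(theta[arms]),
             tau = rep(6, length(arms)))
}

# Multinomial-logit assignment coefficients (reference arm = first row, all
# zero). Obesity coefficients follow the observed obesity gradient across
# arms (thiazide/ARB initiators heavier, beta-blocker initiators leaner);
# propranolol skews young and female.
default_assignment_coefs <- function(arms = default_arms()) {
  m <- matrix(0, nrow = length(arms), ncol = 4L,
              dimnames = list(arms, c("intercept", "obesity", "age_z", "sexF")))
  def <- rbind(
    lisinopril          = c(0.00,  0.0,  0.0, 0.0),
    amlodipine          = c(-1.02, 0.5,  0.3, -0.1),
    atenolol            = c(-1.97, -0.8, 0.1, 0.6),
    hydrochlorothiazide = c(-1.10, 0.8, -0.2, 0.7),
    losartan            = c(-1.64, 0.6,  0.4, 0.1),
    metoprolol          = c(-0.88, -0.7, 0.3, 0.2),
    propranolol         = c(-1.19, -1.0, -0.8, 0.8))
  known <- intersect(arms, rownames(def))
  m[known, ] <- def[known, ]
  m
}

#' Simulation configuration
#'
#' Assembles and validates the generator configuration. All dates are integer
#' day offsets from a fixed epoch (day 0 = 2010-01-01); follow-up is 24
#' thirty-day months.
#'
#' @param n_patients number of raw patients to generate (before eligibility).
#' @param arms drug labels; the first is the reference arm.
#' @param trajectory_params `data.frame` with `arm`, `theta` (asymptotic mean
#'   weight change, kg) and `tau` (time constant, months > 0).
#' @param assignment_coefs matrix `arms x (intercept, obesity, age_z, sexF)`
#'   of multinomial-logit coefficients for confounded arm assignment.
#' @param discontinuation_coefs named vector `(intercept, obesity, age_z,
#'   lwc)`: logit of the monthly hazard of stopping the drug; `lwc` is the
#'   coefficient on the last measured weight change (kg). An `-Inf` intercept
#'   switches discontinuation off.
#' @param measurement_coefs named vector `(intercept, obesity, age_z, lwc)`:
#'   logit of the monthly probability that weight is measured.
#' @param covariate_effect additive shift (kg) in weight change for patients
#'   with baseline obesity, constant across follow-up months. This is the
#'   planted outcome-covariate dependence that makes informative measurement
#'   and nonadherence biasing.
#' @param sigma_resid within-patient measurement noise SD (kg).
#' @param sigma_intercept between-patient random intercept SD (kg) on weight
#'   level (cancels out of weight change; affects the 5%-gain threshold).
#' @param p_missing_supply fraction of prescriptions with blank
#'   days-supply/quantity/refills (default 0.5).
#' @param exclusion_rates named probabilities for planted exclusion events;
#'   see `default_exclusion_rates()`.
#' @param seed integer RNG seed; identical `(config, seed)` yields identical
#'   tables.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       arms = default_arms(),
                       trajectory_params = default_trajectory(arms),
                       assignment_coefs = default_assignment_coefs(arms),
                       discontinuation_coefs = c(intercept = qlogis(0.05),
                                                 obesity = 0.4, age_z = 0.2,
                                                 lwc = 0.2),
                       measurement_coefs = c(intercept = qlogis(0.25),
                                             obesity = 0.8, age_z = 0.3,
                                             lwc = 0.3),
                       covariate_effect = -1.2,
                       sigma_resid = 1.5,
                       sigma_intercept = 2.0,
                       p_missing_supply = 0.5,
                       exclusion_rates = default_exclusion_rates(),
                       seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  if (!is.character(arms) || length(arms) < 2L || anyDuplicated(arms)) {
    stop2("configuration error: 'arms' must be >= 2 distinct drug labels")
  }
  tp <- as.data.table(trajectory_params)
  if (!all(c("arm", "theta", "tau") %in% names(tp)) ||
      !setequal(tp$arm, arms)) {
    stop2("configuration error: 'trajectory_params' needs arm/theta/tau rows ",
          "for every arm")
  }
  if (any(!is.finite(tp$tau)) || any(tp$tau <= 0)) {
    stop2("configuration error: 'trajectory_params$tau' must be > 0")
  }
  check_prob(p_missing_supply, "p_missing_supply")
  er <- exclusion_rates
  defr <- default_exclusion_rates()
  miss <- setdiff(names(defr), names(er))
  er <- c(er, defr[miss])
  for (nm in names(er)) check_prob(er[[nm]], paste0("exclusion_rates$", nm))
  coef_names <- c("intercept", "obesity", "age_z", "lwc")
  for (what in c("discontinuation_coefs", "measurement_coefs")) {
    v <- get(what)
    if (!all(coef_names %in% names(v))) {
      stop2("configuration error: '", what, "' must have names ",
            paste(coef_names, collapse = ", "))
    }
  }
  if (!is.matrix(assignment_coefs) ||
      nrow(assignment_coefs) != length(arms) ||
      ncol(assignment_coefs) != 4L) {
    stop2("configuration error: 'assignment_coefs' must be a ",
          length(arms), " x 4 matrix")
  }
  structure(list(
    n_patients = n_patients,
    arms = arms,
    reference = arms[1L],
    trajectory_params = tp[match(arms, tp$arm)],
    assignment_coefs = assignment_coefs,
    discontinuation_coefs = discontinuation_coefs[coef_names],
    measurement_coefs = measurement_coefs[coef_names],
    covariate_effect = covariate_effect,
    sigma_resid = sigma_resid,
    sigma_intercept = sigma_intercept,
    p_missing_supply = p_missing_supply,
    exclusion_rates = er,
    population = default_population(),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default planted exclusion-event probabilities
#' @return named numeric vector of per-patient event probabilities.
#' @export
default_exclusion_rates <- function() {
  c(cancer = 0.03, pregnancy = 0.02, bariatric = 0.01, heart_failure = 0.02,
    conmed = 0.02, prior_antihypertensive = 0.03, polytherapy = 0.01,
    no_prior_encounter = 0.01, missing_baseline_weight = 0.015,
    missing_bp = 0.01, missing_race = 0.01, missing_sex = 0.005,
    death = 0.008)
}

# Fixed marginal covariate distribution of the source population (moments
# loosely matched to the study's baseline table: mean age 53.3 (SD 14),
# mean BMI 30.6 (SD 7.3), 56% female, 72% White, 63% hypertension dx).
default_population <- function() {
  list(age_mean = 53.3, age_sd = 14, age_clip = c(18, 90),
       bmi_mean = 30.6, bmi_sd = 7.3, bmi_clip = c(16, 60),
       p_female = 0.56,
       race_levels = c("White", "Black", "Asian", "Other"),
       race_probs = c(0.72, 0.20, 0.03, 0.05),
       p_hispanic = 0.07,
       sites = c("A", "B", "C", "D"),
       p_medicaid = 0.15,
       smoking_levels = c("never", "former", "current"),
       smoking_probs = c(0.55, 0.25, 0.20),
       p_htn_dx = 0.63,
       p_prior_weight = 0.6,
       height_mean = c(F = 163, M = 177), height_sd = 7)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients,", length(x$arms), "arms (",
      paste(x$arms, collapse = ", "), ")\n")
  cat("  obesity shift:", x$covariate_effect, "kg; sigma_resid:",
      x$sigma_resid, "kg; p(missing supply):", x$p_missing_supply, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Draw the baseline covariate table shared by the generator and the
# ground-truth integration. `tweight` is the true (error-free) weight in kg,
# including the between-patient random intercept; `e0` is the baseline
# measurement error and `w0` = tweight + e0 the weight the EHR records at
# baseline. The obesity flag is defined from the *observed* baseline BMI so
# the generator's confounder is exactly the covariate the cohort builder
# later derives (documented obesity, not latent obesity).
r_covariates <- function(n, config) {
  pop <- config$population
  sex <- ifelse(runif(n) < pop$p_female, "F", "M")
  race <- sample(pop$race_levels, n, replace = TRUE, prob = pop$race_probs)
  ethnicity <- ifelse(runif(n) < pop$p_hispanic, "Hispanic", "NonHispanic")
  site <- sample(pop$sites, n, replace = TRUE)
  medicaid <- as.integer(runif(n) < pop$p_medicaid)
  smoking <- sample(pop$smoking_levels, n, replace = TRUE,
                    prob = pop$smoking_probs)
  age <- clip(rnorm(n, pop$age_mean, pop$age_sd), pop$age_clip[1], pop$age_clip[2])
  height <- rnorm(n, pop$height_mean[sex], pop$height_sd)
  bmi <- clip(rnorm(n, pop$bmi_mean, pop$bmi_sd), pop$bmi_clip[1], pop$bmi_clip[2])
  tweight <- bmi * (height / 100)^2 + rnorm(n, 0, config$sigma_intercept)
  e0 <- rnorm(n, 0, config$sigma_resid)
  w0 <- tweight + e0
  obs_bmi <- w0 / (height / 100)^2
  data.table(sex = sex, race = race, ethnicity = ethnicity, site = site,
             medicaid = medicaid, smoking = smoking,
             age = age, z_age = (age - pop$age_mean) / pop$age_sd,
             height_cm = height, bmi = bmi, e0 = e0, w0 = w0,
             obesity = as.integer(obs_bmi >= 30), tweight = tweight,
             htn_dx = as.integer(runif(n) < pop$p_htn_dx))
}

# Marginal probability of documented baseline obesity. The observed BMI mixes
# the latent BMI draw with the random intercept and baseline measurement
# error, so the probability is integrated over a large fixed-seed draw of the
# population model rather than read off a single normal CDF.
p_obesity <- function(config, n_integration = 200000L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(104729L)
  mean(r_covariates(n_integration, config)$obesity)
}

# mu_d(t): true mean weight change (kg) at continuous month t under
# full adherence, excluding the obesity shift.
trajectory_mean <- function(config, arm, t) {
  tp <- config$trajectory_params
  i <- match(arm, tp$arm)
  tp$theta[i] * (1 - exp(-t / tp$tau[i]))
}
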