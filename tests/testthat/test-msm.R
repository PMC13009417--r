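flat_panel <- function(n = 40, months = 12L, arms = "a", y_fun = function(arm, m) 2) {
  grid <- data.table::CJ(patient_id = seq_len(n), month = seq_len(months))
  grid[, arm := rep(rep_len(arms, n), each = months)]
  grid[, `:=`(measured = 1L, y = y_fun(arm, month), gain5 = 0L,
              obesity = 0L, age10 = 5, sexF = 0L)]
  grid
}

test_that("a constant outcome is fit exactly by the intercept", {
  p <- flat_panel()
  fit <- fit_msm(p, weights = 1, covariates = NULL,
                 spec = spline_spec(), arms = "a")
  expect_equal(unname(standardize(fit, p[month == 1], "a", c(3L, 6L, 12L))),
               c(2, 2, 2), tolerance = 1e-10)
})

test_that("a clean two-arm separation puts exactly 1.0 on the arm coefficient", {
  p <- flat_panel(n = 40, arms = c("a", "b"),
                  y_fun = function(arm, m) ifelse(arm == "b", 1, 0))
  fit <- fit_msm(p, weights = 1, covariates = NULL, arms = c("a", "b"))
  expect_equal(unname(fit$coef["armb"]), 1, tolerance = 1e-10)
  m <- standardize(fit, p[month == 1], c("a", "b"), c(6L, 6L))
  expect_equal(unname(m[2] - m[1]), 1, tolerance = 1e-10)
})

test_that("the weighted fit equals an independent normal-equations solve", {
  set.seed(314)
  p <- flat_panel(n = 60, arms = c("a", "b"),
                  y_fun = function(arm, m) rnorm(length(m)))
  p[, obesity := rbinom(.N, 1, 0.5)]
  w <- runif(nrow(p), 0.5, 4)
  fit <- fit_msm(p, weights = w, covariates = "obesity", arms = c("a", "b"))
  X <- trialemu:::msm_design(p$arm, p$month,
                             trialemu:::cov_matrix(p, "obesity"),
                             c("a", "b"), spline_spec(), knots = fit$knots)
  ref <- oracle_wls(X, p$y, w)
  expect_equal(unname(fit$coef), unname(drop(ref)), tolerance = 1e-8)
})

test_that("standardization averages predictions over covariate strata", {
  # two equal strata with predictions 1.0 and 3.0 -> 2.0
  p <- flat_panel(n = 40, y_fun = function(arm, m) 0)
  p[, obesity := rep(c(0L, 1L), each = nrow(p) / 2)]
  p[, y := 1 + 2 * obesity]
  fit <- fit_msm(p, weights = 1, covariates = "obesity", arms = "a")
  coh <- p[month == 1, .(patient_id, arm, obesity, age10, sexF)]
  expect_equal(unname(standardize(fit, coh, "a", 6L)), 2, tolerance = 1e-8)
  # with no covariates standardization is exactly the fitted value
  fit0 <- fit_msm(p, weights = 1, covariates = NULL, arms = "a")
  expect_equal(unname(standardize(fit0, coh, "a", 6L)),
               unname(trialemu:::eta_base(fit0, "a", 6L)))
  expect_error(standardize(fit0, coh, "a", 30L), "month")
})

test_that("standardized predictions are continuous and linear beyond boundary knots", {
  set.seed(11)
  p <- flat_panel(n = 200, months = 24L,
                  y_fun = function(arm, m) -1 * (1 - exp(-m / 6)) + rnorm(length(m), 0, 0.2))
  fit <- fit_msm(p, weights = 1, covariates = NULL, arms = "a")
  coh <- p[month == 1]
  mu <- standardize(fit, coh, rep("a", 24), 1:24)
  expect_true(all(is.finite(mu)))
  # beyond the last knot (~22.9) the fitted trend is exactly linear
  ts <- seq(23, 24, by = 0.1)
  upper <- standardize(fit, coh, rep("a", length(ts)), ts)
  expect_lt(max(abs(diff(diff(upper)))), 1e-8)
})

test_that("contrasts subtract the reference and vanish on it", {
  means <- data.table::data.table(arm = rep(c("lisinopril", "metoprolol"), 2),
                                  month = rep(c(6L, 12L), each = 2),
                                  mean_change = c(-0.7, 0.7, -0.6, 1.0))
  out <- arm_contrasts(means)
  expect_equal(out[arm == "lisinopril", contrast_vs_ref], c(0, 0))
  expect_equal(out[arm == "metoprolol" & month == 6, contrast_vs_ref], 1.4)
})

test_that("a flag that never fires yields zero risks and undefined RRs", {
  p <- flat_panel(n = 80, arms = c("lisinopril", "metoprolol"),
                  y_fun = function(arm, m) 0)
  coh <- p[month == 1, .(patient_id, arm, obesity, age10, sexF)]
  expect_warning(
    out <- risk_5pct_rr(p, weights = 1, cohort = coh, covariates = NULL,
                        months = 6L),
    "RR undefined")
  expect_true(all(out$risk5 < 1e-6))
  expect_equal(out[arm == "lisinopril", rr_vs_ref], 1)
  expect_true(is.na(out[arm == "metoprolol", rr_vs_ref]))
})

test_that("planted risks produce the right standardized RR", {
  set.seed(2024)
  p <- flat_panel(n = 3000, months = 6L, arms = c("lisinopril", "metoprolol"),
                  y_fun = function(arm, m) 0)
  p[, gain5 := rbinom(.N, 1, ifelse(arm == "metoprolol", 0.15, 0.10))]
  coh <- p[month == 1, .(patient_id, arm, obesity, age10, sexF)]
  out <- risk_5pct_rr(p, weights = 1, cohort = coh, covariates = NULL,
                      months = 3L)
  expect_equal(out[arm == "metoprolol", rr_vs_ref], 1.5, tolerance = 0.15)
})
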