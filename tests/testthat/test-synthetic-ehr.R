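test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- sim_config(400, seed = 123)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  for (tb in c("demographics", "encounters", "prescriptions", "vitals",
               "conditions", "death")) {
    expect_identical(b1[[tb]], b2[[tb]])
  }
  b3 <- generate_bundle(sim_config(400, seed = 124))
  expect_false(identical(b1$vitals, b3$vitals))
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(0), "n_patients")
  expect_error(sim_config(100, p_missing_supply = 1.5), "p_missing_supply")
  tp <- default_trajectory()
  tp$tau[2] <- -1
  expect_error(sim_config(100, trajectory_params = tp), "tau")
  expect_error(sim_config(100, exclusion_rates = c(cancer = 2)),
               "exclusion_rates")
})

test_that("missing-supply fraction is honored and zero means fully populated", {
  cfg0 <- sim_config(500, seed = 5, p_missing_supply = 0)
  b0 <- generate_bundle(cfg0)
  study <- b0$prescriptions[drug %in% default_arms()]
  expect_false(anyNA(study$days_supply))
  cfg5 <- sim_config(500, seed = 5, p_missing_supply = 0.5)
  frac <- mean(is.na(generate_bundle(cfg5)$prescriptions[
    drug %in% default_arms(), days_supply]))
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("ground truth obeys its structural invariants", {
  cfg <- sim_config(100, seed = 1)
  tr <- ground_truth(cfg, n_integration = 20000L)
  expect_true(all(tr$mean[, "0"] == 0))
  expect_true(all(tr$contrast["lisinopril", ] == 0))
  expect_true(all(tr$risk >= 0 & tr$risk <= 1))
  # null trajectories and no covariate shift: all contrasts identically zero
  tp <- default_trajectory()
  tp$theta <- 0
  cfg0 <- sim_config(100, seed = 1, trajectory_params = tp)
  tr0 <- ground_truth(cfg0, n_integration = 20000L)
  expect_true(all(abs(tr0$contrast) < 1e-12))
})

test_that("the saturating-exponential truth matches its closed form", {
  tp <- default_trajectory()
  tp$theta <- -1
  tp$tau <- 6
  cfg <- sim_config(100, seed = 1, trajectory_params = tp,
                    covariate_effect = 0)
  tr <- ground_truth(cfg, n_integration = 1000L)
  expect_equal(unname(tr$mean["lisinopril", "6"]), -1 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(unname(tr$mean["metoprolol", "12"]), -1 * (1 - exp(-2)),
               tolerance = 1e-12)
})

test_that("every non-planted patient has a prior encounter and a baseline weight", {
  cfg <- sim_config(600, seed = 9)
  b <- generate_bundle(cfg)
  enc <- b$encounters
  rx1 <- b$prescriptions[drug %in% default_arms(),
                         .(b0 = min(fill_day)), by = patient_id]
  has_early <- enc[rx1, on = "patient_id"][day <= b0 - 180L,
                                           uniqueN(patient_id)]
  expect_gt(has_early / nrow(rx1), 0.97)
  w0 <- b$vitals[!is.na(weight_kg)][rx1, on = "patient_id"][
    day >= b0 - 90L & day <= b0, uniqueN(patient_id)]
  expect_gt(w0 / nrow(rx1), 0.96)
})

test_that("measurement frequency is monotone in the measurement intercept", {
  fracs <- vapply(qlogis(c(0.1, 0.3, 0.6)), function(ic) {
    mc <- c(intercept = ic, obesity = 0, age_z = 0, lwc = 0)
    b <- generate_bundle(sim_config(600, seed = 31, measurement_coefs = mc))
    out <- build_cohort(b)
    p <- build_panel(out$cohort, b)
    mean(p$measured)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  expect_equal(fracs[2], 0.3, tolerance = 0.05)
})

test_that("bundles round-trip through the CSV directory format", {
  cfg <- sim_config(150, seed = 77)
  b <- generate_bundle(cfg)
  dir <- file.path(tempdir(), "bundle-rt")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  for (tb in c("encounters", "prescriptions", "conditions", "death")) {
    t1 <- as.data.frame(b[[tb]])
    t2 <- as.data.frame(b2[[tb]])
    expect_equal(nrow(t1), nrow(t2))
    if (nrow(t1)) expect_equal(t1, t2, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(b2$truth$mean, b$truth$mean, tolerance = 1e-12)
  expect_equal(b2$truth$risk, b$truth$risk, tolerance = 1e-12)
  # missing demographics survive the text round trip as missing
  expect_identical(build_cohort(b2)$attrition$reason,
                   build_cohort(b)$attrition$reason)
  unlink(dir, recursive = TRUE)
})

test_that("with all hazards unconfounded the observed means converge to truth", {
  # confounding off-switch at moderate n: covariate coefficients zeroed
  zero <- function(v) {v[c("obesity", "age_z", "lwc")] <- 0; v}
  cfg <- sim_config(6000, seed = 55,
                    assignment_coefs = {
                      a <- default_assignment_coefs()
                      a[, c("obesity", "age_z", "sexF")] <- 0
                      a
                    },
                    discontinuation_coefs = zero(c(intercept = qlogis(0.05),
                                                   obesity = 0.4, age_z = 0.2,
                                                   lwc = 0.2)),
                    measurement_coefs = zero(c(intercept = qlogis(0.3),
                                               obesity = 0.8, age_z = 0.3,
                                               lwc = 0.3)))
  b <- generate_bundle(cfg)
  out <- build_cohort(b)
  p <- build_panel(out$cohort, b)
  p <- out$cohort[, .(patient_id, arm)][p, on = "patient_id"]
  obs <- p[measured == 1L & month == 6L,
           .(m = mean(y), se = sd(y) / sqrt(.N)), by = arm]
  obs[, truth := true_value(b$truth, arm, 6L, "mean")]
  expect_true(all(abs(obs$m - obs$truth) < 3 * obs$se))
})
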