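test_that("the planted eligibility fixture reproduces every intended verdict", {
  fx <- plant_exclusion_fixture()
  out <- build_cohort(fx)
  att <- merge(out$attrition, fx$intended, by = "patient_id",
               suffixes = c("", ".want"))
  expect_equal(att$eligible, att$eligible.want)
  expect_equal(att$reason, att$reason.want)
  expect_setequal(out$cohort$patient_id,
                  fx$intended[eligible == TRUE, patient_id])
  expect_gte(nrow(out$cohort), 3L)
})

test_that("baseline weight selection takes the closest prior value, averaging same-day duplicates", {
  v <- data.frame(day = c(-80, -10), weight_kg = c(85, 83))
  expect_equal(select_baseline_weight(v, 0), 83)
  v2 <- data.frame(day = c(-10, -10), weight_kg = c(82, 84))
  expect_equal(select_baseline_weight(v2, 0), 83)
  v3 <- data.frame(day = -120, weight_kg = 90)
  expect_true(is.na(select_baseline_weight(v3, 0)))
  # day 0 measurement counts as baseline (not after initiation)
  v4 <- data.frame(day = c(-50, 0), weight_kg = c(90, 88))
  expect_equal(select_baseline_weight(v4, 0), 88)
})

test_that("the plausibility filter drops absurd values and 30 kg/month jumps", {
  v <- data.frame(patient_id = 1L, day = c(0, 10, 20, 30),
                  weight_kg = c(80, 400, 130, 81))
  out <- clean_weights(v)
  # 400 is out of range; 130 implies a > 30 kg jump from the last retained 80
  expect_equal(out$weight_kg, c(80, 81))
})

test_that("new-user identification flags polytherapy, prior use and missing encounters", {
  rx <- data.table::data.table(
    patient_id = c(1L, 2L, 2L, 3L, 3L, 4L),
    drug = c("lisinopril", "lisinopril", "amlodipine", "lisinopril",
             "other_antihypertensive", "lisinopril"),
    fill_day = c(0, 0, 0, 100, -50, 0),
    days_supply = 30, quantity = 30, refills = 0)
  enc <- data.table::data.table(patient_id = c(1L, 2L, 3L, 4L),
                                day = c(-200, -300, -400, -100))
  cand <- identify_new_users(rx, enc)
  expect_equal(cand[patient_id == 1, reason], NA_character_)
  expect_equal(cand[patient_id == 2, reason], "polytherapy at initiation")
  expect_equal(cand[patient_id == 3, reason], "prior antihypertensive use")
  expect_equal(cand[patient_id == 4, reason], "no encounter >=6 months prior")
  expect_equal(cand[patient_id == 1, baseline_day], 0)
  # empty prescriptions give an empty result, not an error
  expect_equal(nrow(identify_new_users(rx[0], enc)), 0L)
})

test_that("exclusion windows agree with a day-by-day oracle on random single-event fixtures", {
  set.seed(4031)
  n <- 1000L
  windows <- list(cancer = c(-365L, 30L), pregnancy = c(-365L, 0L),
                  bariatric_surgery = c(-1095L, 30L),
                  heart_failure = c(-365L, 30L))
  cats <- sample(names(windows), n, replace = TRUE)
  days <- sample(-1300:120, n, replace = TRUE)
  B <- 2000L
  demo <- data.table::data.table(
    patient_id = 1:n, sex = ifelse(cats == "pregnancy", "F", "M"),
    race = "White", ethnicity = "NonHispanic", site = "A",
    birth_day = B - round(50 * 365.25), height_cm = 175, medicaid = 0L,
    smoking = "never")
  bundle <- structure(list(
    demographics = demo,
    encounters = data.table::data.table(
      patient_id = rep(1:n, 2), day = rep(c(B - 200L, B), each = n)),
    prescriptions = data.table::data.table(
      patient_id = 1:n, drug = "lisinopril", fill_day = B,
      days_supply = 30, quantity = 30, refills = 0),
    vitals = rbind(
      data.table::data.table(patient_id = 1:n, day = B - 10L, weight_kg = 85,
                             systolic = NA_real_, diastolic = NA_real_),
      data.table::data.table(patient_id = 1:n, day = B, weight_kg = NA_real_,
                             systolic = 140, diastolic = 85)),
    conditions = data.table::data.table(patient_id = 1:n, category = cats,
                                        day = B + days),
    death = data.table::data.table(patient_id = integer(),
                                   death_day = numeric()),
    truth = NULL, config = NULL), class = "ehr_bundle")
  out <- build_cohort(bundle)
  # oracle: scan the closed window day range for the event day
  in_win <- vapply(seq_len(n), function(i) {
    w <- windows[[cats[i]]]
    days[i] %in% seq(w[1], w[2])
  }, logical(1))
  expect_equal(out$attrition$eligible, !in_win)
})

test_that("attrition conserves candidates and records one reason each", {
  b <- generate_bundle(sim_config(800, seed = 21))
  out <- build_cohort(b)
  expect_equal(nrow(out$cohort) + out$attrition[eligible == FALSE, .N],
               nrow(out$attrition))
  expect_true(all(!is.na(out$attrition[eligible == FALSE, reason])))
  expect_true(all(is.na(out$attrition[eligible == TRUE, reason])))
  expect_true(all(out$cohort$age >= 20 & out$cohort$age <= 80))
})

test_that("recent weight change categorizes against the anchor near day -180", {
  b <- tiny_bundle(weights_days = c(-180, -10), weights_kg = c(82, 85))
  coh <- build_cohort(b)$cohort
  expect_equal(coh$recent_wc, "gain") # 85 - 82 = +3 kg
  b2 <- tiny_bundle(weights_days = c(-180, -10), weights_kg = c(85.2, 85))
  expect_equal(build_cohort(b2)$cohort$recent_wc, "stable")
})
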