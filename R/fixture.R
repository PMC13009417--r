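# Deterministic eligibility fixture: one patient per exclusion criterion,
# each violating exactly one rule, plus fully eligible patients (including
# two with events just *outside* their windows, to pin the window edges).

#' Planted eligibility fixture
#'
#' Builds a small deterministic [ehr_bundle] in which each patient violates
#' exactly one eligibility criterion (age < 20 or > 80, cancer within 1 year
#' prior through 1 month after, pregnancy within 1 year prior, bariatric
#' surgery within 3 years prior through 1 month after, heart failure within
#' 1 year prior through 1 month after, anti-obesity/steroid/stimulant within
#' 1 month either side, prior antihypertensive use, a second study drug on
#' the initiation day, no encounter at least 6 months prior, no baseline
#' weight within 3 months, missing sex or race, no blood pressure within 6
#' months), plus eligible patients. The intended verdicts are attached as
#' the `intended` element: `patient_id`, `eligible`, `reason`.
#'
#' @return `ehr_bundle` with an extra `intended` `data.table`.
#' @export
plant_exclusion_fixture <- function() {
  B <- 2000L # common initiation day
  ids <- 1:21
  age_of <- function(years) B - as.integer(round(years * 365.25))

  demo <- data.table(patient_id = ids, sex = "M", race = "White",
                     ethnicity = "NonHispanic", site = "A",
                     birth_day = age_of(50), height_cm = 172,
                     medicaid = 0L, smoking = "never")
  demo[patient_id == 4, birth_day := age_of(19)]
  demo[patient_id == 5, birth_day := age_of(81)]
  demo[patient_id == 7, sex := "F"]
  demo[patient_id == 17, sex := NA_character_]
  demo[patient_id == 18, race := NA_character_]

  enc <- rbindlist(list(
    data.table(patient_id = ids, day = B - 200L),
    data.table(patient_id = ids, day = B)))
  enc <- enc[!(patient_id == 15 & day == B - 200L)]
  enc <- rbind(enc, data.table(patient_id = 15L, day = B - 100L))

  rx <- data.table(patient_id = ids, drug = "lisinopril", fill_day = B,
                   days_supply = 30, quantity = 30, refills = 0)
  extra_rx <- data.table(
    patient_id = c(10L, 11L, 12L, 13L, 14L),
    drug = c("anti_obesity", "steroid", "stimulant",
             "other_antihypertensive", "amlodipine"),
    fill_day = c(B + 15L, B + 15L, B - 10L, B - 300L, B),
    days_supply = 30, quantity = 30, refills = 0)
  rx <- rbind(rx, extra_rx)

  vit_w <- data.table(patient_id = ids, day = B - 10L, weight_kg = 85,
                      systolic = NA_real_, diastolic = NA_real_)
  vit_w[patient_id == 16, day := B - 130L] # outside the 3-month window
  vit_bp <- data.table(patient_id = ids, day = B, weight_kg = NA_real_,
                       systolic = 142, diastolic = 88)
  vit_bp <- vit_bp[patient_id != 19] # no BP on record
  vitals <- rbind(vit_w, vit_bp)
  setorder(vitals, patient_id, day)

  conds <- data.table(
    patient_id = c(6L, 7L, 8L, 9L, 20L, 21L),
    category = c("cancer", "pregnancy", "bariatric_surgery", "heart_failure",
                 "cancer", "bariatric_surgery"),
    day = c(B - 100L, B - 200L, B - 730L, B - 50L, B - 400L, B - 1200L))

  intended <- data.table(patient_id = ids, eligible = TRUE, reason = NA_character_)
  set_reason <- function(id, label) {
    intended[patient_id %in% id, `:=`(eligible = FALSE, reason = label)]
  }
  set_reason(c(4L, 5L), "age")
  set_reason(13L, "prior antihypertensive use")
  set_reason(14L, "polytherapy at initiation")
  set_reason(15L, "no encounter >=6 months prior")
  set_reason(6L, "cancer")
  set_reason(7L, "pregnancy")
  set_reason(8L, "bariatric surgery")
  set_reason(9L, "heart failure")
  set_reason(c(10L, 11L, 12L), "weight-affecting medication")
  set_reason(16L, "no baseline weight")
  set_reason(c(17L, 18L), "missing sex or race/ethnicity")
  set_reason(19L, "no baseline blood pressure")

  structure(list(demographics = demo, encounters = enc, prescriptions = rx,
                 vitals = vitals, conditions = conds,
                 death = data.table(patient_id = integer(), death_day = numeric()),
                 truth = NULL, config = NULL, intended = intended[]),
            class = "ehr_bundle")
}
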