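# EHR bundle schema

A bundle directory holds five delimited tables (CSV, header row) plus an
optional death table and ground-truth JSON. All dates are integer day
offsets from the epoch (day 0 = 2010-01-01); blank cells are missing
values. `write_bundle()` / `read_bundle()` produce and consume this layout.

## demographics.csv — one row per patient
| column | type | notes |
|---|---|---|
| patient_id | integer | primary key |
| sex | character | "F"/"M"; blank = missing |
| race | character | "White"/"Black"/"Asian"/"Other"; blank = missing |
| ethnicity | character | "Hispanic"/"NonHispanic"; blank = missing |
| site | character | health-system identifier |
| birth_day | integer | day offset (negative = before epoch) |
| height_cm | numeric | used for BMI |
| medicaid | integer | 0/1 |
| smoking | character | "never"/"former"/"current" |

## encounters.csv — one row per healthcare visit
| column | type |
|---|---|
| patient_id | integer |
| day | integer |

## prescriptions.csv — one row per fill
| column | type | notes |
|---|---|---|
| patient_id | integer | |
| drug | character | study drugs (`lisinopril`, `amlodipine`, `atenolol`, `hydrochlorothiazide`, `losartan`, `metoprolol`, `propranolol`) or the pre-coded categories `anti_obesity`, `steroid`, `stimulant`, `other_antihypertensive` |
| fill_day | integer | |
| days_supply | numeric | blank = missing |
| quantity | numeric | units dispensed; blank = missing |
| refills | numeric | additional fills authorized; blank = missing |

## vitals.csv — one row per measurement
| column | type | notes |
|---|---|---|
| patient_id | integer | |
| day | integer | |
| weight_kg | numeric | blank on BP-only rows |
| systolic | numeric | mmHg; blank on weight-only rows |
| diastolic | numeric | mmHg |

## conditions.csv — one row per coded condition event
| column | type | notes |
|---|---|---|
| patient_id | integer | |
| category | character | `cancer`, `pregnancy`, `bariatric_surgery`, `heart_failure`, `hypertension` |
| day | integer | event date |

## death.csv — optional, one row per death
| column | type |
|---|---|
| patient_id | integer |
| death_day | integer |

## ground_truth.json — generator output only
Arms, reference arm, months 0..24, P(obesity), and a long table of the
true mean weight change (kg), contrast vs the reference (kg), and
probability of >= 5% gain per arm and month.
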