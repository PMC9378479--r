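tool <- default_trigger_tool()

test_that("eligibility applies the age and polypharmacy thresholds", {
  ten_drugs <- data.frame(
    drug_name = paste0("drug", 1:10),
    atc_code = c("C03CA01", "C09AA02", "C10AA01", "A10BA02", "A02BC01",
                 "N02BE01", "H03AA01", "M04AA01", "B03BB01", "A06AD11")
  )
  ok <- check_eligibility(one_patient_cohort(age = 84, drugs = ten_drugs))
  expect_true(ok$eligible)
  expect_identical(ok$polypharmacy_count, 10L)
  expect_length(ok$reasons[[1]], 0)

  young <- check_eligibility(one_patient_cohort(age = 69, drugs = ten_drugs))
  expect_false(young$age_ok)
  expect_false(young$eligible)

  # a dermatological preparation does not count towards polypharmacy
  five_one_derm <- data.frame(
    drug_name = c("a", "b", "c", "d", "hydrocortisone cream"),
    atc_code = c("C03CA01", "C09AA02", "C10AA01", "A10BA02", "D07AA02")
  )
  derm <- check_eligibility(one_patient_cohort(age = 75, drugs = five_one_derm))
  expect_identical(derm$polypharmacy_count, 4L)
  expect_false(derm$eligible)

  # nor does an as-needed (non-chronic) drug
  five_one_prn <- data.frame(
    drug_name = c("a", "b", "c", "d", "e"),
    atc_code = c("C03CA01", "C09AA02", "C10AA01", "A10BA02", "N02BE01"),
    chronic = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  prn <- check_eligibility(one_patient_cohort(age = 75, drugs = five_one_prn))
  expect_identical(prn$polypharmacy_count, 4L)

  expect_error(one_patient_cohort(age = -1), class = "adrtrigger_input_error")
})

test_that("event labels map to triggers through merged synonym lists", {
  expect_identical(map_event_to_triggers("syncope", tool), "fall")
  expect_identical(map_event_to_triggers("Fall", tool), "fall")
  expect_identical(map_event_to_triggers("dehydration", tool),
                   "renal_insufficiency_dehydration")
  expect_identical(map_event_to_triggers("pneumonia", tool), character())
})

test_that("same-class drugs merge into one combination, distinct classes split", {
  one <- detect_combinations(constipation_cohort(), tool)
  expect_identical(nrow(one), 1L)
  expect_identical(one$trigger_id, "constipation_ileus")
  expect_identical(one$class_id, "opioids")
  expect_identical(one$contributing_drugs[[1]], c("morphine", "oxycodone"))

  two <- detect_combinations(hyponatraemia_cohort(), tool)
  expect_identical(nrow(two), 2L)
  expect_setequal(two$class_id, c("thiazide_diuretics", "loop_diuretics"))
  expect_true(all(two$trigger_id == "hyponatraemia"))

  none <- detect_combinations(
    one_patient_cohort(drugs = data.frame(drug_name = "furosemide",
                                          atc_code = "C03CA01")),
    tool
  )
  expect_identical(nrow(none), 0L)
})

test_that("a fall with a calcium antagonist and a benzodiazepine yields two combinations", {
  cohort <- one_patient_cohort(
    drugs = data.frame(
      drug_name = c("amlodipine", "temazepam"),
      atc_code = c("C08CA01", "N05CD07")
    ),
    events = "fall"
  )
  combos <- detect_combinations(cohort, tool)
  expect_identical(nrow(combos), 2L)
  expect_setequal(combos$class_id, c("calcium_antagonists", "benzodiazepines"))
})

test_that("detection is insensitive to medication order and idempotent", {
  base <- hyponatraemia_cohort()
  shuffled <- base
  shuffled$medications <- shuffled$medications[2:1, ]
  a <- detect_combinations(base, tool)
  b <- detect_combinations(shuffled, tool)
  expect_identical(a, b)
  expect_identical(detect_combinations(base, tool), a)
})

test_that("adding a drug of an already-matched class does not add combinations", {
  base <- constipation_cohort()
  more <- one_patient_cohort(
    patient_id = "pA",
    drugs = data.frame(
      drug_name = c("oxycodone", "morphine", "fentanyl"),
      atc_code = c("N02AA05", "N02AA01", "N02AB03")
    ),
    events = "constipation"
  )
  a <- detect_combinations(base, tool)
  b <- detect_combinations(more, tool)
  expect_identical(nrow(b), nrow(a))
  expect_true(all(a$contributing_drugs[[1]] %in% b$contributing_drugs[[1]]))
  expect_gt(length(b$contributing_drugs[[1]]), length(a$contributing_drugs[[1]]))
})

test_that("every contributing drug re-resolves to its combination class", {
  sim <- generate_cohort(default_cohort_params(n_patients = 40), tool, seed = 11)
  combos <- suppressWarnings(detect_combinations(sim$cohort, tool))
  meds <- sim$cohort$medications
  for (i in seq_len(nrow(combos))) {
    for (d in combos$contributing_drugs[[i]]) {
      code <- meds$atc_code[meds$patient_id == combos$patient_id[i] &
                              meds$drug_name == d][1]
      expect_true(combos$class_id[i] %in% classify_drug(code, tool))
    }
  }
  # per-trigger combination count never exceeds the trigger's class count
  per <- dplyr::count(combos, patient_id, trigger_id)
  limits <- purrr::map_int(per$trigger_id,
                           ~ nrow(associated_classes(tool, .x)))
  expect_true(all(per$n <= limits))
})

test_that("screen_cohort summarises the per-patient burden", {
  both <- merge_cohorts(constipation_cohort("pA"), hyponatraemia_cohort("pB"))
  screen <- screen_cohort(both, tool, bypass_eligibility = TRUE)
  expect_identical(screen$summary$n_combinations, 3L)
  counts <- sort(screen$per_patient$n_combinations)
  expect_identical(counts, c(1L, 2L))
  expect_identical(screen$summary$frac_with_any, 1)

  # default mode screens only eligible admissions (these have < 5 drugs)
  strict <- screen_cohort(both, tool)
  expect_identical(strict$summary$n_screened, 0L)
  expect_identical(strict$summary$n_combinations, 0L)

  expect_error(
    merge_cohorts(constipation_cohort("dup"), constipation_cohort("dup")),
    class = "adrtrigger_input_error"
  )
})

test_that("discharge-letter events are ignored unless the source is widened", {
  cohort <- adr_cohort(
    patients = data.frame(patient_id = "p1", age = 80, sex = "male"),
    medications = data.frame(patient_id = "p1", drug_name = "furosemide",
                             atc_code = "C03CA01", chronic = TRUE),
    events = data.frame(patient_id = "p1", label = "hyponatraemia",
                        source = "discharge_letter", documented_as = "diagnosis")
  )
  expect_identical(nrow(detect_combinations(cohort, tool)), 0L)
  both <- detect_combinations(cohort, tool,
                              sources = c("admission_letter", "discharge_letter"))
  expect_identical(nrow(both), 1L)
})
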