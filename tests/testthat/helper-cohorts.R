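# Small cohorts built in code for unit tests.

one_patient_cohort <- function(patient_id = "p1", age = 84, sex = "female",
                               drugs = NULL, events = NULL,
                               changes = NULL, links = NULL) {
  adr_cohort(
    patients = data.frame(patient_id = patient_id, age = age, sex = sex),
    medications = if (is.null(drugs)) NULL else data.frame(
      patient_id = patient_id,
      drug_name = drugs$drug_name,
      atc_code = drugs$atc_code,
      chronic = drugs$chronic %||% TRUE
    ),
    events = if (is.null(events)) NULL else data.frame(
      patient_id = patient_id,
      label = events,
      source = "admission_letter",
      documented_as = "diagnosis"
    ),
    medication_changes = if (is.null(changes)) NULL else data.frame(
      patient_id = patient_id,
      drug_name = changes$drug_name,
      action = changes$action
    ),
    adr_links = if (is.null(links)) NULL else data.frame(
      patient_id = patient_id,
      event_label = links$event_label,
      drug_name = links$drug_name
    )
  )
}

`%||%` <- rlang::`%||%`

# patient with constipation on two opioids (one combination expected)
constipation_cohort <- function(id = "pA") {
  one_patient_cohort(
    patient_id = id,
    drugs = data.frame(
      drug_name = c("oxycodone", "morphine"),
      atc_code = c("N02AA05", "N02AA01")
    ),
    events = "constipation"
  )
}

# patient with hyponatraemia on a thiazide and a loop diuretic
# (two combinations expected: one per drug class)
hyponatraemia_cohort <- function(id = "pB") {
  one_patient_cohort(
    patient_id = id,
    drugs = data.frame(
      drug_name = c("hydrochlorothiazide", "furosemide"),
      atc_code = c("C03AA03", "C03CA01")
    ),
    events = "hyponatraemia"
  )
}

merge_cohorts <- function(...) {
  parts <- list(...)
  adr_cohort(
    patients = dplyr::bind_rows(lapply(parts, `[[`, "patients")),
    medications = dplyr::bind_rows(lapply(parts, `[[`, "medications")),
    events = dplyr::bind_rows(lapply(parts, `[[`, "events")),
    medication_changes = dplyr::bind_rows(lapply(parts, `[[`, "medication_changes")),
    adr_links = dplyr::bind_rows(lapply(parts, `[[`, "adr_links"))
  )
}

# n_each pairs per cell of a 2x2 confusion layout over two categories
pairs_from_counts <- function(aa, ab, ba, bb,
                              cat1 = "possible", cat2 = "unlikely") {
  tibble::tibble(
    category_a = c(rep(cat1, aa + ab), rep(cat2, ba + bb)),
    category_b = c(rep(cat1, aa), rep(cat2, ab), rep(cat1, ba), rep(cat2, bb))
  )
}
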