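#' Check guideline eligibility of each admission
#'
#' Applies the screening eligibility criteria of the geriatric polypharmacy
#' guideline: age at least `min_age` years and polypharmacy, defined as the
#' chronic use of at least `min_drugs` prescription drugs excluding
#' dermatological preparations at admission.
#'
#' @param cohort An [adr_cohort()].
#' @param min_age Minimum age in years (guideline default 70).
#' @param min_drugs Minimum number of chronic, non-dermatological drugs
#'   (guideline default 5).
#' @return Tibble with one row per patient: `patient_id`, `age`, `age_ok`,
#'   `polypharmacy_count`, `eligible` and a `reasons` list-column naming the
#'   failed criteria (empty when eligible).
#' @examples
#' cohort <- adr_cohort(
#'   patients = data.frame(patient_id = "p1", age = 84, sex = "female"),
#'   medications = data.frame(
#'     patient_id = "p1",
#'     drug_name = c("furosemide", "enalapril", "simvastatin", "metformin",
#'                   "omeprazole"),
#'     atc_code = c("C03CA01", "C09AA02", "C10AA01", "A10BA02", "A02BC01"),
#'     chronic = TRUE
#'   )
#' )
#' check_eligibility(cohort)
#' @export
check_eligibility <- function(cohort, min_age = 70, min_drugs = 5) {
  stopifnot(inherits(cohort, "adr_cohort"))
  counts <- cohort$medications |>
    dplyr::filter(.data$chronic, !.data$dermatological) |>
    dplyr::count(.data$patient_id, name = "polypharmacy_count")
  out <- cohort$patients |>
    dplyr::select("patient_id", "age") |>
    dplyr::left_join(counts, by = "patient_id") |>
    dplyr::mutate(
      polypharmacy_count = dplyr::coalesce(.data$polypharmacy_count, 0L),
      age_ok = .data$age >= min_age,
      eligible = .data$age_ok & .data$polypharmacy_count >= min_drugs,
      reasons = purrr::map2(.data$age_ok, .data$polypharmacy_count >= min_drugs, function(a, d) {
        c(if (!a) paste0("age below ", min_age),
          if (!d) paste0("fewer than ", min_drugs, " chronic non-dermatological drugs"))
      })
    )
  out
}

#' Map a documented event label to triggers
#'
#' Case-insensitive exact match of the normalised event label against each
#' trigger's synonym list; labels matching no synonym map to no trigger.
#'
#' @param label A clinical event label (character scalar).
#' @param tool A `trigger_tool`.
#' @return Character vector of matching `trigger_id`s (synonyms are unique
#'   across triggers, so at most one under a valid tool).
#' @examples
#' map_event_to_triggers("Syncope", default_trigger_tool())
#' map_event_to_triggers("pneumonia", default_trigger_tool())
#' @export
map_event_to_triggers <- function(label, tool) {
  stopifnot(length(label) == 1)
  syn <- synonym_table(tool)
  unique(syn$trigger_id[syn$synonym == normalise_label(label)])
}

#' Detect trigger-drug combinations
#'
#' For each documented clinical event that maps to a trigger of the tool,
#' and each drug class of that trigger with at least one medication in the
#' record resolving to it, emits exactly one combination aggregating all
#' such drugs. Multiple drugs of the same class linked to the same trigger
#' count as one combination (e.g. oxycodone and morphine with constipation),
#' while drugs of different classes count separately (e.g. a thiazide and a
#' loop diuretic with hyponatraemia): combinations are unique per
#' (patient, trigger, class).
#'
#' @param cohort An [adr_cohort()].
#' @param tool A `trigger_tool`.
#' @param sources Event sources considered; the default screens the
#'   admission letter only, mirroring screening on the day of admission.
#'   Use `c("admission_letter", "discharge_letter")` to widen.
#' @return Tibble ordered by tool catalogue order (trigger, then class),
#'   then patient order, with `combination_ref`, `patient_id`, `trigger_id`,
#'   `class_id`, `contributing_drugs` (list-column of drug names) and
#'   `matched_events` (list-column of the event labels that matched).
#'   A drug resolving to two classes of the same trigger contributes to
#'   both combinations, with a warning.
#' @examples
#' cohort <- adr_cohort(
#'   patients = data.frame(patient_id = "p1", age = 84, sex = "female"),
#'   medications = data.frame(
#'     patient_id = "p1",
#'     drug_name = c("oxycodone", "morphine"),
#'     atc_code = c("N02AA05", "N02AA01"),
#'     chronic = TRUE
#'   ),
#'   events = data.frame(patient_id = "p1", label = "constipation",
#'                       source = "admission_letter", documented_as = "symptom")
#' )
#' detect_combinations(cohort, default_trigger_tool())
#' @export
detect_combinations <- function(cohort, tool, sources = "admission_letter") {
  stopifnot(inherits(cohort, "adr_cohort"), inherits(tool, "trigger_tool"))
  sources <- match.arg(sources, EVENT_SOURCES, several.ok = TRUE)
  empty <- tibble::tibble(
    combination_ref = character(), patient_id = character(),
    trigger_id = character(), class_id = character(),
    contributing_drugs = list(), matched_events = list()
  )
  events <- cohort$events |>
    dplyr::filter(.data$source %in% sources) |>
    dplyr::mutate(synonym = normalise_label(.data$label))
  if (nrow(events) == 0 || nrow(cohort$medications) == 0) {
    return(empty)
  }
  syn <- synonym_table(tool)
  patient_triggers <- events |>
    dplyr::inner_join(syn, by = "synonym", relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id, .data$trigger_id) |>
    dplyr::summarise(matched_events = list(sort(unique(.data$label))), .groups = "drop")
  if (nrow(patient_triggers) == 0) {
    return(empty)
  }
  drug_classes <- classify_atc_codes(cohort$medications$atc_code, tool)
  patient_drug_classes <- cohort$medications |>
    dplyr::select("patient_id", "drug_name", "atc_code") |>
    dplyr::inner_join(drug_classes, by = "atc_code", relationship = "many-to-many")
  tc <- trigger_class_table(tool)
  combos <- patient_triggers |>
    dplyr::inner_join(tc, by = "trigger_id", relationship = "many-to-many") |>
    dplyr::inner_join(patient_drug_classes, by = c("patient_id", "class_id"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id, .data$trigger_id, .data$class_id) |>
    dplyr::summarise(
      contributing_drugs = list(sort(unique(.data$drug_name))),
      matched_events = .data$matched_events[1],
      .groups = "drop"
    )
  if (nrow(combos) == 0) {
    return(empty)
  }
  # one drug in >= 2 classes of the same trigger: transparent, but flagged
  multi <- combos |>
    dplyr::select("patient_id", "trigger_id", "contributing_drugs") |>
    tidyr::unnest_longer("contributing_drugs", values_to = "drug_name") |>
    dplyr::count(.data$patient_id, .data$trigger_id, .data$drug_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    warn(paste0(
      "drug(s) resolving to multiple classes of the same trigger ",
      "(contributing to each): ",
      paste(unique(multi$drug_name), collapse = ", ")
    ))
  }
  trigger_order <- tool$triggers$trigger_id
  class_order <- tool$classes$class_id
  patient_order <- cohort$patients$patient_id
  combos |>
    dplyr::arrange(
      match(.data$trigger_id, trigger_order),
      match(.data$class_id, class_order),
      match(.data$patient_id, patient_order)
    ) |>
    dplyr::mutate(
      combination_ref = paste(.data$patient_id, .data$trigger_id, .data$class_id, sep = "::")
    ) |>
    dplyr::select("combination_ref", "patient_id", "trigger_id", "class_id",
                  "contributing_drugs", "matched_events")
}

#' Screen a cohort for trigger-drug combinations
#'
#' Applies the eligibility filter (unless bypassed), detects combinations
#' for every screened admission and summarises the per-patient burden.
#'
#' @inheritParams detect_combinations
#' @inheritParams check_eligibility
#' @param bypass_eligibility If `TRUE`, screen every admission regardless of
#'   age and polypharmacy.
#' @return An `adr_screen` object (list) with `combinations` (as
#'   [detect_combinations()]), `per_patient` (tibble of `patient_id`,
#'   `n_combinations` over screened patients), `eligibility` (the
#'   [check_eligibility()] table) and `summary` (one-row tibble:
#'   `n_patients`, `n_screened`, `n_combinations`, median/IQR/max
#'   combinations per screened patient and the fraction with at least one).
#' @export
screen_cohort <- function(cohort, tool, min_age = 70, min_drugs = 5,
                          bypass_eligibility = FALSE,
                          sources = "admission_letter") {
  stopifnot(inherits(cohort, "adr_cohort"))
  eligibility <- check_eligibility(cohort, min_age = min_age, min_drugs = min_drugs)
  screened_ids <- if (bypass_eligibility) {
    eligibility$patient_id
  } else {
    eligibility$patient_id[eligibility$eligible]
  }
  sub <- subset_cohort(cohort, screened_ids)
  combinations <- detect_combinations(sub, tool, sources = sources)
  per_patient <- tibble::tibble(patient_id = screened_ids) |>
    dplyr::left_join(
      dplyr::count(combinations, .data$patient_id, name = "n_combinations"),
      by = "patient_id"
    ) |>
    dplyr::mutate(n_combinations = dplyr::coalesce(.data$n_combinations, 0L))
  n <- per_patient$n_combinations
  summary <- tibble::tibble(
    n_patients = nrow(cohort$patients),
    n_screened = length(screened_ids),
    n_combinations = sum(n),
    median_per_patient = if (length(n)) stats::median(n) else NA_real_,
    q25_per_patient = if (length(n)) unname(stats::quantile(n, 0.25)) else NA_real_,
    q75_per_patient = if (length(n)) unname(stats::quantile(n, 0.75)) else NA_real_,
    max_per_patient = if (length(n)) max(n) else NA_integer_,
    frac_with_any = if (length(n)) mean(n > 0) else NA_real_
  )
  structure(
    list(combinations = combinations, per_patient = per_patient,
         eligibility = eligibility, summary = summary),
    class = "adr_screen"
  )
}

#' @export
print.adr_screen <- function(x, ...) {
  s <- x$summary
  cat("<adr_screen> ", s$n_screened, "/", s$n_patients, " admissions screened\n", sep = "")
  cat("  combinations: ", s$n_combinations,
      " (median ", s$median_per_patient,
      ", IQR ", s$q25_per_patient, "-", s$q75_per_patient,
      ", max ", s$max_per_patient, " per patient)\n", sep = "")
  cat("  patients with >= 1 combination: ",
      round_half_up(100 * s$frac_with_any, 1), "%\n", sep = "")
  invisible(x)
}

# Restrict a cohort to the given patients (keeping patient order).
subset_cohort <- function(cohort, patient_ids) {
  keep <- function(tbl) tbl[tbl$patient_id %in% patient_ids, , drop = FALSE]
  structure(
    list(
      patients = keep(cohort$patients),
      medications = keep(cohort$medications),
      events = keep(cohort$events),
      medication_changes = keep(cohort$medication_changes),
      adr_links = keep(cohort$adr_links)
    ),
    class = "adr_cohort"
  )
}
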