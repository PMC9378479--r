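#' Classify recognition of combinations by usual care
#'
#' Applies the two-branch recognition rule to each detected combination.
#' Branch 1: the attending physician explicitly documented the trigger-drug
#' pair (an `adr_links` entry whose event maps to the combination's trigger
#' and whose drug is a contributing drug). Branch 2: the trigger's event is
#' documented and at least one contributing drug underwent a medication
#' change (withdrawal, discontinuation or dose adjustment). Otherwise the
#' combination is not recognised. Drug matching is by normalised drug name
#' (lowercased, trimmed), since changes are recorded per product.
#'
#' @param combinations Tibble from [detect_combinations()].
#' @param cohort The [adr_cohort()] the combinations were derived from.
#' @param tool The `trigger_tool` used for detection.
#' @return Tibble with `combination_ref`, `recognised`, `basis`
#'   (`"explicit_documentation"`, `"trigger_plus_medication_change"` or
#'   `"none"`) and a `changed_drugs` list-column (the contributing drugs
#'   that were changed; empty unless basis is the medication-change branch).
#'   An explicit link naming a drug absent from the patient's medication
#'   list is flagged with a warning as a data inconsistency (and ignored).
#' @export
assess_recognition <- function(combinations, cohort, tool) {
  stopifnot(inherits(cohort, "adr_cohort"), inherits(tool, "trigger_tool"))
  combinations <- tibble::as_tibble(combinations)
  unknown <- setdiff(combinations$patient_id, cohort$patients$patient_id)
  if (length(unknown)) {
    stop_input("combinations reference patients absent from the cohort: ",
               paste(unknown, collapse = ", "))
  }
  if (nrow(combinations) == 0) {
    return(tibble::tibble(combination_ref = character(), recognised = logical(),
                          basis = character(), changed_drugs = list()))
  }
  contrib <- combinations |>
    dplyr::select("combination_ref", "patient_id", "trigger_id", "contributing_drugs") |>
    tidyr::unnest_longer("contributing_drugs", values_to = "drug_name") |>
    dplyr::mutate(drug_norm = normalise_label(.data$drug_name))
  syn <- synonym_table(tool)
  meds_norm <- dplyr::mutate(cohort$medications,
                             drug_norm = normalise_label(.data$drug_name))
  links <- cohort$adr_links |>
    dplyr::mutate(
      synonym = normalise_label(.data$event_label),
      drug_norm = normalise_label(.data$drug_name)
    ) |>
    dplyr::inner_join(syn, by = "synonym", relationship = "many-to-many")
  orphan <- dplyr::anti_join(
    dplyr::mutate(cohort$adr_links, drug_norm = normalise_label(.data$drug_name)),
    meds_norm, by = c("patient_id", "drug_norm")
  )
  if (nrow(orphan)) {
    warn(paste0("explicit ADR link(s) name drugs absent from the medication list ",
                "(ignored as data inconsistency): ",
                paste(unique(orphan$drug_name), collapse = ", ")))
    links <- dplyr::semi_join(links, meds_norm, by = c("patient_id", "drug_norm"))
  }
  explicit_refs <- contrib |>
    dplyr::inner_join(links, by = c("patient_id", "trigger_id", "drug_norm"),
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$combination_ref) |>
    dplyr::pull("combination_ref")
  changes <- dplyr::mutate(cohort$medication_changes,
                           drug_norm = normalise_label(.data$drug_name))
  changed <- contrib |>
    dplyr::inner_join(dplyr::select(changes, "patient_id", "drug_norm"),
                      by = c("patient_id", "drug_norm"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$combination_ref) |>
    dplyr::summarise(changed_drugs = list(sort(unique(.data$drug_name))),
                     .groups = "drop")
  out <- combinations |>
    dplyr::select("combination_ref") |>
    dplyr::left_join(changed, by = "combination_ref") |>
    dplyr::mutate(
      explicit = .data$combination_ref %in% explicit_refs,
      basis = dplyr::case_when(
        explicit ~ "explicit_documentation",
        !purrr::map_lgl(.data$changed_drugs, is.null) ~ "trigger_plus_medication_change",
        TRUE ~ "none"
      ),
      recognised = .data$basis != "none",
      changed_drugs = purrr::map2(.data$changed_drugs, .data$basis, function(d, b) {
        if (b == "trigger_plus_medication_change") d else character()
      })
    ) |>
    dplyr::select("combination_ref", "recognised", "basis", "changed_drugs")
  out
}

#' Stratified recognition rates
#'
#' Recognised fractions overall and per trigger, computed over a restriction
#' set of consensus causality categories (never defaulting to include
#' unclassifiable combinations). An empty stratum reports `NA` rates, not
#' zero.
#'
#' @param recognition Tibble from [assess_recognition()].
#' @param consensus Tibble from [reach_consensus()]; every recognition row
#'   must have a matching consensus entry.
#' @param combinations Tibble from [detect_combinations()] (supplies each
#'   combination's trigger).
#' @param restrict Character vector of categories defining the denominator;
#'   default the ADR set (possible, probable, certain).
#' @return Tibble with one row per trigger plus an `"(overall)"` row:
#'   `trigger_id`, `n` (denominator), `n_recognised`, `rate`.
#' @export
recognition_summary <- function(recognition, consensus, combinations,
                                restrict = c("possible", "probable", "certain")) {
  check_categories(restrict)
  recognition <- tibble::as_tibble(recognition)
  missing <- setdiff(recognition$combination_ref, consensus$combination_ref)
  if (length(missing)) {
    stop_input("recognition rows without consensus entry: ",
               paste(head(missing, 5), collapse = ", "))
  }
  joined <- recognition |>
    dplyr::inner_join(dplyr::select(consensus, "combination_ref", "final_category"),
                      by = "combination_ref") |>
    dplyr::inner_join(dplyr::select(combinations, "combination_ref", "trigger_id"),
                      by = "combination_ref") |>
    dplyr::filter(.data$final_category %in% restrict)
  per_trigger <- joined |>
    dplyr::group_by(.data$trigger_id) |>
    dplyr::summarise(n = dplyr::n(), n_recognised = sum(.data$recognised), .groups = "drop")
  overall <- tibble::tibble(
    trigger_id = "(overall)",
    n = nrow(joined),
    n_recognised = sum(joined$recognised)
  )
  dplyr::bind_rows(per_trigger, overall) |>
    dplyr::mutate(rate = ifelse(.data$n > 0, .data$n_recognised / .data$n, NA_real_))
}

#' Recognition rates from aggregated reference counts
#'
#' Recovers per-trigger recognised counts from a table of ADR counts and
#' printed recognition percentages (counts are `round_half_up(n * pct /
#' 100)`), for both strata: all ADRs (possible + probable + certain) and
#' probable + certain only, with pooled overall rows.
#'
#' @param counts Tibble with `trigger_id`, `n_adr`, `recognised_pct`,
#'   `n_adr_pc`, `recognised_pct_pc` (see [reference_recognition_counts()]).
#' @return Tibble with `stratum` (`"all_adr"` / `"probable_certain"`),
#'   `trigger_id` (incl. `"(overall)"`), `n`, `n_recognised`, `rate`.
#' @export
recognition_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  one <- function(n, pct, stratum) {
    rec <- ifelse(n > 0 & !is.na(pct), round_half_up(n * pct / 100), 0)
    tbl <- tibble::tibble(
      stratum = stratum,
      trigger_id = counts$trigger_id,
      n = as.integer(n),
      n_recognised = as.integer(rec)
    )
    overall <- tibble::tibble(
      stratum = stratum, trigger_id = "(overall)",
      n = sum(tbl$n), n_recognised = sum(tbl$n_recognised)
    )
    dplyr::bind_rows(tbl, overall)
  }
  dplyr::bind_rows(
    one(counts$n_adr, counts$recognised_pct, "all_adr"),
    one(counts$n_adr_pc, counts$recognised_pct_pc, "probable_certain")
  ) |>
    dplyr::mutate(rate = ifelse(.data$n > 0, .data$n_recognised / .data$n, NA_real_))
}
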