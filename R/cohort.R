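EVENT_SOURCES <- c("admission_letter", "discharge_letter")
EVENT_DOCUMENTED_AS <- c("symptom", "diagnosis", "health_problem")
CHANGE_ACTIONS <- c("withdrawal", "discontinuation", "dose_adjustment")

#' Build a structured admission cohort
#'
#' Bundles the tables describing one admission per patient into a validated
#' `adr_cohort`: demographics, the medication list with ATC codes and
#' chronic/dermatological flags, documented clinical events, medication
#' changes, and explicit ADR-documentation statements by the attending
#' physician. All screening, recognition and simulation functions take this
#' object.
#'
#' @param patients Data frame with `patient_id`, `age` (years), `sex`
#'   (`"female"`/`"male"`) and optionally `admission_date` (ISO-8601).
#' @param medications Data frame with `patient_id`, `drug_name`, `atc_code`
#'   (may be `""` when unrecorded), `chronic` (logical; chronic use at
#'   admission) and optionally `dermatological` (logical; derived from a
#'   leading `"D"` in the ATC code when absent).
#' @param events Data frame with `patient_id`, `label` (normalised clinical
#'   event name), `source` (`"admission_letter"`/`"discharge_letter"`) and
#'   `documented_as` (`"symptom"`, `"diagnosis"` or `"health_problem"`).
#' @param medication_changes Data frame with `patient_id`, `drug_name` and
#'   `action` (`"withdrawal"`, `"discontinuation"` or `"dose_adjustment"`).
#'   Every changed drug must appear in the patient's medication list.
#' @param adr_links Data frame with `patient_id`, `event_label` and
#'   `drug_name`: trigger-drug pairs explicitly documented as ADRs.
#' @return An `adr_cohort`: a classed list of the five tibbles.
#' @seealso [read_cohort_jsonl()], [check_eligibility()], [detect_combinations()]
#' @export
adr_cohort <- function(patients,
                       medications = NULL,
                       events = NULL,
                       medication_changes = NULL,
                       adr_links = NULL) {
  empty <- function(...) tibble::tibble(...)
  patients <- tibble::as_tibble(patients)
  if (!"admission_date" %in% names(patients)) patients$admission_date <- NA_character_
  patients <- dplyr::mutate(
    patients,
    patient_id = as.character(.data$patient_id),
    age = as.integer(.data$age),
    sex = as.character(.data$sex),
    admission_date = as.character(.data$admission_date)
  )
  medications <- tibble::as_tibble(
    medications %||%
      empty(patient_id = character(), drug_name = character(),
            atc_code = character(), chronic = logical())
  )
  if (!"atc_code" %in% names(medications)) medications$atc_code <- ""
  if (!"chronic" %in% names(medications)) medications$chronic <- TRUE
  medications$atc_code[is.na(medications$atc_code)] <- ""
  if (!"dermatological" %in% names(medications)) {
    medications$dermatological <- startsWith(medications$atc_code, "D")
  }
  events <- tibble::as_tibble(
    events %||%
      empty(patient_id = character(), label = character(),
            source = character(), documented_as = character())
  )
  if (!"source" %in% names(events)) events$source <- "admission_letter"
  if (!"documented_as" %in% names(events)) events$documented_as <- "diagnosis"
  medication_changes <- tibble::as_tibble(
    medication_changes %||%
      empty(patient_id = character(), drug_name = character(), action = character())
  )
  adr_links <- tibble::as_tibble(
    adr_links %||%
      empty(patient_id = character(), event_label = character(), drug_name = character())
  )
  first <- function(tbl, cols) {
    dplyr::select(tbl, dplyr::all_of(intersect(cols, names(tbl))),
                  dplyr::everything())
  }
  cohort <- structure(
    list(
      patients = first(patients, c("patient_id", "age", "sex", "admission_date")),
      medications = first(medications, c("patient_id", "drug_name", "atc_code",
                                         "chronic", "dermatological")),
      events = first(events, c("patient_id", "label", "source", "documented_as")),
      medication_changes = first(medication_changes,
                                 c("patient_id", "drug_name", "action")),
      adr_links = first(adr_links, c("patient_id", "event_label", "drug_name"))
    ),
    class = "adr_cohort"
  )
  validate_cohort(cohort)
}

#' Validate an admission cohort
#'
#' @param cohort An `adr_cohort`.
#' @return `cohort` invisibly if valid, else an informative error: unique
#'   patient identifiers, non-negative ages, known sex/source/action levels,
#'   non-empty event labels, medication changes restricted to listed drugs,
#'   and dermatological flags consistent with a leading `"D"` ATC code.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "adr_cohort"))
  p <- cohort$patients
  if (anyDuplicated(p$patient_id)) {
    stop_input("duplicate patient_id in cohort: ",
               paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "))
  }
  if (any(is.na(p$age)) || any(p$age < 0)) {
    stop_input("patient age must be a non-negative integer")
  }
  if (!all(p$sex %in% c("female", "male"))) {
    stop_input("sex must be 'female' or 'male'")
  }
  m <- cohort$medications
  bad_derm <- startsWith(m$atc_code, "D") & !m$dermatological
  if (any(bad_derm)) {
    stop_input("medication(s) with a 'D' ATC code not flagged dermatological: ",
               paste(unique(m$drug_name[bad_derm]), collapse = ", "))
  }
  e <- cohort$events
  if (any(!nzchar(e$label))) stop_input("clinical events must have a non-empty label")
  if (!all(e$source %in% EVENT_SOURCES)) {
    stop_input("event source must be one of: ", paste(EVENT_SOURCES, collapse = ", "))
  }
  if (!all(e$documented_as %in% EVENT_DOCUMENTED_AS)) {
    stop_input("documented_as must be one of: ", paste(EVENT_DOCUMENTED_AS, collapse = ", "))
  }
  ch <- cohort$medication_changes
  if (!all(ch$action %in% CHANGE_ACTIONS)) {
    stop_input("medication change action must be one of: ",
               paste(CHANGE_ACTIONS, collapse = ", "))
  }
  if (nrow(ch)) {
    listed <- dplyr::semi_join(
      ch, m, by = c("patient_id", "drug_name")
    )
    if (nrow(listed) < nrow(ch)) {
      orphan <- dplyr::anti_join(ch, m, by = c("patient_id", "drug_name"))
      stop_input("medication change for drug(s) not on the medication list: ",
                 paste(unique(orphan$drug_name), collapse = ", "))
    }
  }
  extra <- setdiff(
    unique(c(m$patient_id, e$patient_id, ch$patient_id, cohort$adr_links$patient_id)),
    p$patient_id
  )
  if (length(extra)) {
    stop_input("records reference unknown patient_id(s): ", paste(extra, collapse = ", "))
  }
  invisible(cohort)
}

#' @export
print.adr_cohort <- function(x, ...) {
  cat("<adr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$medications), " medications, ",
      nrow(x$events), " events, ",
      nrow(x$medication_changes), " medication changes, ",
      nrow(x$adr_links), " explicit ADR links\n", sep = "")
  invisible(x)
}

patient_to_list <- function(cohort, id) {
  sub <- function(tbl) {
    out <- tbl[tbl$patient_id == id, setdiff(names(tbl), "patient_id"), drop = FALSE]
    purrr::transpose(as.list(out))
  }
  p <- cohort$patients[cohort$patients$patient_id == id, ]
  list(
    patient_id = id,
    age = p$age[[1]],
    sex = p$sex[[1]],
    admission_date = p$admission_date[[1]],
    medications = sub(cohort$medications),
    events = sub(cohort$events),
    medication_changes = sub(cohort$medication_changes),
    adr_links = sub(cohort$adr_links)
  )
}

#' Write / read a cohort as JSON lines
#'
#' One admission per line, UTF-8, ISO-8601 dates: the interchange format for
#' structured admission records. `read_cohort_jsonl()` can select the first
#' admission per patient (by `admission_date`) when a file carries repeat
#' admissions under the same `patient_id`.
#'
#' @param cohort An `adr_cohort`.
#' @param path File path.
#' @param first_admission If `TRUE`, keep only each patient's earliest
#'   admission (requires `admission_date`); if `FALSE` (default), repeat
#'   patient identifiers are an error.
#' @return `write_cohort_jsonl()` returns `path` invisibly;
#'   `read_cohort_jsonl()` returns an `adr_cohort`.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  stopifnot(inherits(cohort, "adr_cohort"))
  lines <- purrr::map_chr(cohort$patients$patient_id, function(id) {
    jsonlite::toJSON(patient_to_list(cohort, id), auto_unbox = TRUE, null = "null")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path, first_admission = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
  patients <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      patient_id = as.character(r$patient_id),
      age = as.integer(r$age),
      sex = as.character(r$sex),
      admission_date = as.character(r$admission_date %||% NA_character_)
    )
  })
  if (first_admission && anyDuplicated(patients$patient_id)) {
    keep <- patients |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::arrange(.data$patient_id, .data$admission_date, .data$.row) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
    recs <- recs[sort(keep$.row)]
    patients <- patients[sort(keep$.row), ]
  }
  part <- function(field) {
    purrr::map2_dfr(recs, patients$patient_id, function(r, id) {
      x <- r[[field]]
      if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
        return(NULL)
      }
      dplyr::mutate(tibble::as_tibble(x), patient_id = id)
    })
  }
  adr_cohort(
    patients = patients,
    medications = nullify_empty(part("medications")),
    events = nullify_empty(part("events")),
    medication_changes = nullify_empty(part("medication_changes")),
    adr_links = nullify_empty(part("adr_links"))
  )
}

nullify_empty <- function(tbl) {
  if (is.null(tbl) || nrow(tbl) == 0) NULL else tbl
}

#' Write / read a cohort as a flat CSV trio
#'
#' The same information as the JSON-lines format, split over
#' `patients.csv`, `medications.csv` and `events_changes.csv` (the latter
#' holding events, medication changes and explicit ADR links distinguished
#' by a `record_type` column).
#'
#' @param cohort An `adr_cohort`.
#' @param dir Directory holding (or receiving) the three CSV files.
#' @inheritParams write_cohort_jsonl
#' @return `write_cohort_csv()` returns `dir` invisibly; `read_cohort_csv()`
#'   an `adr_cohort`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "adr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(cohort$medications, file.path(dir, "medications.csv"), na = "")
  ec <- dplyr::bind_rows(
    dplyr::mutate(cohort$events, record_type = "event"),
    dplyr::mutate(cohort$medication_changes, record_type = "medication_change"),
    dplyr::mutate(cohort$adr_links, record_type = "adr_link")
  )
  readr::write_csv(ec, file.path(dir, "events_changes.csv"), na = "")
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir, first_admission = FALSE) {
  chr <- readr::cols(.default = readr::col_character())
  patients <- readr::read_csv(file.path(dir, "patients.csv"), col_types = chr)
  if (first_admission && anyDuplicated(patients$patient_id)) {
    patients <- patients |>
      dplyr::arrange(.data$patient_id, .data$admission_date) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  }
  medications <- readr::read_csv(file.path(dir, "medications.csv"), col_types = chr) |>
    dplyr::mutate(
      chronic = as.logical(.data$chronic),
      dermatological = as.logical(.data$dermatological)
    ) |>
    dplyr::semi_join(patients, by = "patient_id")
  ec <- readr::read_csv(file.path(dir, "events_changes.csv"), col_types = chr) |>
    dplyr::semi_join(patients, by = "patient_id")
  pick <- function(type, cols) {
    out <- ec[ec$record_type == type, intersect(cols, names(ec)), drop = FALSE]
    nullify_empty(out)
  }
  adr_cohort(
    patients = dplyr::mutate(patients, age = as.integer(.data$age)),
    medications = nullify_empty(medications),
    events = pick("event", c("patient_id", "label", "source", "documented_as")),
    medication_changes = pick("medication_change", c("patient_id", "drug_name", "action")),
    adr_links = pick("adr_link", c("patient_id", "event_label", "drug_name"))
  )
}
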