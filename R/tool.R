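#' Load a trigger-tool definition
#'
#' Reads a structured tool definition (YAML, or JSON — YAML is a superset)
#' describing the triggers of an ADR trigger tool and the ATC-coded drug
#' classes associated with each trigger, and validates it. The shipped
#' default encodes the explicated trigger tool of the Dutch geriatric
#' polypharmacy guideline: 16 triggers (the merged fall/collapse/hypotension/
#' dizziness/syncope event, delirium/confusion/drowsiness, three bleeding
#' subtypes, supratherapeutic INR, electrolyte and glucose disturbances,
#' renal insufficiency/dehydration, constipation/ileus, vomiting/diarrhoea,
#' acute heart failure and fracture), each paired with drug classes pinned
#' to ATC prefixes or explicit codes.
#'
#' @param path Path to a YAML (or JSON) tool definition. See the shipped
#'   `trigger_tool.yaml` under `system.file("extdata", package =
#'   "adrtrigger")` for the documented schema.
#' @return A `trigger_tool` object: a list with `name`, `version`,
#'   `triggers` (tibble: `trigger_id`, `label`, `event_synonyms` list-column,
#'   `class_ids` list-column) and `classes` (tibble: `class_id`, `label`,
#'   `atc_prefixes`, `include_codes`, `exclude_codes` list-columns).
#' @seealso [default_trigger_tool()], [classify_drug()], [associated_classes()]
#' @examples
#' tool <- default_trigger_tool()
#' nrow(tool$triggers)
#' classify_drug("C03CA01", tool)
#' @export
load_trigger_tool <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("name", "version", "drug_classes", "triggers")) {
    if (is.null(raw[[field]])) {
      stop_validation("tool definition is missing the '", field, "' field")
    }
  }
  chr0 <- function(x) as.character(x %||% character())
  classes <- purrr::map(raw$drug_classes, function(cl) {
    if (is.null(cl$class_id)) stop_validation("drug class without a class_id")
    tibble::tibble(
      class_id = as.character(cl$class_id),
      label = as.character(cl$label %||% cl$class_id),
      atc_prefixes = list(chr0(cl$atc_prefixes)),
      include_codes = list(chr0(cl$include_codes)),
      exclude_codes = list(chr0(cl$exclude_codes))
    )
  })
  classes <- dplyr::bind_rows(classes)
  triggers <- purrr::map(raw$triggers, function(tr) {
    if (is.null(tr$trigger_id)) stop_validation("trigger without a trigger_id")
    tibble::tibble(
      trigger_id = as.character(tr$trigger_id),
      label = as.character(tr$label %||% tr$trigger_id),
      event_synonyms = list(chr0(tr$event_synonyms)),
      class_ids = list(chr0(tr$drug_classes))
    )
  })
  triggers <- dplyr::bind_rows(triggers)
  tool <- structure(
    list(
      name = as.character(raw$name),
      version = as.character(raw$version),
      triggers = triggers,
      classes = classes
    ),
    class = "trigger_tool"
  )
  validate_trigger_tool(tool)
}

#' Validate a trigger tool
#'
#' Checks the structural invariants of a `trigger_tool`: unique trigger and
#' class identifiers, non-empty synonym and class lists, synonyms unique
#' across triggers, every referenced class present in the registry, every
#' class carrying at least one ATC prefix or include code, no code both
#' included and excluded, and all prefixes/codes matching the ATC pattern
#' (letter, two digits, then optionally letter, letter, two digits).
#'
#' @param tool A `trigger_tool`.
#' @return `tool`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending trigger or class.
#' @export
validate_trigger_tool <- function(tool) {
  stopifnot(inherits(tool, "trigger_tool"))
  cls <- tool$classes
  trg <- tool$triggers
  if (anyDuplicated(cls$class_id)) {
    stop_validation("duplicate class_id: ",
                    paste(unique(cls$class_id[duplicated(cls$class_id)]), collapse = ", "))
  }
  if (anyDuplicated(trg$trigger_id)) {
    stop_validation("duplicate trigger_id: ",
                    paste(unique(trg$trigger_id[duplicated(trg$trigger_id)]), collapse = ", "))
  }
  for (i in seq_len(nrow(cls))) {
    id <- cls$class_id[i]
    prefixes <- cls$atc_prefixes[[i]]
    inc <- cls$include_codes[[i]]
    exc <- cls$exclude_codes[[i]]
    if (length(prefixes) == 0 && length(inc) == 0) {
      stop_validation("drug class '", id, "' has neither atc_prefixes nor include_codes")
    }
    bad <- c(prefixes, inc, exc)[!is_valid_atc(c(prefixes, inc, exc))]
    if (length(bad)) {
      stop_validation("drug class '", id, "' has malformed ATC entries: ",
                      paste(bad, collapse = ", "))
    }
    both <- intersect(inc, exc)
    if (length(both)) {
      stop_validation("drug class '", id, "' lists codes in both include and exclude: ",
                      paste(both, collapse = ", "))
    }
  }
  for (i in seq_len(nrow(trg))) {
    id <- trg$trigger_id[i]
    if (length(trg$event_synonyms[[i]]) == 0) {
      stop_validation("trigger '", id, "' has no event synonyms")
    }
    if (length(trg$class_ids[[i]]) == 0) {
      stop_validation("trigger '", id, "' has no drug classes")
    }
    missing <- setdiff(trg$class_ids[[i]], cls$class_id)
    if (length(missing)) {
      stop_validation("trigger '", id, "' references unknown drug classes: ",
                      paste(missing, collapse = ", "))
    }
  }
  syn <- synonym_table(tool)
  dup <- syn$synonym[duplicated(syn$synonym)]
  if (length(dup)) {
    stop_conflict("event synonym(s) listed under more than one trigger: ",
                  paste(unique(dup), collapse = ", "))
  }
  invisible(tool)
}

#' The shipped default trigger tool
#'
#' @return The validated `trigger_tool` parsed from the shipped
#'   `trigger_tool.yaml` (cached after the first call).
#' @export
default_trigger_tool <- function() {
  if (is.null(the$default_tool)) {
    the$default_tool <- load_trigger_tool(extdata_path("trigger_tool.yaml"))
  }
  the$default_tool
}

#' @export
print.trigger_tool <- function(x, ...) {
  cat("<trigger_tool> ", x$name, " v", x$version, "\n", sep = "")
  cat("  triggers:     ", nrow(x$triggers), "\n", sep = "")
  cat("  drug classes: ", nrow(x$classes), "\n", sep = "")
  invisible(x)
}

# Long table of normalised event synonyms: one row per (trigger_id, synonym).
synonym_table <- function(tool) {
  tool$triggers |>
    dplyr::select("trigger_id", "event_synonyms") |>
    tidyr::unnest_longer("event_synonyms", values_to = "synonym") |>
    dplyr::mutate(synonym = normalise_label(.data$synonym))
}

# Long table of (trigger_id, class_id) associations in catalogue order.
trigger_class_table <- function(tool) {
  tool$triggers |>
    dplyr::select("trigger_id", "class_ids") |>
    tidyr::unnest_longer("class_ids", values_to = "class_id")
}

#' Resolve an ATC code to drug classes
#'
#' A code belongs to a class when it is listed in the class's
#' `include_codes`, or when any of the class's `atc_prefixes` equals the
#' code's leading characters; codes in `exclude_codes` are removed again.
#' Matching is strictly textual and independent of registry order. A drug
#' may resolve to more than one class (for instance, morphine is an opioid
#' and also carries sedative properties relevant to the delirium trigger).
#'
#' @param atc_code A single ATC code (e.g. `"C03CA01"` for furosemide), or
#'   `""`/`NA` when no code is recorded (resolves to no class).
#' @param tool A `trigger_tool`.
#' @return Character vector of matching `class_id`s (sorted; possibly empty).
#' @examples
#' tool <- default_trigger_tool()
#' classify_drug("C03CA01", tool) # loop diuretic
#' classify_drug("", tool)        # nothing to match
#' @export
classify_drug <- function(atc_code, tool) {
  stopifnot(length(atc_code) == 1)
  if (is.na(atc_code) || !nzchar(atc_code)) {
    return(character())
  }
  if (!is_valid_atc(atc_code)) {
    stop_input("malformed ATC code: '", atc_code, "'")
  }
  res <- classify_atc_codes(atc_code, tool)
  sort(res$class_id)
}

# Vectorised classifier over distinct codes: tibble(atc_code, class_id).
# Empty/NA codes yield no rows; malformed codes error.
classify_atc_codes <- function(codes, tool) {
  codes <- unique(codes[!is.na(codes) & nzchar(codes)])
  if (length(codes) == 0) {
    return(tibble::tibble(atc_code = character(), class_id = character()))
  }
  bad <- codes[!is_valid_atc(codes)]
  if (length(bad)) {
    stop_input("malformed ATC code(s): ", paste(bad, collapse = ", "))
  }
  cls <- tool$classes
  hits <- purrr::map(seq_len(nrow(cls)), function(i) {
    prefixes <- cls$atc_prefixes[[i]]
    matched <- codes %in% cls$include_codes[[i]]
    for (p in prefixes) {
      matched <- matched | startsWith(codes, p)
    }
    matched <- matched & !(codes %in% cls$exclude_codes[[i]])
    if (!any(matched)) return(NULL)
    tibble::tibble(atc_code = codes[matched], class_id = cls$class_id[i])
  })
  dplyr::bind_rows(
    tibble::tibble(atc_code = character(), class_id = character()),
    hits
  )
}

#' Drug classes associated with a trigger
#'
#' @param tool A `trigger_tool`.
#' @param trigger_id A trigger identifier present in the tool.
#' @return Tibble of the trigger's drug-class specifications in catalogue
#'   order (columns as in `tool$classes`).
#' @examples
#' associated_classes(default_trigger_tool(), "supratherapeutic_inr")$class_id
#' @export
associated_classes <- function(tool, trigger_id) {
  stopifnot(inherits(tool, "trigger_tool"), length(trigger_id) == 1)
  i <- match(trigger_id, tool$triggers$trigger_id)
  if (is.na(i)) {
    stop_lookup("unknown trigger_id: '", trigger_id, "'")
  }
  ids <- tool$triggers$class_ids[[i]]
  tool$classes[match(ids, tool$classes$class_id), ]
}

#' Shipped example drugs
#'
#' A small catalogue of common generic drugs with their ATC codes, used in
#' examples, tests and by the synthetic-cohort generator. Every drug class
#' of the default tool is represented by at least one drug; the catalogue
#' also carries tool-neutral drugs (statins, proton-pump inhibitors, ...)
#' and one dermatological preparation.
#'
#' @return Tibble with `drug_name` and `atc_code`.
#' @export
example_drugs <- function() {
  if (is.null(the$example_drugs)) {
    the$example_drugs <- readr::read_csv(
      extdata_path("example_drugs.csv"),
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  the$example_drugs
}

#' Reporting-level drug-class grouping
#'
#' Maps the fine-grained `class_id`s of the default tool to the ATC
#' level-2/3 style reporting labels used in published evaluations
#' (e.g. thiazide, loop and potassium-sparing diuretics all report as
#' "Diuretics"). Editable: pass your own mapping to [drug_attribution()].
#'
#' @return Tibble with `class_id` and `drug_group`.
#' @export
reporting_groups <- function() {
  if (is.null(the$reporting_groups)) {
    the$reporting_groups <- readr::read_csv(
      extdata_path("reporting_groups.csv"),
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  the$reporting_groups
}
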