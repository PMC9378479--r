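#' Reference evaluation counts for the default tool
#'
#' Transcriptions of the published evaluation of the explicated geriatric
#' ADR trigger tool, shipped as plain-text fixtures for regression testing
#' and as defaults for the synthetic-cohort generator:
#' `reference_trigger_counts()` gives per-trigger combination counts,
#' causality-category counts and contributing-drug summaries (941
#' combinations over 345 admissions); `reference_recognition_counts()` the
#' per-trigger ADR counts with recognition percentages in both causality
#' strata; `reference_attribution_counts()` the per-trigger reporting-level
#' drug-class counts among ADRs.
#'
#' @return A tibble (see the shipped TSVs under
#'   `system.file("extdata", package = "adrtrigger")` for columns).
#' @export
reference_trigger_counts <- function() {
  readr::read_tsv(
    extdata_path("reference_trigger_counts.tsv"),
    col_types = readr::cols(
      trigger_id = readr::col_character(),
      mean_drugs = readr::col_double(),
      .default = readr::col_integer()
    )
  )
}

#' @rdname reference_trigger_counts
#' @export
reference_recognition_counts <- function() {
  readr::read_tsv(
    extdata_path("reference_recognition.tsv"),
    col_types = readr::cols(
      trigger_id = readr::col_character(),
      n_adr = readr::col_integer(),
      n_adr_pc = readr::col_integer(),
      .default = readr::col_double()
    )
  )
}

#' @rdname reference_trigger_counts
#' @export
reference_attribution_counts <- function() {
  readr::read_tsv(
    extdata_path("reference_attribution.tsv"),
    col_types = readr::cols(
      trigger_id = readr::col_character(),
      drug_group = readr::col_character(),
      n_adr = readr::col_integer(),
      n_pc = readr::col_integer()
    )
  )
}

#' Performance report from per-trigger causality counts
#'
#' Core of the evaluation: from a per-trigger table of combination counts
#' and causality-category counts, computes each trigger's share of the
#' total, ADR count (possible + probable + certain) and positive predictive
#' value (PPV = ADRs / detected combinations per trigger, undefined at zero
#' combinations), plus a totals row. Excluded triggers are removed before
#' totals are formed, which is how the sensitivity analysis dropping
#' low-PPV triggers is computed.
#'
#' @param counts Tibble with `trigger_id`, `n_combinations` and the five
#'   category columns `unclassifiable`, `unlikely`, `possible`, `probable`,
#'   `certain`; optional `mean_drugs`, `min_drugs`, `max_drugs`.
#' @param exclude_triggers Optional character vector of `trigger_id`s to
#'   drop before computing totals.
#' @return An `adr_performance` object: list with `rows` (per-trigger
#'   tibble, catalogue order, including zero-count triggers), `totals`
#'   (one-row tibble), `exclusions`, and slots `recognition` / `attribution`
#'   filled by [compute_performance()] when those inputs are present.
#'   Proportions are unrounded; use [render_performance()] for one-decimal
#'   display percentages. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' perf <- performance_from_counts(reference_trigger_counts())
#' glance(perf)
#' @export
performance_from_counts <- function(counts, exclude_triggers = NULL) {
  counts <- tibble::as_tibble(counts)
  need <- c("trigger_id", "n_combinations", whoumc_categories)
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop_input("counts table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_sum <- with(counts, n_combinations !=
                    unclassifiable + unlikely + possible + probable + certain)
  if (any(bad_sum)) {
    stop_validation("causality counts do not sum to n_combinations for: ",
                    paste(counts$trigger_id[bad_sum], collapse = ", "))
  }
  if (!is.null(exclude_triggers)) {
    unknown <- setdiff(exclude_triggers, counts$trigger_id)
    if (length(unknown)) {
      stop_lookup("exclude_triggers not in counts: ", paste(unknown, collapse = ", "))
    }
    counts <- counts[!counts$trigger_id %in% exclude_triggers, ]
  }
  for (col in c("mean_drugs", "min_drugs", "max_drugs")) {
    if (!col %in% names(counts)) counts[[col]] <- NA_real_
  }
  total_n <- sum(counts$n_combinations)
  rows <- counts |>
    dplyr::mutate(
      share_of_total = if (total_n > 0) .data$n_combinations / total_n else NA_real_,
      n_adr = .data$possible + .data$probable + .data$certain,
      ppv = ifelse(.data$n_combinations > 0,
                   .data$n_adr / .data$n_combinations, NA_real_)
    ) |>
    dplyr::select("trigger_id", "n_combinations", "share_of_total",
                  "mean_drugs", "min_drugs", "max_drugs",
                  dplyr::all_of(whoumc_categories), "n_adr", "ppv")
  weighted_mean_drugs <- if (total_n > 0) {
    ok <- !is.na(rows$mean_drugs) & rows$n_combinations > 0
    sum(rows$mean_drugs[ok] * rows$n_combinations[ok]) / sum(rows$n_combinations[ok])
  } else {
    NA_real_
  }
  totals <- tibble::tibble(
    trigger_id = "(total)",
    n_combinations = total_n,
    share_of_total = if (total_n > 0) 1 else NA_real_,
    mean_drugs = weighted_mean_drugs,
    min_drugs = if (all(is.na(rows$min_drugs))) NA_real_ else min(rows$min_drugs, na.rm = TRUE),
    max_drugs = if (all(is.na(rows$max_drugs))) NA_real_ else max(rows$max_drugs, na.rm = TRUE),
    unclassifiable = sum(rows$unclassifiable),
    unlikely = sum(rows$unlikely),
    possible = sum(rows$possible),
    probable = sum(rows$probable),
    certain = sum(rows$certain),
    n_adr = sum(rows$n_adr),
    ppv = if (total_n > 0) sum(rows$n_adr) / total_n else NA_real_
  )
  structure(
    list(rows = rows, totals = totals,
         exclusions = exclude_triggers %||% character(),
         recognition = NULL, attribution = NULL),
    class = "adr_performance"
  )
}

#' Evaluate screened, adjudicated combinations
#'
#' Produces the full performance report from combination-level pipeline
#' output: per-trigger and overall PPV, causality distribution,
#' contributing-drug summaries, and (when recognition results are supplied)
#' stratified recognition rates and drug-class attribution.
#'
#' The mean number of associated drugs per trigger is the mean, over
#' trigger events, of contributing-drug counts aggregated per
#' (patient, trigger) across that trigger's drug classes.
#'
#' @param combinations Tibble from [detect_combinations()].
#' @param consensus Tibble from [reach_consensus()]; every combination must
#'   have a consensus entry.
#' @param tool The `trigger_tool` (fixes row order; zero-count triggers are
#'   reported).
#' @param recognition Optional tibble from [assess_recognition()]; adds the
#'   stratified recognition table.
#' @param exclude_triggers Optional triggers to drop (totals recomputed
#'   over the remaining rows).
#' @param groups Reporting-level class grouping for attribution (default
#'   [reporting_groups()]).
#' @return An `adr_performance` (see [performance_from_counts()]) with
#'   `recognition` and `attribution` filled when available.
#' @export
compute_performance <- function(combinations, consensus, tool,
                                recognition = NULL, exclude_triggers = NULL,
                                groups = reporting_groups()) {
  stopifnot(inherits(tool, "trigger_tool"))
  combinations <- tibble::as_tibble(combinations)
  consensus <- tibble::as_tibble(consensus)
  orphan <- setdiff(combinations$combination_ref, consensus$combination_ref)
  if (length(orphan)) {
    stop_input("combination(s) without a consensus entry: ",
               paste(head(orphan, 5), collapse = ", "))
  }
  joined <- combinations |>
    dplyr::inner_join(dplyr::select(consensus, "combination_ref", "final_category"),
                      by = "combination_ref") |>
    dplyr::mutate(n_drugs = purrr::map_int(.data$contributing_drugs, length))
  cat_counts <- joined |>
    dplyr::count(.data$trigger_id, .data$final_category) |>
    tidyr::pivot_wider(names_from = "final_category", values_from = "n", values_fill = 0L)
  per_event_drugs <- joined |>
    dplyr::group_by(.data$patient_id, .data$trigger_id) |>
    dplyr::summarise(n_drugs = sum(.data$n_drugs), .groups = "drop") |>
    dplyr::group_by(.data$trigger_id) |>
    dplyr::summarise(
      mean_drugs = mean(.data$n_drugs),
      min_drugs = min(.data$n_drugs),
      max_drugs = max(.data$n_drugs),
      .groups = "drop"
    )
  counts <- tibble::tibble(trigger_id = tool$triggers$trigger_id) |>
    dplyr::left_join(cat_counts, by = "trigger_id") |>
    dplyr::left_join(per_event_drugs, by = "trigger_id")
  for (cat in whoumc_categories) {
    if (!cat %in% names(counts)) counts[[cat]] <- 0L
    counts[[cat]] <- dplyr::coalesce(counts[[cat]], 0L)
  }
  counts$n_combinations <- counts$unclassifiable + counts$unlikely +
    counts$possible + counts$probable + counts$certain
  perf <- performance_from_counts(counts, exclude_triggers = exclude_triggers)
  kept <- function(tbl) {
    dplyr::filter(tbl, !.data$trigger_id %in% (exclude_triggers %||% character()))
  }
  joined <- kept(joined)
  if (!is.null(recognition)) {
    perf$recognition <- dplyr::bind_rows(
      dplyr::mutate(
        recognition_summary(recognition, consensus, kept(combinations),
                            restrict = c("possible", "probable", "certain")),
        stratum = "all_adr"
      ),
      dplyr::mutate(
        recognition_summary(recognition, consensus, kept(combinations),
                            restrict = c("probable", "certain")),
        stratum = "probable_certain"
      )
    ) |>
      dplyr::select("stratum", dplyr::everything())
  }
  perf$attribution <- drug_attribution(joined, consensus, groups = groups)
  perf
}

#' Causality-category distribution
#'
#' Counts and proportions of the five WHO-UMC categories over all
#' adjudicated combinations (unclassifiable included).
#'
#' @param x A consensus tibble (with `final_category`), a character vector
#'   of categories, or an `adr_performance` (uses its totals row).
#' @return Tibble with `category`, `n`, `proportion` (summing to one).
#' @export
causality_distribution <- function(x) {
  UseMethod("causality_distribution")
}

#' @export
causality_distribution.adr_performance <- function(x) {
  n <- purrr::map_int(whoumc_categories, ~ as.integer(x$totals[[.x]]))
  distribution_table(whoumc_categories, n)
}

#' @export
causality_distribution.character <- function(x) {
  if (length(x) == 0) stop_input("empty causality list")
  check_categories(x)
  tab <- table(factor(x, levels = whoumc_categories))
  distribution_table(whoumc_categories, as.integer(tab))
}

#' @export
causality_distribution.default <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"final_category" %in% names(x)) {
    stop_input("expected a 'final_category' column")
  }
  causality_distribution(x$final_category)
}

distribution_table <- function(category, n) {
  total <- sum(n)
  if (total == 0) stop_input("empty causality list")
  tibble::tibble(category = category, n = n, proportion = n / total)
}

#' Drug-class attribution of ADRs
#'
#' Counts the drug classes attributed to combinations in a causality
#' restriction set, each combination contributing its class once, grouped
#' to reporting-level labels (ATC level-2/3 style).
#'
#' @param combinations Tibble from [detect_combinations()], or any tibble
#'   with `combination_ref`, `trigger_id`, `class_id`.
#' @param consensus Tibble from [reach_consensus()].
#' @param restrict Categories defining attribution (default the ADR set).
#' @param groups Tibble mapping `class_id` to `drug_group` (default
#'   [reporting_groups()]; unmapped classes report as `"Other"`).
#' @return Tibble with `trigger_id`, `drug_group`, `n` per trigger.
#'   Summarise across triggers with [attribution_overall()].
#' @export
drug_attribution <- function(combinations, consensus,
                             restrict = c("possible", "probable", "certain"),
                             groups = reporting_groups()) {
  check_categories(restrict)
  combinations <- tibble::as_tibble(combinations)
  joined <- if ("final_category" %in% names(combinations)) {
    combinations
  } else {
    dplyr::inner_join(
      combinations,
      dplyr::select(consensus, "combination_ref", "final_category"),
      by = "combination_ref"
    )
  }
  joined |>
    dplyr::filter(.data$final_category %in% restrict) |>
    dplyr::left_join(groups, by = "class_id") |>
    dplyr::mutate(drug_group = dplyr::coalesce(.data$drug_group, "Other")) |>
    dplyr::count(.data$trigger_id, .data$drug_group, name = "n")
}

#' Overall drug-class ranking
#'
#' @param attribution Tibble with `drug_group` and a count column `n`.
#' @param n_col Name of the count column (allows the reference fixture's
#'   `n_adr` / `n_pc` columns).
#' @return Tibble `drug_group`, `n`, `share`, sorted by descending count.
#' @export
attribution_overall <- function(attribution, n_col = "n") {
  attribution <- tibble::as_tibble(attribution)
  attribution |>
    dplyr::group_by(.data$drug_group) |>
    dplyr::summarise(n = sum(.data[[n_col]]), .groups = "drop") |>
    dplyr::filter(.data$n > 0) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Render, write and re-read performance reports
#'
#' `render_performance()` returns display tables with percentages rounded
#' half away from zero to one decimal alongside the raw fractions.
#' `write_performance_report()` writes `performance.tsv`,
#' `recognition.tsv`/`attribution.tsv` (when present) and a `report.json`
#' that `read_performance_report()` parses back into an equal
#' `adr_performance` object.
#'
#' @param report An `adr_performance`.
#' @param dir Output directory (created if needed).
#' @param path A `report.json` path.
#' @return `render_performance()`: a tibble including the totals row with
#'   `share_pct` and `ppv_pct` display columns; `write_performance_report()`
#'   returns `dir` invisibly; `read_performance_report()` an
#'   `adr_performance`.
#' @export
render_performance <- function(report) {
  stopifnot(inherits(report, "adr_performance"))
  dplyr::bind_rows(report$rows, report$totals) |>
    dplyr::mutate(
      share_pct = round_half_up(100 * .data$share_of_total, 1),
      ppv_pct = round_half_up(100 * .data$ppv, 1)
    )
}

#' @rdname render_performance
#' @export
write_performance_report <- function(report, dir) {
  stopifnot(inherits(report, "adr_performance"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(render_performance(report), file.path(dir, "performance.tsv"), na = "")
  if (!is.null(report$recognition)) {
    readr::write_tsv(report$recognition, file.path(dir, "recognition.tsv"), na = "")
  }
  if (!is.null(report$attribution)) {
    readr::write_tsv(report$attribution, file.path(dir, "attribution.tsv"), na = "")
  }
  payload <- list(
    rows = report$rows,
    totals = report$totals,
    exclusions = report$exclusions,
    recognition = report$recognition,
    attribution = report$attribution
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' @rdname render_performance
#' @export
read_performance_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(NULL)
    tibble::as_tibble(x)
  }
  rows <- tibble::as_tibble(payload$rows)
  totals <- tibble::as_tibble(payload$totals)
  structure(
    list(
      rows = rows,
      totals = totals,
      exclusions = as.character(payload$exclusions %||% character()),
      recognition = as_tbl(payload$recognition),
      attribution = as_tbl(payload$attribution)
    ),
    class = "adr_performance"
  )
}

#' @export
print.adr_performance <- function(x, ...) {
  t <- x$totals
  cat("<adr_performance> ", t$n_combinations, " combinations, ",
      t$n_adr, " ADRs, overall PPV ",
      round_half_up(100 * t$ppv, 1), "%\n", sep = "")
  if (length(x$exclusions)) {
    cat("  excluded triggers: ", paste(x$exclusions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname performance_from_counts
#' @param x,object An `adr_performance`.
#' @param ... Unused.
#' @method tidy adr_performance
#' @export
tidy.adr_performance <- function(x, ...) {
  x$rows
}

#' @rdname performance_from_counts
#' @method glance adr_performance
#' @export
glance.adr_performance <- function(x, ...) {
  tibble::tibble(
    n_triggers = nrow(x$rows),
    n_combinations = x$totals$n_combinations,
    n_adr = x$totals$n_adr,
    ppv = x$totals$ppv,
    n_excluded = length(x$exclusions)
  )
}

#' @rdname performance_from_counts
#' @method autoplot adr_performance
#' @export
autoplot.adr_performance <- function(object, ...) {
  df <- object$rows |>
    dplyr::filter(.data$n_combinations > 0) |>
    dplyr::mutate(trigger_id = stats::reorder(.data$trigger_id, .data$ppv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppv, y = .data$trigger_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$totals$ppv, linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(
      x = "positive predictive value",
      y = NULL,
      title = "PPV per trigger",
      subtitle = sprintf("overall PPV %.1f%% (dashed)", 100 * object$totals$ppv)
    )
}
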