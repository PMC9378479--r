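#' WHO-UMC causality categories
#'
#' The five categories of the WHO-UMC causality scheme, from strongest to
#' weakest causal support on the ordered scale, plus the unordered
#' `"unclassifiable"`.
#'
#' @format Character vector of length 5.
#' @export
whoumc_categories <- c("certain", "probable", "possible", "unlikely", "unclassifiable")

#' Is a causality category counted as an ADR?
#'
#' Trigger-drug combinations scored certain, probable or possible are
#' considered adverse drug reactions; unlikely and unclassifiable are not.
#'
#' @param category Character vector of WHO-UMC categories.
#' @return Logical vector.
#' @examples
#' is_adr(c("possible", "unlikely", "certain"))
#' @export
is_adr <- function(category) {
  check_categories(category)
  category %in% c("certain", "probable", "possible")
}

check_categories <- function(category) {
  bad <- setdiff(unique(category), whoumc_categories)
  if (length(bad)) {
    stop_input("unknown causality category: ", paste(bad, collapse = ", "))
  }
  invisible(category)
}

#' Build structured WHO-UMC evidence
#'
#' Vectorised constructor for the evidence fields feeding
#' [classify_whoumc()]. All fields carry explicit unknown states, so a row
#' is always complete.
#'
#' @param temporal_relationship `"plausible"`, `"improbable"` or `"unknown"`:
#'   time course between drug intake and the event.
#' @param alternative_explanation `"excluded"`, `"unlikely"`, `"plausible"`
#'   or `"unknown"`: could disease or other drugs explain the event?
#' @param dechallenge `"positive"`, `"negative"`, `"not_done"` or
#'   `"unknown"`: response to withdrawal.
#' @param rechallenge `"positive"`, `"negative"` or `"not_done"`: response
#'   to re-exposure.
#' @param pharmacologically_definitive Logical: is the event definitive
#'   pharmacologically or phenomenologically (e.g. a toxic plasma level)?
#' @param data_sufficient Logical: is there enough information to judge at
#'   all? `FALSE` forces `"unclassifiable"`.
#' @return Tibble of validated evidence rows.
#' @export
causality_evidence <- function(temporal_relationship = "unknown",
                               alternative_explanation = "unknown",
                               dechallenge = "unknown",
                               rechallenge = "not_done",
                               pharmacologically_definitive = FALSE,
                               data_sufficient = TRUE) {
  ev <- tibble::tibble(
    temporal_relationship = as.character(temporal_relationship),
    alternative_explanation = as.character(alternative_explanation),
    dechallenge = as.character(dechallenge),
    rechallenge = as.character(rechallenge),
    pharmacologically_definitive = as.logical(pharmacologically_definitive),
    data_sufficient = as.logical(data_sufficient)
  )
  levels <- list(
    temporal_relationship = c("plausible", "improbable", "unknown"),
    alternative_explanation = c("excluded", "unlikely", "plausible", "unknown"),
    dechallenge = c("positive", "negative", "not_done", "unknown"),
    rechallenge = c("positive", "negative", "not_done")
  )
  for (field in names(levels)) {
    bad <- setdiff(unique(ev[[field]]), levels[[field]])
    if (length(bad)) {
      stop_input("invalid ", field, " value: ", paste(bad, collapse = ", "))
    }
  }
  if (anyNA(ev$pharmacologically_definitive) || anyNA(ev$data_sufficient)) {
    stop_input("pharmacologically_definitive and data_sufficient must be TRUE/FALSE")
  }
  ev
}

#' The shipped WHO-UMC decision table
#'
#' Parses the editable decision table (`whoumc_decision_table.yaml` under
#' the package's `extdata`) that [classify_whoumc()] applies: an ordered
#' list of rules, each with `when` (all-of), optional `any_of` and optional
#' `unless` conditions over the evidence fields. Pass a path to use a
#' locally adapted table.
#'
#' @param path Path to a decision-table YAML; `NULL` for the shipped one.
#' @return List of rules, classed `whoumc_rules`.
#' @export
whoumc_rules <- function(path = NULL) {
  if (is.null(path) && !is.null(the$whoumc_rules)) {
    return(the$whoumc_rules)
  }
  raw <- yaml::read_yaml(path %||% extdata_path("whoumc_decision_table.yaml"))
  rules <- raw$rules
  if (is.null(rules)) stop_validation("decision table has no 'rules' field")
  cats <- purrr::map_chr(rules, "category")
  check_categories(cats)
  out <- structure(rules, class = "whoumc_rules")
  if (is.null(path)) the$whoumc_rules <- out
  out
}

rule_matches <- function(cond, row) {
  if (is.null(cond) || length(cond) == 0) return(TRUE)
  all(purrr::imap_lgl(cond, function(values, field) row[[field]] %in% values))
}

rule_any_of <- function(cond, row) {
  if (is.null(cond) || length(cond) == 0) return(TRUE)
  any(purrr::imap_lgl(cond, function(values, field) row[[field]] %in% values))
}

#' Score WHO-UMC causality from structured evidence
#'
#' Applies the shipped, documented decision table row by row: the first rule
#' (highest category) whose conditions all hold wins. Under the default
#' table: certain needs a plausible time course, alternatives excluded, a
#' positive dechallenge and either a positive rechallenge or a
#' pharmacologically definitive event; probable needs plausible time,
#' alternatives at most unlikely and positive dechallenge; possible needs
#' only a plausible time course (vetoed when a plausible alternative meets a
#' negative dechallenge); insufficient data is unclassifiable; everything
#' else is unlikely.
#'
#' @param evidence Tibble from [causality_evidence()] (one or more rows).
#' @param rules A `whoumc_rules` decision table (shipped default).
#' @return Character vector of categories, one per evidence row.
#' @examples
#' classify_whoumc(causality_evidence(
#'   temporal_relationship = "plausible",
#'   alternative_explanation = "excluded",
#'   dechallenge = "positive",
#'   rechallenge = "positive"
#' ))
#' @export
classify_whoumc <- function(evidence, rules = whoumc_rules()) {
  evidence <- causality_evidence(
    evidence$temporal_relationship, evidence$alternative_explanation,
    evidence$dechallenge, evidence$rechallenge,
    evidence$pharmacologically_definitive, evidence$data_sufficient
  )
  purrr::map_chr(seq_len(nrow(evidence)), function(i) {
    row <- as.list(evidence[i, ])
    for (rule in rules) {
      if (rule_matches(rule$when, row) &&
          rule_any_of(rule$any_of, row) &&
          !(length(rule$unless %||% list()) > 0 && rule_matches(rule$unless, row))) {
        return(rule$category)
      }
    }
    "unlikely"
  })
}

#' Adjudicate dual-rater assessments to a consensus
#'
#' Implements the consensus protocol of a dual-rater causality assessment:
#' equal categories stand immediately; any disagreement (one WHO-UMC
#' category or more, and unclassifiable versus any ordered category counts
#' as disagreement) must carry a discussed `resolution`; failing that, a
#' `third_expert` category decides; a disagreement with neither is an error.
#'
#' @param ratings Tibble with `combination_ref`, `category_a`, `category_b`
#'   and optionally `resolution` and `third_expert` columns (NA where not
#'   applicable). See [pair_assessments()] to build it from two per-rater
#'   tables.
#' @return Tibble `combination_ref`, `final_category`, `agreement_path`
#'   (`"immediate"`, `"discussed"` or `"third_expert"`), `category_a`,
#'   `category_b`.
#' @examples
#' reach_consensus(tibble::tibble(
#'   combination_ref = c("c1", "c2"),
#'   category_a = c("possible", "possible"),
#'   category_b = c("possible", "probable"),
#'   resolution = c(NA, "probable")
#' ))
#' @export
reach_consensus <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  for (col in c("combination_ref", "category_a", "category_b")) {
    if (!col %in% names(ratings)) stop_input("ratings must have a '", col, "' column")
  }
  if (!"resolution" %in% names(ratings)) ratings$resolution <- NA_character_
  if (!"third_expert" %in% names(ratings)) ratings$third_expert <- NA_character_
  check_categories(ratings$category_a)
  check_categories(ratings$category_b)
  check_categories(ratings$resolution[!is.na(ratings$resolution)])
  check_categories(ratings$third_expert[!is.na(ratings$third_expert)])
  if (anyDuplicated(ratings$combination_ref)) {
    stop_input("duplicate combination_ref in ratings")
  }
  agree <- ratings$category_a == ratings$category_b
  final <- ifelse(agree, ratings$category_a,
                  ifelse(!is.na(ratings$resolution), ratings$resolution,
                         ratings$third_expert))
  path <- ifelse(agree, "immediate",
                 ifelse(!is.na(ratings$resolution), "discussed", "third_expert"))
  unresolved <- !agree & is.na(ratings$resolution) & is.na(ratings$third_expert)
  if (any(unresolved)) {
    stop_input("disagreement without resolution or third expert for: ",
               paste(head(ratings$combination_ref[unresolved], 5), collapse = ", "))
  }
  tibble::tibble(
    combination_ref = ratings$combination_ref,
    final_category = final,
    agreement_path = path,
    category_a = ratings$category_a,
    category_b = ratings$category_b
  )
}

#' Pair two raters' assessment tables
#'
#' @param a,b Tibbles with `combination_ref` and `category` (and optionally
#'   `rater_id`), one row per combination each, covering the same
#'   combinations.
#' @return Tibble with `combination_ref`, `category_a`, `category_b`,
#'   suitable for [reach_consensus()] and [cohens_kappa()].
#' @export
pair_assessments <- function(a, b) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  if (anyDuplicated(a$combination_ref) || anyDuplicated(b$combination_ref)) {
    stop_input("each rater must assess each combination once")
  }
  if (!setequal(a$combination_ref, b$combination_ref)) {
    stop_input("raters assessed different combination sets")
  }
  dplyr::inner_join(
    dplyr::select(a, "combination_ref", category_a = "category"),
    dplyr::select(b, "combination_ref", category_b = "category"),
    by = "combination_ref"
  )
}

#' Cohen's kappa for dual-rater causality assessments
#'
#' Unweighted Cohen's kappa over the 5x5 WHO-UMC confusion matrix:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and
#' chance-expected agreement `pe` from the marginal category frequencies.
#' In the degenerate case `pe = 1` (both raters used one identical category
#' throughout), kappa is 1 when observed agreement is 1 and 0 otherwise,
#' with a warning.
#'
#' @param ratings Tibble with `category_a` and `category_b` columns (e.g.
#'   from [pair_assessments()]), or a character vector of rater A's
#'   categories if `b` is given.
#' @param b Optional character vector of rater B's categories.
#' @return A `kappa_result`: list with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `band` (see [kappa_band()]), `n_pairs`,
#'   `n_discordant` and the confusion `table`. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' k <- cohens_kappa(c("possible", "certain", "unlikely"),
#'                   c("possible", "probable", "unlikely"))
#' k$kappa
#' @export
cohens_kappa <- function(ratings, b = NULL) {
  if (!is.null(b)) {
    ratings <- tibble::tibble(category_a = ratings, category_b = b)
  }
  ratings <- tibble::as_tibble(ratings)
  if (nrow(ratings) == 0) stop_input("no rating pairs supplied")
  check_categories(ratings$category_a)
  check_categories(ratings$category_b)
  a <- factor(ratings$category_a, levels = whoumc_categories)
  bb <- factor(ratings$category_b, levels = whoumc_categories)
  tab <- table(a, bb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warn("degenerate kappa: both raters used a single identical category")
    kappa <- if (po == 1) 1 else 0
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(
    list(
      kappa = kappa,
      observed_agreement = po,
      expected_agreement = pe,
      band = kappa_band(kappa),
      n_pairs = n,
      n_discordant = as.integer(n - sum(diag(tab))),
      table = tab
    ),
    class = "kappa_result"
  )
}

#' Verbal agreement band for a kappa value
#'
#' Maps kappa to the conventional verbal bands: poor (< 0.00), slight
#' (0.00-0.20), fair (0.21-0.40), moderate (0.41-0.60), substantial
#' (0.61-0.80), almost perfect (0.81-1.00). Values falling between two
#' printed ranges belong to the band whose range starts below them.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @examples
#' kappa_band(c(0.76, 0.85, -0.05))
#' @export
kappa_band <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1) || any(kappa > 1)) {
    stop_input("kappa must lie in [-1, 1]")
  }
  bands <- c("slight", "fair", "moderate", "substantial", "almost_perfect")
  idx <- findInterval(kappa, c(0, 0.21, 0.41, 0.61, 0.81))
  ifelse(kappa < 0, "poor", bands[pmax(idx, 1L)])
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("<kappa_result> kappa = ", signif(x$kappa, 4),
      " (", x$band, "), observed agreement ", signif(x$observed_agreement, 4),
      ", ", x$n_discordant, "/", x$n_pairs, " discordant\n", sep = "")
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x A `kappa_result`.
#' @param ... Unused.
#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  as.data.frame(x$table) |>
    tibble::as_tibble() |>
    rlang::set_names(c("category_a", "category_b", "n")) |>
    dplyr::mutate(dplyr::across(1:2, as.character))
}

#' @rdname cohens_kappa
#' @method glance kappa_result
#' @export
glance.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa,
    observed_agreement = x$observed_agreement,
    expected_agreement = x$expected_agreement,
    band = x$band,
    n_pairs = x$n_pairs,
    n_discordant = x$n_discordant
  )
}

#' @rdname cohens_kappa
#' @param object A `kappa_result`.
#' @method autoplot kappa_result
#' @export
autoplot.kappa_result <- function(object, ...) {
  df <- tidy.kappa_result(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$category_a, levels = whoumc_categories),
    y = factor(.data$category_b, levels = rev(whoumc_categories)),
    fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(
      x = "rater A", y = "rater B",
      title = sprintf("Cohen's kappa = %.2f (%s)", object$kappa, object$band)
    ) +
    ggplot2::guides(fill = "none")
}
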