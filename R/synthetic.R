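#' Parameters for the synthetic-cohort generator
#'
#' Bundles and validates everything [generate_cohort()] needs: demographic
#' distributions, medication burden, per-trigger expected combination
#' counts, per-trigger causality mixtures and per-(trigger, category)
#' recognition probabilities. [default_cohort_params()] fills these from
#' the shipped reference counts so that the generator emulates an acutely
#' admitted geriatric polypharmacy cohort (age centred on 84 with IQR
#' roughly 79-88 truncated at 70, around 10 chronic drugs with IQR 8-13,
#' 61% female, about 2.7 trigger-drug combinations per patient).
#'
#' @param n_patients Number of admissions to generate.
#' @param female_fraction Proportion of female patients.
#' @param age_mean,age_sd,age_min Age distribution: normal truncated below
#'   at `age_min` years.
#' @param drug_count_min,drug_count_mu,drug_count_size Chronic drug count:
#'   `drug_count_min` plus a negative binomial with mean `drug_count_mu`
#'   and size `drug_count_size`.
#' @param trigger_weights Named numeric: expected combinations per patient
#'   for each trigger; the per-patient total is negative binomial with mean
#'   `sum(trigger_weights)` and size `dispersion`, truncated at
#'   `max_combinations`.
#' @param causality_mixture Tibble `trigger_id` plus one column per WHO-UMC
#'   category; each row a probability vector summing to one.
#' @param recognition_probs Tibble `trigger_id` plus one probability column
#'   per category: chance that a combination of that trigger and true
#'   category receives planted recognition evidence (an explicit ADR link
#'   or a medication change in a contributing drug).
#' @param dispersion Negative-binomial size of the per-patient combination
#'   count (1 = geometric).
#' @param max_combinations Upper truncation of per-patient combinations.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n_patients,
                          female_fraction,
                          age_mean, age_sd, age_min,
                          drug_count_min, drug_count_mu, drug_count_size,
                          trigger_weights,
                          causality_mixture,
                          recognition_probs,
                          dispersion = 1,
                          max_combinations = 16) {
  params <- structure(
    list(
      n_patients = as.integer(n_patients),
      female_fraction = female_fraction,
      age_mean = age_mean, age_sd = age_sd, age_min = age_min,
      drug_count_min = as.integer(drug_count_min),
      drug_count_mu = drug_count_mu,
      drug_count_size = drug_count_size,
      trigger_weights = trigger_weights,
      causality_mixture = tibble::as_tibble(causality_mixture),
      recognition_probs = tibble::as_tibble(recognition_probs),
      dispersion = dispersion,
      max_combinations = as.integer(max_combinations)
    ),
    class = "cohort_params"
  )
  validate_cohort_params(params)
}

validate_cohort_params <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_patients < 0) stop_input("n_patients must be non-negative")
  probs <- c(params$female_fraction,
             unlist(params$recognition_probs[whoumc_categories]))
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop_input("probabilities must lie in [0, 1]")
  }
  w <- params$trigger_weights
  if (is.null(names(w)) || any(!nzchar(names(w))) || any(w < 0)) {
    stop_input("trigger_weights must be a named non-negative numeric vector")
  }
  mx <- params$causality_mixture
  missing <- setdiff(c("trigger_id", whoumc_categories), names(mx))
  if (length(missing)) {
    stop_input("causality_mixture lacks column(s): ", paste(missing, collapse = ", "))
  }
  sums <- rowSums(mx[whoumc_categories])
  off <- abs(sums - 1) > 1e-8
  if (any(off)) {
    stop_input("causality_mixture rows must sum to 1: ",
               paste(mx$trigger_id[off], collapse = ", "))
  }
  missing_mix <- setdiff(names(w)[w > 0], mx$trigger_id)
  if (length(missing_mix)) {
    stop_input("no causality mixture for weighted trigger(s): ",
               paste(missing_mix, collapse = ", "))
  }
  invisible(params)
}

#' Default generator parameters from the reference evaluation
#'
#' Builds [cohort_params()] whose expected per-trigger combination shares,
#' causality mixtures and recognition probabilities reproduce the shipped
#' reference counts of the default tool's evaluation (345 admissions, 941
#' combinations). Recognition probabilities for probable and certain use
#' the probable+certain stratum rate; the possible-only rate is solved from
#' the two strata; unlikely combinations are recognised at the rate implied
#' by the overall classifiable recognition count (153/536); unclassifiable
#' combinations are never recognised.
#'
#' @param n_patients Cohort size (default 345, the reference cohort).
#' @return A `cohort_params`.
#' @examples
#' p <- default_cohort_params()
#' round(p$trigger_weights[["fall"]] / sum(p$trigger_weights), 3)
#' @export
default_cohort_params <- function(n_patients = 345) {
  ref <- reference_trigger_counts()
  rec <- reference_recognition_counts()
  weights <- setNames(ref$n_combinations / 345, ref$trigger_id)
  mixture <- ref |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(whoumc_categories),
      ~ ifelse(.data$n_combinations > 0, .x / .data$n_combinations, 0)
    )) |>
    dplyr::mutate(
      # zero-frequency triggers never sample a category; keep rows valid
      unlikely = ifelse(.data$n_combinations > 0, .data$unlikely, 1)
    ) |>
    dplyr::select("trigger_id", dplyr::all_of(whoumc_categories))
  rec_counts <- rec |>
    dplyr::mutate(
      rec_all = ifelse(.data$n_adr > 0, round_half_up(.data$n_adr * .data$recognised_pct / 100), 0),
      rec_pc = ifelse(.data$n_adr_pc > 0, round_half_up(.data$n_adr_pc * .data$recognised_pct_pc / 100), 0),
      p_pc = ifelse(.data$n_adr_pc > 0, .data$rec_pc / .data$n_adr_pc, 1),
      n_possible = .data$n_adr - .data$n_adr_pc,
      p_possible = ifelse(.data$n_possible > 0,
                          pmin(1, pmax(0, (.data$rec_all - .data$rec_pc) / .data$n_possible)),
                          1)
    )
  recognition <- tibble::tibble(
    trigger_id = rec_counts$trigger_id,
    certain = rec_counts$p_pc,
    probable = rec_counts$p_pc,
    possible = rec_counts$p_possible,
    unlikely = 153 / 536,
    unclassifiable = 0
  )
  cohort_params(
    n_patients = n_patients,
    female_fraction = 0.61,
    age_mean = 84, age_sd = 6.7, age_min = 70,
    drug_count_min = 5, drug_count_mu = 5.8, drug_count_size = 3,
    trigger_weights = weights,
    causality_mixture = mixture,
    recognition_probs = recognition,
    dispersion = 1,
    max_combinations = 16
  )
}

sample_one <- function(x, prob = NULL) {
  if (length(x) == 1) return(x)
  sample(x, 1, prob = prob)
}

NOISE_EVENTS <- c("pneumonia", "urinary tract infection", "anaemia",
                  "chest pain", "cough", "back pain")

#' Generate a synthetic admission cohort with ground truth
#'
#' Draws a reproducible cohort of structured admission records: each
#' patient receives demographics, a chronic medication list built from the
#' shipped example-drug catalogue, planted trigger events with
#' class-resolving drugs according to the trigger weights, true causality
#' categories from the per-trigger mixtures, and planted recognition
#' evidence (explicit ADR link or medication change) with the configured
#' probabilities; tool-neutral background drugs, noise events and noise
#' medication changes are added on top.
#'
#' Background and contributing drugs are chosen to avoid resolving into the
#' drug classes of the patient's other planted triggers wherever the
#' catalogue allows; where class overlap makes that impossible (several
#' triggers share e.g. the diuretic and renin-angiotensin classes), the
#' extra detections are kept and labelled as incidental in the ground truth
#' (with causality drawn from the same per-trigger mixture), rather than
#' suppressed.
#'
#' @param params A [cohort_params()].
#' @param tool A `trigger_tool` (the default tool).
#' @param seed Integer seed; identical `(params, tool, seed)` give
#'   identical cohorts.
#' @return List with `cohort` (an [adr_cohort()]) and `truth`: a tibble of
#'   every detectable combination (`combination_ref`, `patient_id`,
#'   `trigger_id`, `class_id`, `drugs` list-column, `true_category`,
#'   `recognised`, `planted`), with attribute `incidental_rate`.
#' @export
generate_cohort <- function(params, tool = default_trigger_tool(), seed = 1) {
  validate_cohort_params(params)
  stopifnot(inherits(tool, "trigger_tool"))
  unknown <- setdiff(names(params$trigger_weights), tool$triggers$trigger_id)
  if (length(unknown)) {
    stop_input("trigger_weights reference unknown trigger(s): ",
               paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  if (params$n_patients == 0) {
    empty_cohort <- adr_cohort(
      patients = tibble::tibble(patient_id = character(), age = integer(),
                                sex = character())
    )
    empty_truth <- tibble::tibble(
      combination_ref = character(), patient_id = character(),
      trigger_id = character(), class_id = character(), drugs = list(),
      true_category = character(), recognised = logical(), planted = logical()
    )
    attr(empty_truth, "incidental_rate") <- 0
    attr(empty_truth, "seed") <- seed
    return(list(cohort = empty_cohort, truth = empty_truth))
  }
  drugs <- example_drugs()
  class_map <- classify_atc_codes(drugs$atc_code, tool)
  drug_classes <- purrr::map(
    drugs$atc_code, ~ class_map$class_id[class_map$atc_code == .x]
  )
  names(drug_classes) <- drugs$drug_name
  class_join <- dplyr::inner_join(class_map, drugs, by = "atc_code")
  drugs_by_class <- split(class_join$drug_name, class_join$class_id)
  tc <- trigger_class_table(tool)
  classes_of <- split(tc$class_id, tc$trigger_id)
  syn_of <- setNames(tool$triggers$event_synonyms, tool$triggers$trigger_id)
  w <- params$trigger_weights
  w <- w[w > 0]
  mu_total <- sum(w)
  mix <- params$causality_mixture
  mix_mat <- as.matrix(mix[whoumc_categories])
  rownames(mix_mat) <- mix$trigger_id
  rec <- params$recognition_probs
  rec_mat <- as.matrix(rec[whoumc_categories])
  rownames(rec_mat) <- rec$trigger_id
  ref <- reference_trigger_counts()
  mean_drugs_ref <- setNames(ifelse(is.na(ref$mean_drugs), 1, ref$mean_drugs),
                             ref$trigger_id)

  n <- params$n_patients
  pad <- max(4, nchar(as.character(n)))
  pids <- sprintf("p%0*d", pad, seq_len(n))
  sexes <- ifelse(runif(n) < params$female_fraction, "female", "male")
  u <- runif(n, pnorm(params$age_min, params$age_mean, params$age_sd), 1)
  ages <- round(qnorm(u, params$age_mean, params$age_sd))
  n_drugs_all <- params$drug_count_min +
    rnbinom(n, size = params$drug_count_size, mu = params$drug_count_mu)
  k_all <- pmin(rnbinom(n, size = params$dispersion, mu = mu_total),
                params$max_combinations)
  dates <- sprintf("2015-%02d-%02d", sample.int(12, n, replace = TRUE),
                   sample.int(28, n, replace = TRUE))

  # growing accumulators (cohort sizes are small enough for simple appends)
  ev_pid <- character(); ev_label <- character(); ev_doc <- character()
  md_pid <- character(); md_drug <- character()
  ch_pid <- character(); ch_drug <- character(); ch_action <- character()
  ln_pid <- character(); ln_event <- character(); ln_drug <- character()
  tr_pid <- character(); tr_trig <- character(); tr_class <- character()
  tr_drugs <- list(); tr_cat <- character(); tr_rec <- logical()

  # Strict conflict-free (class, drugs) assignment for trigger t: the new
  # combination is not detectable under any other planted trigger of the
  # patient and its drugs resolve to no planted class but their own.
  # NULL when impossible.
  try_assign_strict <- function(t, active, used_classes, used_drugs) {
    t_classes <- classes_of[[t]]
    other_classes <- unique(unlist(classes_of[setdiff(active, t)], use.names = FALSE))
    cand <- setdiff(setdiff(t_classes, used_classes[[t]]), other_classes)
    if (length(cand) == 0) return(NULL)
    all_blocked <- unique(c(t_classes, other_classes))
    for (cl in sample(cand)) {
      pool <- setdiff(drugs_by_class[[cl]] %||% character(), used_drugs)
      clean <- pool[purrr::map_lgl(pool, function(d) {
        !any(setdiff(drug_classes[[d]], cl) %in% all_blocked)
      })]
      if (length(clean)) {
        n_d <- min(length(clean), 1 + rpois(1, max(0, mean_drugs_ref[[t]] - 1)))
        chosen <- if (length(clean) == 1) clean else sample(clean, n_d)
        return(list(class = cl, drugs = chosen))
      }
    }
    NULL
  }

  # Shared assignment: the slot reuses a class (and possibly drugs) that
  # other planted triggers are also associated with, exactly as one drug
  # documented under two clinical events counts under both triggers.
  # Classes whose sibling combinations can be absorbed by the patient's
  # remaining slot draws are preferred, keeping per-trigger totals close to
  # the configured weights.
  try_assign_shared <- function(t, active, used_classes, used_drugs, remaining) {
    t_classes <- classes_of[[t]]
    active_classes <- unique(unlist(classes_of[unique(c(active, t))], use.names = FALSE))
    cand <- setdiff(t_classes, used_classes[[t]])
    if (length(cand) == 0) return(NULL)
    cand <- sample(cand)
    cost <- purrr::map_int(cand, function(cl) {
      sibs <- purrr::keep(setdiff(active, t), function(s) {
        cl %in% classes_of[[s]] && !cl %in% used_classes[[s]]
      })
      sum(remaining[sibs] == 0L)
    })
    cand <- cand[order(cost)]
    for (cl in cand) {
      in_class <- used_drugs[purrr::map_lgl(used_drugs, function(d) {
        cl %in% drug_classes[[d]]
      })]
      if (length(in_class)) {
        return(list(class = cl, drugs = in_class, new_drugs = character()))
      }
      pool <- setdiff(drugs_by_class[[cl]] %||% character(), used_drugs)
      clean <- pool[purrr::map_lgl(pool, function(d) {
        !any(setdiff(drug_classes[[d]], cl) %in% active_classes)
      })]
      if (length(clean)) {
        chosen <- sample_one(clean)
        return(list(class = cl, drugs = chosen, new_drugs = chosen))
      }
    }
    NULL
  }

  for (i in seq_len(n)) {
    pid <- pids[i]
    k <- k_all[i]
    slots <- if (k > 0 && mu_total > 0) {
      sample(names(w), k, replace = TRUE, prob = w)
    } else {
      character()
    }
    active <- character()            # triggers with a planted event
    event_of <- list()               # planted event label per trigger
    used_classes <- list()           # classes used per trigger
    used_drugs <- character()
    credits <- setNames(integer(length(w)), names(w))
    # patient-local combination accumulators
    p_trig <- character(); p_class <- character(); p_drugs <- list()
    p_cat <- character(); p_rec <- logical()

    draw_combo <- function(t) {
      true_cat <- sample_one(whoumc_categories, prob = mix_mat[t, ])
      p_r <- rec_mat[t, true_cat]
      if (is.na(p_r)) p_r <- 0
      c(true_cat, runif(1) < p_r)
    }
    activate <- function(t) {
      # planting t's event; any used drug already resolving into t's classes
      # becomes a sibling combination of t (the event catches it too)
      active <<- c(active, t)
      event_of[[t]] <<- sample_one(syn_of[[t]])
      ev_pid <<- c(ev_pid, pid); ev_label <<- c(ev_label, event_of[[t]])
      ev_doc <<- c(ev_doc, sample_one(EVENT_DOCUMENTED_AS))
      for (cl_e in intersect(classes_of[[t]], unique(unlist(purrr::map(used_drugs, ~ drug_classes[[.x]]))))) {
        ds <- used_drugs[purrr::map_lgl(used_drugs, function(d) cl_e %in% drug_classes[[d]])]
        cr <- draw_combo(t)
        p_trig <<- c(p_trig, t); p_class <<- c(p_class, cl_e)
        p_drugs[[length(p_drugs) + 1]] <<- ds
        p_cat <<- c(p_cat, cr[1]); p_rec <<- c(p_rec, as.logical(cr[2]))
        used_classes[[t]] <<- c(used_classes[[t]], cl_e)
        credits[[t]] <<- credits[[t]] + 1L
      }
    }

    remaining <- setNames(integer(length(w)), names(w))
    for (s in slots) remaining[[s]] <- remaining[[s]] + 1L

    for (slot_t in slots) {
      t <- slot_t
      remaining[[t]] <- remaining[[t]] - 1L
      if (credits[[t]] > 0) {
        # this trigger already gained a combination through class sharing
        credits[[t]] <- credits[[t]] - 1L
        next
      }
      if (!t %in% active) {
        activate(t)
        if (credits[[t]] > 0) {
          # the new event already caught planted drugs; that combination
          # satisfies this slot
          credits[[t]] <- credits[[t]] - 1L
          next
        }
      }
      res <- try_assign_strict(t, active, used_classes, used_drugs)
      if (is.null(res)) {
        res <- try_assign_shared(t, active, used_classes, used_drugs, remaining)
        if (is.null(res)) next
      } else {
        res$new_drugs <- res$drugs
      }
      cl <- res$class
      used_classes[[t]] <- c(used_classes[[t]], cl)
      used_drugs <- c(used_drugs, res$new_drugs)
      cr <- draw_combo(t)
      p_trig <- c(p_trig, t); p_class <- c(p_class, cl)
      p_drugs[[length(p_drugs) + 1]] <- res$drugs
      p_cat <- c(p_cat, cr[1]); p_rec <- c(p_rec, as.logical(cr[2]))
      # class sharing: the same drugs are detected under every other active
      # trigger associated with this class; plant those siblings too
      for (s in setdiff(active, t)) {
        if (cl %in% classes_of[[s]] && !cl %in% used_classes[[s]]) {
          crs <- draw_combo(s)
          p_trig <- c(p_trig, s); p_class <- c(p_class, cl)
          p_drugs[[length(p_drugs) + 1]] <- res$drugs
          p_cat <- c(p_cat, crs[1]); p_rec <- c(p_rec, as.logical(crs[2]))
          used_classes[[s]] <- c(used_classes[[s]], cl)
          credits[[s]] <- credits[[s]] + 1L
        }
      }
    }

    # final contributing-drug list per combination mirrors detection:
    # every planted drug of the class contributes
    if (length(p_trig)) {
      p_drugs <- purrr::map(p_class, function(cl) {
        sort(used_drugs[purrr::map_lgl(used_drugs, function(d) cl %in% drug_classes[[d]])])
      })
    }

    # materialise recognition evidence: medication changes only for drugs
    # contributing to a single combination (a change in a shared drug would
    # recognise every combination it contributes to); explicit trigger-drug
    # links otherwise
    if (length(p_trig)) {
      drug_combo_count <- table(unlist(p_drugs))
      for (ci in seq_along(p_trig)) {
        if (!p_rec[ci]) next
        ds <- p_drugs[[ci]]
        uniq <- ds[drug_combo_count[ds] == 1]
        if (length(uniq) && runif(1) < 0.5) {
          ch_pid <- c(ch_pid, pid); ch_drug <- c(ch_drug, sample_one(uniq))
          ch_action <- c(ch_action, sample_one(CHANGE_ACTIONS))
        } else {
          ln_pid <- c(ln_pid, pid)
          ln_event <- c(ln_event, event_of[[p_trig[ci]]])
          ln_drug <- c(ln_drug, ds[1])
        }
      }
    }

    tr_pid <- c(tr_pid, rep(pid, length(p_trig)))
    tr_trig <- c(tr_trig, p_trig); tr_class <- c(tr_class, p_class)
    tr_drugs <- c(tr_drugs, p_drugs)
    tr_cat <- c(tr_cat, p_cat); tr_rec <- c(tr_rec, p_rec)

    blocked_classes <- unique(unlist(classes_of[active], use.names = FALSE))
    deficit <- n_drugs_all[i] - length(used_drugs)
    background <- character()
    if (deficit > 0) {
      pool <- setdiff(drugs$drug_name, c(used_drugs, "hydrocortisone cream"))
      pool <- pool[purrr::map_lgl(pool, function(d) {
        !any(drug_classes[[d]] %in% blocked_classes)
      })]
      background <- if (length(pool) <= deficit) pool else sample(pool, deficit)
    }
    all_drugs <- c(used_drugs, background)
    md_pid <- c(md_pid, rep(pid, length(all_drugs)))
    md_drug <- c(md_drug, all_drugs)
    if (runif(1) < 0.3) {
      ev_pid <- c(ev_pid, pid)
      ev_label <- c(ev_label, sample_one(NOISE_EVENTS))
      ev_doc <- c(ev_doc, sample_one(EVENT_DOCUMENTED_AS))
    }
    safe <- setdiff(all_drugs, unique(unlist(p_drugs)))
    if (length(safe) && runif(1) < 0.15) {
      ch_pid <- c(ch_pid, pid); ch_drug <- c(ch_drug, sample_one(safe))
      ch_action <- c(ch_action, sample_one(CHANGE_ACTIONS))
    }
  }

  cohort <- adr_cohort(
    patients = tibble::tibble(patient_id = pids, age = ages, sex = sexes,
                              admission_date = dates),
    medications = nullify_empty(tibble::tibble(
      patient_id = md_pid, drug_name = md_drug,
      atc_code = drugs$atc_code[match(md_drug, drugs$drug_name)],
      chronic = TRUE
    )),
    events = nullify_empty(tibble::tibble(
      patient_id = ev_pid, label = ev_label,
      source = "admission_letter", documented_as = ev_doc
    )),
    medication_changes = nullify_empty(tibble::tibble(
      patient_id = ch_pid, drug_name = ch_drug, action = ch_action
    )),
    adr_links = nullify_empty(tibble::tibble(
      patient_id = ln_pid, event_label = ln_event, drug_name = ln_drug
    ))
  )
  truth <- tibble::tibble(
    combination_ref = paste(tr_pid, tr_trig, tr_class, sep = "::"),
    patient_id = tr_pid, trigger_id = tr_trig, class_id = tr_class,
    drugs = tr_drugs, true_category = tr_cat, recognised = tr_rec,
    planted = TRUE
  )

  # label incidental detections and give them causality from the mixture
  detected <- suppressWarnings(detect_combinations(cohort, tool))
  incidental <- detected[!detected$combination_ref %in% truth$combination_ref, ]
  if (nrow(incidental)) {
    inc_cat <- purrr::map_chr(incidental$trigger_id, function(t) {
      if (!t %in% rownames(mix_mat)) return("unlikely")
      sample_one(whoumc_categories, prob = mix_mat[t, ])
    })
    inc_rec <- assess_recognition(incidental, cohort, tool)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      combination_ref = incidental$combination_ref,
      patient_id = incidental$patient_id,
      trigger_id = incidental$trigger_id,
      class_id = incidental$class_id,
      drugs = incidental$contributing_drugs,
      true_category = inc_cat,
      recognised = inc_rec$recognised,
      planted = FALSE
    ))
  }
  attr(truth, "incidental_rate") <- if (nrow(truth)) mean(!truth$planted) else 0
  attr(truth, "seed") <- seed
  list(cohort = cohort, truth = truth)
}

#' Simulated dual raters over a ground truth
#'
#' Rater A returns each combination's true category; rater B independently
#' perturbs each to an adjacent category (on the chain certain-probable-
#' possible-unlikely-unclassifiable, ends moving inward) with probability
#' `error_rate`. At `error_rate = 0` both raters equal the truth.
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param error_rate Per-combination perturbation probability in \[0, 1\].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Tibble with `combination_ref`, `category_a`, `category_b`,
#'   ready for [reach_consensus()] and [cohens_kappa()].
#' @export
perfect_rater <- function(truth, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) stop_input("error_rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  a <- truth$true_category
  idx <- match(a, whoumc_categories)
  flip <- runif(length(a)) < error_rate
  step <- ifelse(idx == 1, 1L,
                 ifelse(idx == length(whoumc_categories), -1L,
                        sample(c(-1L, 1L), length(a), replace = TRUE)))
  b <- ifelse(flip, whoumc_categories[idx + step], a)
  tibble::tibble(
    combination_ref = truth$combination_ref,
    category_a = a,
    category_b = b
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Convenience wrapper: generates a cohort, detects combinations, simulates
#' the dual-rater assessment (disagreements resolved by discussion back to
#' the true category), classifies recognition from the planted evidence,
#' and evaluates performance.
#'
#' @param params A [cohort_params()] (default [default_cohort_params()]).
#' @param tool A `trigger_tool`.
#' @param seed Integer seed for the whole run.
#' @param rater_error Perturbation probability for the second rater
#'   (default 163/941, the reference discordance).
#' @return List with `cohort`, `truth`, `combinations`, `ratings`,
#'   `consensus`, `kappa`, `recognition` and `performance`.
#' @examples
#' \donttest{
#' sim <- simulate_study(default_cohort_params(n_patients = 50), seed = 7)
#' glance(sim$performance)
#' }
#' @export
simulate_study <- function(params = default_cohort_params(),
                           tool = default_trigger_tool(),
                           seed = 1,
                           rater_error = 163 / 941) {
  gen <- generate_cohort(params, tool, seed = seed)
  combinations <- suppressWarnings(detect_combinations(gen$cohort, tool))
  truth <- gen$truth[match(combinations$combination_ref, gen$truth$combination_ref), ]
  ratings <- perfect_rater(truth, rater_error)
  ratings$resolution <- ifelse(ratings$category_a == ratings$category_b,
                               NA_character_, truth$true_category)
  consensus <- reach_consensus(ratings)
  kappa <- if (nrow(ratings)) cohens_kappa(ratings) else NULL
  recognition <- assess_recognition(combinations, gen$cohort, tool)
  performance <- compute_performance(combinations, consensus, tool,
                                     recognition = recognition)
  list(
    cohort = gen$cohort, truth = truth, combinations = combinations,
    ratings = ratings, consensus = consensus, kappa = kappa,
    recognition = recognition, performance = performance
  )
}
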