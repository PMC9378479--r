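tool <- default_trigger_tool()

test_that("reference counts are internally consistent and produce the report", {
  ref <- reference_trigger_counts()
  perf <- performance_from_counts(ref)
  expect_identical(perf$totals$n_combinations, sum(ref$n_combinations))
  expect_identical(perf$totals$n_adr,
                   sum(ref$possible + ref$probable + ref$certain))
  # column sums of the rows reproduce the totals
  for (cat in whoumc_categories) {
    expect_identical(sum(perf$rows[[cat]]), perf$totals[[cat]])
  }
  expect_equal(sum(perf$rows$share_of_total), 1, tolerance = 1e-12)
  # zero-count triggers are reported with undefined PPV, not dropped
  icb <- perf$rows[perf$rows$trigger_id == "intracranial_bleeding", ]
  expect_identical(icb$n_combinations, 0L)
  expect_true(is.na(icb$ppv))
})

test_that("per-trigger PPV is ADRs over combinations", {
  perf <- performance_from_counts(reference_trigger_counts())
  row <- function(id) perf$rows[perf$rows$trigger_id == id, ]
  expect_equal(row("hypokalaemia")$ppv, 1)
  expect_equal(row("fracture")$ppv, 0)
  expect_equal(row("constipation_ileus")$ppv, 24 / 35, tolerance = 1e-12)
})

test_that("exclusions recompute totals over remaining rows", {
  perf <- performance_from_counts(reference_trigger_counts(),
                                  exclude_triggers = c("fall", "delirium"))
  expect_identical(nrow(perf$rows), 14L)
  expect_identical(perf$exclusions, c("fall", "delirium"))
  expect_error(
    performance_from_counts(reference_trigger_counts(),
                            exclude_triggers = "nope"),
    class = "adrtrigger_lookup_error"
  )
  # excluding a trigger with PPV below the overall PPV raises the overall PPV
  full <- performance_from_counts(reference_trigger_counts())
  low <- full$rows$trigger_id[
    !is.na(full$rows$ppv) & full$rows$ppv < full$totals$ppv &
      full$rows$n_combinations > 0
  ]
  for (id in low) {
    excl <- performance_from_counts(reference_trigger_counts(),
                                    exclude_triggers = id)
    expect_gt(excl$totals$ppv, full$totals$ppv)
  }
})

test_that("proportions are invariant to scaling all counts", {
  ref <- reference_trigger_counts()
  scaled <- dplyr::mutate(ref, dplyr::across(
    c("n_combinations", dplyr::all_of(whoumc_categories)), ~ .x * 3L
  ))
  a <- performance_from_counts(ref)
  b <- performance_from_counts(scaled)
  expect_equal(a$rows$ppv, b$rows$ppv)
  expect_equal(a$rows$share_of_total, b$rows$share_of_total)
  expect_equal(a$totals$ppv, b$totals$ppv)
})

test_that("inconsistent causality counts are rejected", {
  bad <- reference_trigger_counts()
  bad$possible[1] <- bad$possible[1] + 1L
  expect_error(performance_from_counts(bad),
               class = "adrtrigger_validation_error")
})

test_that("compute_performance aggregates combination-level output", {
  both <- merge_cohorts(constipation_cohort("pA"), hyponatraemia_cohort("pB"))
  combos <- detect_combinations(both, tool)
  consensus <- tibble::tibble(
    combination_ref = combos$combination_ref,
    final_category = c("probable", "possible", "unlikely")[seq_len(nrow(combos))]
  )
  perf <- compute_performance(combos, consensus, tool)
  expect_identical(perf$totals$n_combinations, 3L)
  expect_identical(perf$totals$n_adr, 2L)
  expect_equal(perf$totals$ppv, 2 / 3, tolerance = 1e-12)
  hypo <- perf$rows[perf$rows$trigger_id == "hyponatraemia", ]
  expect_identical(hypo$n_combinations, 2L)
  # the two diuretics under one trigger event give two drugs per trigger
  expect_equal(hypo$mean_drugs, 2)
  expect_error(compute_performance(combos, consensus[-1, ], tool),
               class = "adrtrigger_input_error")
})

test_that("causality distributions cover all five categories and sum to one", {
  perf <- performance_from_counts(reference_trigger_counts())
  dist <- causality_distribution(perf)
  expect_identical(dist$category, whoumc_categories)
  expect_identical(sum(dist$n), perf$totals$n_combinations)
  expect_equal(sum(dist$proportion), 1, tolerance = 1e-12)

  single <- causality_distribution(c("certain"))
  expect_identical(single$n[single$category == "certain"], 1L)
  expect_identical(single$proportion[single$category == "certain"], 1)
  expect_error(causality_distribution(character()),
               class = "adrtrigger_input_error")
})

test_that("drug attribution groups classes to reporting level", {
  both <- merge_cohorts(constipation_cohort("pA"), hyponatraemia_cohort("pB"))
  combos <- detect_combinations(both, tool)
  consensus <- tibble::tibble(
    combination_ref = combos$combination_ref,
    final_category = "possible"
  )
  attr_tbl <- drug_attribution(combos, consensus)
  expect_setequal(attr_tbl$drug_group, c("Analgesics", "Diuretics"))
  expect_identical(sum(attr_tbl$n), 3L)
  overall <- attribution_overall(attr_tbl)
  expect_identical(overall$drug_group[1], "Diuretics")
  expect_equal(overall$share[overall$drug_group == "Diuretics"], 2 / 3,
               tolerance = 1e-12)
  # nothing attributed when the restriction excludes everything
  none <- drug_attribution(combos, dplyr::mutate(consensus,
                                                 final_category = "unlikely"))
  expect_identical(nrow(none), 0L)
})

test_that("display rounding is half away from zero", {
  expect_identical(round_half_up(c(41.75, 23.05, -0.5, 0.5), 1),
                   c(41.8, 23.1, -0.5, 0.5))
  expect_identical(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  perf <- performance_from_counts(reference_trigger_counts())
  rendered <- render_performance(perf)
  expect_equal(rendered$ppv_pct,
               round_half_up(100 * rendered$ppv, 1))
})

test_that("reports round-trip through JSON", {
  both <- merge_cohorts(constipation_cohort("pA"), hyponatraemia_cohort("pB"))
  combos <- detect_combinations(both, tool)
  consensus <- tibble::tibble(
    combination_ref = combos$combination_ref,
    final_category = c("probable", "possible", "unlikely")[seq_len(nrow(combos))]
  )
  rec <- assess_recognition(combos, both, tool)
  perf <- compute_performance(combos, consensus, tool, recognition = rec)
  dir <- tempfile()
  write_performance_report(perf, dir)
  expect_true(file.exists(file.path(dir, "performance.tsv")))
  back <- read_performance_report(file.path(dir, "report.json"))
  expect_equal(back$rows, perf$rows, tolerance = 1e-12)
  expect_equal(back$totals, perf$totals, tolerance = 1e-12)
  expect_equal(back$recognition, perf$recognition, tolerance = 1e-12)
  expect_identical(back$exclusions, perf$exclusions)
})

test_that("tidy, glance and autoplot work on performance reports", {
  perf <- performance_from_counts(reference_trigger_counts())
  expect_identical(tidy(perf), perf$rows)
  gl <- glance(perf)
  expect_identical(gl$n_combinations, perf$totals$n_combinations)
  expect_s3_class(autoplot(perf), "ggplot")
})
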