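test_that("the WHO-UMC decision table scores canonical evidence patterns", {
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "plausible", alternative_explanation = "excluded",
    dechallenge = "positive", rechallenge = "positive"
  )), "certain")
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "plausible", alternative_explanation = "excluded",
    dechallenge = "positive", pharmacologically_definitive = TRUE
  )), "certain")
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "plausible", alternative_explanation = "unlikely",
    dechallenge = "positive"
  )), "probable")
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "plausible", alternative_explanation = "plausible",
    dechallenge = "unknown"
  )), "possible")
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "improbable"
  )), "unlikely")
  expect_identical(classify_whoumc(causality_evidence(
    temporal_relationship = "plausible", alternative_explanation = "plausible",
    dechallenge = "negative"
  )), "unlikely")
  expect_identical(classify_whoumc(causality_evidence(
    data_sufficient = FALSE
  )), "unclassifiable")
  expect_error(causality_evidence(temporal_relationship = "maybe"),
               class = "adrtrigger_input_error")
})

test_that("strengthening any single evidence field never lowers the category", {
  # lattice orders, weakest to strongest causal support
  lattice <- list(
    temporal_relationship = c("improbable", "unknown", "plausible"),
    alternative_explanation = c("plausible", "unknown", "unlikely", "excluded"),
    dechallenge = c("negative", "not_done", "unknown", "positive"),
    rechallenge = c("negative", "not_done", "positive"),
    pharmacologically_definitive = c(FALSE, TRUE),
    data_sufficient = c(FALSE, TRUE)
  )
  rank <- c(unclassifiable = 0, unlikely = 1, possible = 2, probable = 3, certain = 4)
  set.seed(2024)
  for (rep in 1:200) {
    ev <- causality_evidence(
      temporal_relationship = sample(lattice$temporal_relationship, 1),
      alternative_explanation = sample(lattice$alternative_explanation, 1),
      dechallenge = sample(lattice$dechallenge, 1),
      rechallenge = sample(lattice$rechallenge, 1),
      pharmacologically_definitive = sample(c(TRUE, FALSE), 1),
      data_sufficient = sample(c(TRUE, FALSE), 1)
    )
    field <- sample(names(lattice), 1)
    pos <- match(list(ev[[field]]), as.list(lattice[[field]]))
    if (pos == length(lattice[[field]])) next
    up <- ev
    up[[field]] <- lattice[[field]][pos + 1]
    expect_gte(rank[[classify_whoumc(up)]], rank[[classify_whoumc(ev)]])
  }
})

test_that("consensus follows the immediate / discussed / third-expert protocol", {
  out <- reach_consensus(tibble::tibble(
    combination_ref = c("c1", "c2", "c3"),
    category_a = c("possible", "possible", "unlikely"),
    category_b = c("possible", "probable", "certain"),
    resolution = c(NA, "probable", NA),
    third_expert = c(NA, NA, "probable")
  ))
  expect_identical(out$final_category, c("possible", "probable", "probable"))
  expect_identical(out$agreement_path, c("immediate", "discussed", "third_expert"))

  expect_error(reach_consensus(tibble::tibble(
    combination_ref = "c1", category_a = "possible", category_b = "certain"
  )), class = "adrtrigger_input_error")

  a <- tibble::tibble(combination_ref = c("c1", "c2"), rater_id = "A",
                      category = c("possible", "unlikely"))
  b <- tibble::tibble(combination_ref = c("c1", "c3"), rater_id = "B",
                      category = c("possible", "unlikely"))
  expect_error(pair_assessments(a, b), class = "adrtrigger_input_error")
})

test_that("unclassifiable against any ordered category counts as disagreement", {
  expect_error(reach_consensus(tibble::tibble(
    combination_ref = "c1",
    category_a = "unclassifiable", category_b = "unlikely"
  )), class = "adrtrigger_input_error")
  ok <- reach_consensus(tibble::tibble(
    combination_ref = "c1",
    category_a = "unclassifiable", category_b = "unlikely",
    resolution = "unlikely"
  ))
  expect_identical(ok$agreement_path, "discussed")
})

test_that("kappa reproduces hand-computed agreement statistics", {
  perfect <- cohens_kappa(rep(whoumc_categories, 3), rep(whoumc_categories, 3))
  expect_identical(perfect$kappa, 1)
  expect_identical(perfect$n_discordant, 0L)

  # 2x2 confusion [[45, 15], [25, 15]]: po = 0.60, pe = 0.54
  k <- cohens_kappa(pairs_from_counts(45, 15, 25, 15))
  expect_equal(k$observed_agreement, 0.60, tolerance = 1e-12)
  expect_equal(k$expected_agreement, 0.54, tolerance = 1e-12)
  expect_equal(k$kappa, 0.06 / 0.46, tolerance = 1e-12)

  expect_error(cohens_kappa(tibble::tibble(category_a = character(),
                                           category_b = character())),
               class = "adrtrigger_input_error")
})

test_that("kappa matches an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (rep in 1:20) {
    a <- sample(whoumc_categories, 300, replace = TRUE)
    b <- ifelse(runif(300) < 0.6, a, sample(whoumc_categories, 300, replace = TRUE))
    ours <- cohens_kappa(a, b)
    tab <- table(factor(a, whoumc_categories), factor(b, whoumc_categories))
    theirs <- e1071::classAgreement(tab)
    expect_equal(ours$kappa, theirs$kappa, tolerance = 1e-10)
    expect_equal(ours$observed_agreement, theirs$diag, tolerance = 1e-10)
  }
})

test_that("kappa is invariant under relabelling and bounded by observed agreement", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sample(whoumc_categories, 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.5, a, sample(whoumc_categories, 200, replace = TRUE))
    k <- cohens_kappa(a, b)
    perm <- setNames(sample(whoumc_categories), whoumc_categories)
    k2 <- cohens_kappa(unname(perm[a]), unname(perm[b]))
    expect_equal(k2$kappa, k$kappa, tolerance = 1e-12)
    if (k$expected_agreement > 0) {
      expect_lte(k$kappa, k$observed_agreement + 1e-12)
    }
    expect_identical(k$kappa == 1, k$observed_agreement == 1)
  }
})

test_that("degenerate single-category ratings warn and keep the agreement identity", {
  expect_warning(k <- cohens_kappa(rep("possible", 10), rep("possible", 10)),
                 "degenerate")
  expect_identical(k$kappa, 1)
})

test_that("kappa bands follow the printed intervals including their edges", {
  expect_identical(kappa_band(0.76), "substantial")
  expect_identical(kappa_band(0.85), "almost_perfect")
  expect_identical(kappa_band(-0.05), "poor")
  expect_identical(
    kappa_band(c(0, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81, 1)),
    c("slight", "slight", "fair", "fair", "moderate", "moderate",
      "substantial", "substantial", "almost_perfect", "almost_perfect")
  )
  expect_error(kappa_band(1.2), class = "adrtrigger_input_error")
})

test_that("is_adr partitions the five categories", {
  expect_identical(is_adr(whoumc_categories),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(is_adr("definite"), class = "adrtrigger_input_error")
})

test_that("tidy and glance expose the confusion table and summary", {
  k <- cohens_kappa(pairs_from_counts(45, 15, 25, 15))
  td <- tidy(k)
  expect_identical(sum(td$n), 100L)
  gl <- glance(k)
  expect_identical(gl$n_pairs, 100L)
  expect_identical(gl$n_discordant, 40L)
  expect_s3_class(autoplot(k), "ggplot")
})
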