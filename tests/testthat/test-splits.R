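# Pig-level stratified splitting and cross-validation folds.

toy_pigs <- function(n_fr_pigs = 6, n_nr_pigs = 6, boluses = 5) {
  data.frame(
    pig_id = sprintf("pig%02d", seq_len(n_fr_pigs + n_nr_pigs)),
    injury_model = rep(c("HEM", "IRI", "EPACC"),
                       length.out = n_fr_pigs + n_nr_pigs),
    n_boluses = boluses,
    n_fr = c(rep(boluses, n_fr_pigs), rep(0, n_nr_pigs)),
    stringsAsFactors = FALSE
  )
}

test_that("58 pigs split into disjoint 29/29 halves across all plans", {
  feats <- fixture_study_features()
  pigs <- pig_label_table(feats)
  splits <- make_splits(pigs, n_splits = 29, seed = 3)
  expect_length(splits, 29)
  for (sp in splits) {
    expect_length(sp$train_pigs, 29)
    expect_length(sp$test_pigs, 29)
    expect_length(intersect(sp$train_pigs, sp$test_pigs), 0)
    expect_setequal(c(sp$train_pigs, sp$test_pigs), pigs$pig_id)
  }
})

test_that("splitting is deterministic given the seed", {
  pigs <- toy_pigs()
  a <- make_splits(pigs, 5, seed = 4)
  b <- make_splits(pigs, 5, seed = 4)
  expect_identical(lapply(a, `[[`, "train_pigs"),
                   lapply(b, `[[`, "train_pigs"))
})

test_that("uniform per-pig prevalence yields that prevalence on both sides", {
  pigs <- toy_pigs(0, 8)
  pigs$n_fr <- 2 # every pig 2/5 FR
  sp <- make_splits(pigs, 3, seed = 5)
  for (s in sp) {
    expect_equal(s$fr_prevalence_train, 0.4)
    expect_equal(s$fr_prevalence_test, 0.4)
  }
})

test_that("stratified splitter matches the exhaustive optimum on a toy cohort", {
  pigs <- toy_pigs(6, 6, boluses = 5) # adversarial: pigs all-FR or all-NR
  splits <- make_splits(pigs, 5, seed = 6)
  # brute-force best achievable score over all half-partitions
  combos <- utils::combn(pigs$pig_id, 6, simplify = FALSE)
  best <- min(vapply(combos, function(tr)
    fluidresp:::split_score(pigs, tr, 0.5, 0.25), numeric(1)))
  for (sp in splits) {
    expect_lte(sp$score, best * 1.1 + 1e-12)
    expect_lt(abs(sp$fr_prevalence_train - 0.5), 0.05)
    expect_lt(abs(sp$fr_prevalence_test - 0.5), 0.05)
  }
})

test_that("29 training pigs spread into folds of sizes 6,6,6,6,5", {
  feats <- fixture_study_features()
  pigs <- pig_label_table(feats)
  sp <- make_splits(pigs, 1, seed = 3)[[1]]
  folds <- make_cv_folds(sp, pigs, k = 5, seed = 9)
  expect_setequal(folds$pig_id, sp$train_pigs)
  expect_equal(sort(as.integer(table(folds$fold))), c(5L, 6L, 6L, 6L, 6L))
  expect_false(any(duplicated(folds$pig_id))) # no pig spans folds
})

test_that("fold FR prevalences are balanced on a toy cohort", {
  pigs <- toy_pigs(5, 5, boluses = 4)
  sp <- structure(list(split_id = 1, train_pigs = pigs$pig_id,
                       test_pigs = character(0)), class = "split_plan")
  folds <- make_cv_folds(sp, pigs, k = 5, seed = 2)
  prev <- sapply(split(folds$pig_id, folds$fold), function(ids) {
    d <- pigs[pigs$pig_id %in% ids, ]
    sum(d$n_fr) / sum(d$n_boluses)
  })
  expect_lte(max(prev) - min(prev), 0.15)
})

test_that("degenerate split requests are rejected", {
  pigs <- toy_pigs(2, 1)
  expect_error(make_splits(pigs, 2, seed = 1), "at least 4")
  pigs <- toy_pigs(3, 3)
  expect_error(make_splits(pigs, 0, seed = 1), "n_splits")
  sp <- make_splits(pigs, 1, seed = 1)[[1]]
  expect_error(make_cv_folds(sp, pigs, k = 5, seed = 1), "fewer training pigs")
})

test_that("plans serialize to a reproducible long table", {
  pigs <- toy_pigs()
  splits <- make_splits(pigs, 2, seed = 4)
  folds <- lapply(splits, make_cv_folds, pigs = pigs, k = 3, seed = 4)
  tab <- splits_to_table(splits, folds)
  expect_equal(nrow(tab), 2 * nrow(pigs))
  expect_true(all(is.na(tab$fold[tab$role == "test"])))
  expect_true(all(!is.na(tab$fold[tab$role == "train"])))
})
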