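# Feature selection: KS screening + correlation pruning, RFE, permutation
# importance, mutual information, and the consensus rule.

test_that("statistical selection keeps a strongly separated feature", {
  pt <- make_planted_table(n_per_class = 100)
  res <- select_statistical(pt$x, pt$y)
  expect_s3_class(res, "selection_result")
  expect_true("signal" %in% res$retained)
})

test_that("duplicated features are pruned to a single survivor", {
  pt <- make_planted_table(n_per_class = 50, n_noise = 5)
  x <- pt$x
  x$signal_copy <- x$signal # |r| = 1 with signal
  res <- select_statistical(x, pt$y)
  expect_equal(sum(c("signal", "signal_copy") %in% res$retained), 1)
  # no retained pair above the pruning threshold
  if (length(res$retained) > 1) {
    cm <- abs(stats::cor(x[res$retained]))
    diag(cm) <- 0
    expect_lt(max(cm), 0.9)
  }
})

test_that("the literal retention direction is available behind a flag", {
  pt <- make_planted_table(n_per_class = 100)
  res <- select_statistical(pt$x, pt$y, direction = "literal")
  expect_false("signal" %in% res$retained)
  expect_error(select_statistical(pt$x, rep("FR", 200)), "both classes")
})

test_that("RFE returns exactly n_keep features and keeps a perfect separator", {
  pt <- make_planted_table(n_per_class = 40, effect = 8)
  res <- select_rfe(pt$x, pt$y, n_keep = 10, seed = 2, ntree = 80)
  expect_length(res$retained, 10)
  expect_true("signal" %in% res$retained)
  all50 <- select_rfe(pt$x, pt$y, n_keep = ncol(pt$x), seed = 2, ntree = 50)
  expect_setequal(all50$retained, names(pt$x))
  expect_error(select_rfe(pt$x, pt$y, n_keep = 99, seed = 2), "exceeds")
})

test_that("permutation importance ranks the informative feature first", {
  pt <- make_planted_table(n_per_class = 40, effect = 4)
  fold_id <- rep(1:5, length.out = length(pt$y))
  res <- select_permutation(pt$x, pt$y, fold_id, n_keep = 10, seed = 3,
                            ntree = 80)
  expect_length(res$retained, 10)
  expect_equal(res$retained[1], "signal")
  imp <- res$diagnostics
  expect_gt(imp$importance[imp$feature == "signal"],
            max(imp$importance[imp$feature != "signal"]))
})

test_that("permutation importances vanish when labels are shuffled", {
  pt <- make_planted_table(n_per_class = 40, effect = 4)
  set.seed(8)
  y_perm <- sample(pt$y)
  fold_id <- rep(1:5, length.out = length(pt$y))
  res <- select_permutation(pt$x, y_perm, fold_id, n_keep = 10, seed = 3,
                            ntree = 80)
  expect_lt(mean(res$diagnostics$importance), 0.05)
})

test_that("mutual information separates dependent from independent features", {
  set.seed(12)
  n <- 150
  y <- rep(c("FR", "NR"), length.out = n)
  x <- data.frame(
    informative = ifelse(y == "FR", 1, 0) + rnorm(n, 0, 0.05),
    indep1 = rnorm(n), indep2 = runif(n)
  )
  res <- select_mutual_info(x, y, n_keep = 2, seed = 5)
  expect_length(res$retained, 2)
  expect_equal(res$retained[1], "informative")
  mi <- res$diagnostics
  expect_lt(mi$mi[mi$feature == "indep1"], 0.1)
  expect_gt(mi$mi[mi$feature == "informative"], 0.3)
})

selection_result_stub <- function(feats) {
  structure(list(method = "stub", split_id = NA, retained = feats,
                 diagnostics = NULL), class = "selection_result")
}

test_that("consensus counts trials and applies the inclusive 50% boundary", {
  mk <- function(feats) selection_result_stub(feats)
  # feature "a" in 58 of 116 trials (boundary), "b" in 57, "c" in all
  results <- c(
    replicate(58, mk(c("a", "c")), simplify = FALSE),
    replicate(57, mk(c("b", "c")), simplify = FALSE),
    replicate(1, mk("c"), simplify = FALSE)
  )
  cons <- consensus_features(results, registry = c("a", "b", "c"))
  expect_equal(attr(cons, "n_trials"), 116)
  expect_true("a" %in% cons)
  expect_false("b" %in% cons)
  expect_equal(cons[1], "c") # ordered by descending frequency
})

test_that("all four selectors run on real cohort features", {
  feats <- fixture_small_features()
  x <- impute_features(feats[feature_registry()], feats[feature_registry()])
  fold_id <- as.integer(factor(feats$pig_id)) %% 3 + 1
  sels <- select_all_methods(x, feats$label, fold_id, n_keep = 10, seed = 6,
                             ntree = 60)
  expect_named(sels, c("statistical", "rfe", "permutation", "mutual_info"))
  for (m in c("rfe", "permutation", "mutual_info")) {
    expect_length(sels[[m]]$retained, 10)
    expect_true(all(sels[[m]]$retained %in% feature_registry()))
  }
  expect_true(all(sels$statistical$retained %in% feature_registry()))
  expect_gt(length(sels$statistical$retained), 0)
})
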