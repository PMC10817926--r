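# Holdout evaluation: discrimination, threshold sweeps, calibration,
# aggregation and error analysis.

test_that("AUROC equals the brute-force pairwise-ranking oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- c("FR", "NR", sample(c("FR", "NR"), n - 2, replace = TRUE))
    s <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE) # ties
         else runif(n)
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(runif(5), rep("FR", 5)), "class")
})

test_that("perfect and null scorers bracket the AUROC scale", {
  y <- rep(c("FR", "NR"), each = 100)
  s <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
  rep1 <- evaluate_holdout(s, y)
  expect_equal(rep1$auroc, 1.0)
  expect_equal(rep1$thresholds$accuracy[rep1$thresholds$threshold == 0.5], 1.0)
  set.seed(6)
  y2 <- sample(rep(c("FR", "NR"), each = 1000))
  s2 <- runif(2000)
  expect_lt(abs(auroc(s2, y2) - 0.5), 0.03)
})

test_that("threshold sweep endpoints behave degenerately as they must", {
  set.seed(7)
  y <- sample(rep(c("FR", "NR"), c(30, 20)))
  s <- runif(50, 0.05, 0.95)
  rep1 <- evaluate_holdout(s, y)
  t0 <- rep1$thresholds[rep1$thresholds$threshold == 0, ]
  expect_equal(t0$recall, 1)
  expect_equal(t0$specificity, 0)
  expect_equal(t0$accuracy, mean(y == "FR"))
  t1 <- rep1$thresholds[rep1$thresholds$threshold == 1, ]
  expect_equal(t1$recall, 0)
  expect_equal(t1$specificity, 1)
  expect_equal(t1$accuracy, mean(y == "NR"))
  expect_true(is.na(t1$precision)) # no positive calls at that threshold
})

test_that("AUPRC is at least the prevalence for an informative scorer", {
  set.seed(9)
  y <- rep(c("FR", "NR"), each = 200)
  s <- ifelse(y == "FR", rnorm(400, 0.6, 0.2), rnorm(400, 0.4, 0.2))
  expect_gt(auprc(s, y), mean(y == "FR"))
})

test_that("calibration bins conserve counts and detect a single-point mass", {
  y <- rep(c("FR", "NR"), c(55, 45))
  cal <- calibration_curve(rep(0.55, 100), y)
  expect_equal(sum(cal$count), 100)
  occupied <- cal[cal$count > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$observed_fr, 0.55)
  expect_equal(occupied$mean_predicted, 0.55)
  expect_equal(nrow(cal), 10) # empty bins reported with count 0
  expect_error(calibration_curve(c(-0.1, 0.5), c("FR", "NR")), "0, 1")
})

test_that("aggregation reports means with normal-theory CIs", {
  mk <- function(au) {
    suppressWarnings(evaluate_holdout(
      c(0.8, 0.7, 0.3, 0.2, 0.6, 0.4, 0.55, 0.45, 0.65, 0.35),
      rep(c("FR", "NR"), 5), split_id = au))
  }
  reps <- list(mk(1), mk(2), mk(3))
  agg <- aggregate_splits(reps)
  expect_equal(agg$metrics$ci_half_width[agg$metrics$metric == "auroc"], 0)
  # hand-check the CI closed form on synthetic AUROC values
  reps2 <- reps
  reps2[[1]]$auroc <- 0.8; reps2[[2]]$auroc <- 0.9; reps2[[3]]$auroc <- 0.85
  agg2 <- aggregate_splits(reps2)
  row <- agg2$metrics[agg2$metrics$metric == "auroc", ]
  expect_equal(row$mean, 0.85)
  expect_equal(row$ci_half_width, 1.96 * stats::sd(c(0.8, 0.9, 0.85)) / sqrt(3))
})

test_that("error analysis recovers exact linear relations and flags degeneracy", {
  mk <- function(au) {
    r <- suppressWarnings(evaluate_holdout(
      c(0.8, 0.7, 0.3, 0.2, 0.6, 0.4, 0.55, 0.45, 0.65, 0.35),
      rep(c("FR", "NR"), 5)))
    r$auroc <- au
    r
  }
  reps <- list(mk(0.9), mk(0.8), mk(0.7), mk(0.6))
  meta <- data.frame(grey_zone_prop = c(0.1, 0.2, 0.3, 0.4),
                     shift_fraction = rep(0.2, 4))
  ea <- error_analysis(reps, meta)
  grey <- ea[ea$predictor == "grey_zone_prop", ]
  expect_equal(grey$pearson_r, -1)
  expect_equal(grey$slope, -1)
  expect_true(is.na(ea$pearson_r[ea$predictor == "shift_fraction"]))
})

test_that("identical train/test distributions shift about alpha of features", {
  set.seed(31)
  n_rep <- 40
  fracs <- replicate(n_rep, {
    a <- as.data.frame(matrix(rnorm(100 * 50), ncol = 50))
    b <- as.data.frame(matrix(rnorm(100 * 50), ncol = 50))
    feature_shift_fraction(a, b)
  })
  expect_lt(abs(mean(fracs) - 0.1), 0.04)
})
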