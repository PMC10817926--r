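# Candidate classifiers (random forest as the production model; ridge
# logistic regression, RBF-SVM and gradient boosting as comparators),
# hyperparameter tuning by pig-level cross-validated AUROC, and bundle
# serialization with provenance.

#' Default hyperparameter grids
#'
#' Rows are ordered smallest-capacity first; AUROC ties during tuning resolve
#' to the earliest row (fewest trees / strongest regularization).
#'
#' @return Named list of data.frame grids for `"RF"`, `"LR"`, `"SVM"`, `"GBM"`.
#' @export
default_grids <- function() {
  list(
    RF = expand.grid(ntree = c(100, 300), nodesize = c(5, 1)),
    LR = data.frame(lambda = c(1, 0.1, 0.01, 0.001)),
    SVM = expand.grid(cost = c(0.5, 2, 8), gamma = c(0.01, 0.05, 0.25)),
    GBM = expand.grid(nrounds = c(50, 150), max_depth = c(2, 3), eta = c(0.1, 0.3))
  )
}

fit_algorithm <- function(x, y, algorithm, par, seed) {
  x <- as.data.frame(x)
  y <- as_label_factor(y)
  with_seed(seed, switch(algorithm,
    RF = randomForest::randomForest(x = x, y = y, ntree = par$ntree,
                                    nodesize = par$nodesize),
    LR = glmnet::glmnet(as.matrix(x), y, family = "binomial", alpha = 0,
                        lambda = par$lambda),
    SVM = e1071::svm(x = x, y = y, kernel = "radial", cost = par$cost,
                     gamma = par$gamma, probability = TRUE, scale = TRUE),
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = par$max_depth,
                    eta = par$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x),
                                  label = as.integer(y == "FR")),
      nrounds = par$nrounds, verbose = 0),
    stopf("unknown algorithm: %s", algorithm)))
}

predict_algorithm <- function(fit, algorithm, x) {
  x <- as.data.frame(x)
  switch(algorithm,
    RF = stats::predict(fit, x, type = "prob")[, "FR"],
    LR = as.numeric(stats::predict(fit, as.matrix(x), type = "response")),
    SVM = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "FR"]
    },
    GBM = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))))
}

#' Tune hyperparameters by pig-level CV and fit the final model
#'
#' Grid search maximizing mean fold AUROC over the supplied pig-level folds;
#' ties resolve to the smallest-capacity configuration (earliest grid row).
#' A fold whose held-out part is single-class scores 0.5 with a warning. The
#' winning configuration is refit on the full training split.
#'
#' @param x Training features (restricted to a selection's features).
#' @param y Labels (`"FR"`/`"NR"`).
#' @param fold_id Integer fold id per row (no pig spans folds).
#' @param algorithm `"RF"`, `"LR"`, `"SVM"` or `"GBM"`.
#' @param grid Hyperparameter data.frame (default from [default_grids()]).
#' @param seed Seed.
#' @param selection_method Provenance tag stored in the bundle.
#' @return A `model_bundle`: fitted model, algorithm, `selected_features`,
#'   `hyperparameters`, CV AUROC mean/sd, seed, selection method.
#' @export
tune_and_fit <- function(x, y, fold_id, algorithm = "RF", grid = NULL,
                         seed = 1, selection_method = NA_character_) {
  x <- as.data.frame(x)
  y <- as_label_factor(y)
  if (is.null(grid)) grid <- default_grids()[[algorithm]]
  folds <- sort(unique(fold_id))
  cv_scores <- matrix(NA_real_, nrow = nrow(grid), ncol = length(folds))
  for (g in seq_len(nrow(grid))) {
    for (fi in seq_along(folds)) {
      hold <- fold_id == folds[fi]
      if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2) {
        warning("single-class fold scored as 0.5", call. = FALSE)
        cv_scores[g, fi] <- 0.5
        next
      }
      fit <- fit_algorithm(x[!hold, , drop = FALSE], y[!hold], algorithm,
                           grid[g, , drop = FALSE], derive_seed(seed, g, fi))
      p <- predict_algorithm(fit, algorithm, x[hold, , drop = FALSE])
      cv_scores[g, fi] <- auroc(p, y[hold])
    }
  }
  means <- rowMeans(cv_scores)
  best <- which.max(means) # ties -> earliest (smallest-capacity) row
  final <- fit_algorithm(x, y, algorithm, grid[best, , drop = FALSE],
                         derive_seed(seed, 0L))
  structure(list(
    algorithm = algorithm, fit = final,
    selected_features = names(x),
    hyperparameters = as.list(grid[best, , drop = FALSE]),
    cv_auroc_mean = means[best],
    cv_auroc_sd = stats::sd(cv_scores[best, ]),
    cv_scores = cv_scores, seed = seed,
    selection_method = selection_method
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s on %d features; CV AUROC %.3f +/- %.3f\n",
              x$algorithm, length(x$selected_features),
              x$cv_auroc_mean, x$cv_auroc_sd))
  invisible(x)
}

#' Predict fluid-responsiveness probabilities from a fitted bundle
#'
#' @param bundle A `model_bundle`.
#' @param x Feature table whose columns must match
#'   `bundle$selected_features` exactly (extra columns in a wider table are
#'   subset away; genuinely missing ones raise a schema error).
#' @return Numeric vector of FR probabilities in `[0, 1]`.
#' @export
predict_proba <- function(bundle, x) {
  x <- as.data.frame(x)
  want <- bundle$selected_features
  missing <- setdiff(want, names(x))
  if (length(missing))
    stopf("feature schema mismatch; missing: %s", paste(missing, collapse = ", "))
  p <- predict_algorithm(bundle$fit, bundle$algorithm, x[want])
  pmin(pmax(p, 0), 1)
}

#' Classify probabilities at a decision threshold
#'
#' @param proba FR probabilities.
#' @param threshold Decision threshold (default 0.5); the boundary is
#'   inclusive: probability >= threshold predicts FR.
#' @return Character vector of `"FR"`/`"NR"`.
#' @export
classify_proba <- function(proba, threshold = 0.5) {
  ifelse(proba >= threshold, "FR", "NR")
}

#' Save / load a model bundle with a plain-text provenance sidecar
#'
#' @param bundle A `model_bundle`.
#' @param path Destination `.rds` path; a `<path>.meta.txt` sidecar records
#'   algorithm, features, hyperparameters, CV score and seed so provenance is
#'   inspectable without deserialization.
#' @return `path` (`save_bundle`) or the restored bundle (`load_bundle`).
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  meta <- c(
    sprintf("algorithm: %s", bundle$algorithm),
    sprintf("selection_method: %s", bundle$selection_method),
    sprintf("selected_features: %s", paste(bundle$selected_features, collapse = ",")),
    sprintf("hyperparameters: %s",
            paste(names(bundle$hyperparameters), unlist(bundle$hyperparameters),
                  sep = "=", collapse = ",")),
    sprintf("cv_auroc_mean: %.6f", bundle$cv_auroc_mean),
    sprintf("seed: %s", bundle$seed)
  )
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)
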