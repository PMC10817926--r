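# The four feature-selection methods compared by the pipeline, plus the
# cross-trial consensus rule. All selectors operate on the 50-feature table
# and a binary FR/NR label vector; stochastic selectors take explicit seeds.

as_label_factor <- function(y) {
  y <- factor(y, levels = c("NR", "FR"))
  if (anyNA(y)) stopf("labels must be 'FR' or 'NR'")
  if (nlevels(droplevels(y)) < 2) stopf("need both classes present")
  y
}

selection_result <- function(method, retained, diagnostics, split_id = NA) {
  structure(list(method = method, split_id = split_id,
                 retained = retained, diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s (split %s): %d features\n", x$method,
              as.character(x$split_id), length(x$retained)))
  cat(" ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Statistical feature selection: KS screening plus correlation pruning
#'
#' Per feature, a two-sample Kolmogorov-Smirnov test between the FR and NR
#' distributions retains discriminative features (`p < alpha` under the
#' default `direction = "discriminative"`; `direction = "literal"` applies the
#' opposite `p > alpha` rule). Retained features are then pruned to a fixpoint:
#' while any pair has `|Pearson r| >= corr_threshold`, the member with the
#' larger KS p is dropped (tie: the later one in registry order).
#'
#' @param x Feature data.frame/matrix (columns = features).
#' @param y Labels (`"FR"`/`"NR"`), >= 2 boluses per class.
#' @param alpha KS screening level (default 0.1).
#' @param corr_threshold Correlation pruning threshold (default 0.9).
#' @param direction `"discriminative"` (default) or `"literal"`.
#' @param split_id Bookkeeping tag.
#' @return A `selection_result` (retained in column order, with KS p values in
#'   `diagnostics`).
#' @export
select_statistical <- function(x, y, alpha = 0.1, corr_threshold = 0.9,
                               direction = c("discriminative", "literal"),
                               split_id = NA) {
  direction <- match.arg(direction)
  y <- as_label_factor(y)
  if (min(table(y)) < 2) stopf("need >= 2 boluses per class")
  x <- as.data.frame(x)
  ks_p <- vapply(x, function(v) {
    suppressWarnings(stats::ks.test(v[y == "FR"], v[y == "NR"])$p.value)
  }, numeric(1))
  keep <- if (direction == "discriminative") ks_p < alpha else ks_p > alpha
  retained <- names(x)[keep]
  # correlation pruning to fixpoint
  repeat {
    if (length(retained) < 2) break
    cm <- abs(suppressWarnings(stats::cor(x[retained])))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    pair <- which(cm >= corr_threshold, arr.ind = TRUE)
    if (!nrow(pair)) break
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    a <- retained[pair[1, 1]]; b <- retained[pair[1, 2]]
    # drop the less discriminative member; tie -> the later in registry order
    drop <- if (ks_p[a] > ks_p[b]) a else if (ks_p[b] > ks_p[a]) b else b
    retained <- setdiff(retained, drop)
  }
  selection_result("statistical", retained,
                   data.frame(feature = names(x), ks_p = unname(ks_p),
                              retained = names(x) %in% retained),
                   split_id)
}

rf_fit_quiet <- function(x, y, ntree, seed) {
  with_seed(seed, randomForest::randomForest(x = as.data.frame(x), y = y,
                                             ntree = ntree))
}

#' Recursive feature elimination with a random-forest scorer
#'
#' Repeatedly fits a random forest and removes the single feature with the
#' lowest importance (mean decrease in Gini) until exactly `n_keep` remain.
#'
#' @param x Feature table; `y` labels.
#' @param n_keep Number of features to retain (default 10).
#' @param seed Seed (one substream per elimination round).
#' @param ntree Trees per scoring fit (default 200).
#' @param split_id Bookkeeping tag.
#' @return `selection_result` with retained features ordered by final
#'   importance (descending).
#' @export
select_rfe <- function(x, y, n_keep = 10, seed = 1, ntree = 200, split_id = NA) {
  y <- as_label_factor(y)
  x <- as.data.frame(x)
  if (n_keep > ncol(x)) stopf("n_keep (%d) exceeds available features (%d)",
                              n_keep, ncol(x))
  current <- names(x)
  round <- 0L
  imp <- NULL
  while (length(current) > n_keep) {
    round <- round + 1L
    fit <- rf_fit_quiet(x[current], y, ntree, derive_seed(seed, round))
    imp <- randomForest::importance(fit)[, 1]
    current <- current[current != names(which.min(imp))]
  }
  fit <- rf_fit_quiet(x[current], y, ntree, derive_seed(seed, round + 1L))
  imp <- randomForest::importance(fit)[, 1]
  retained <- names(sort(imp, decreasing = TRUE))
  selection_result("rfe", retained,
                   data.frame(feature = retained, importance = unname(sort(imp, decreasing = TRUE))),
                   split_id)
}

#' Permutation-importance feature selection on held-out folds
#'
#' For each cross-validation fold, fits a random forest on the remaining folds
#' and measures, per feature, the mean held-out AUROC decrease over `n_perm`
#' random permutations of that feature's column. Importances are averaged
#' across folds; the top `n_keep` features are retained (ties broken by
#' registry/column order).
#'
#' @param x Feature table; `y` labels.
#' @param fold_id Integer fold assignment per row (pig-level folds).
#' @param n_keep Number retained (default 10).
#' @param n_perm Permutations per feature per fold (default 10).
#' @param seed Seed; `ntree` trees per fold model.
#' @param ntree Trees per fold model (default 200).
#' @param split_id Bookkeeping tag.
#' @return `selection_result` with mean importances in `diagnostics`.
#' @export
select_permutation <- function(x, y, fold_id, n_keep = 10, n_perm = 10,
                               seed = 1, ntree = 200, split_id = NA) {
  y <- as_label_factor(y)
  x <- as.data.frame(x)
  if (n_keep > ncol(x)) stopf("n_keep (%d) exceeds available features (%d)",
                              n_keep, ncol(x))
  folds <- sort(unique(fold_id))
  imp_mat <- matrix(NA_real_, nrow = ncol(x), ncol = length(folds),
                    dimnames = list(names(x), NULL))
  for (fi in seq_along(folds)) {
    hold <- fold_id == folds[fi]
    if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2) next
    fit <- rf_fit_quiet(x[!hold, ], y[!hold], ntree, derive_seed(seed, fi))
    base_p <- stats::predict(fit, x[hold, ], type = "prob")[, "FR"]
    base_auc <- auroc(base_p, y[hold])
    with_seed(derive_seed(seed, fi, 1L), {
      for (j in seq_len(ncol(x))) {
        drop <- numeric(n_perm)
        xh <- x[hold, ]
        for (r in seq_len(n_perm)) {
          xp <- xh
          xp[[j]] <- sample(xp[[j]])
          pp <- stats::predict(fit, xp, type = "prob")[, "FR"]
          drop[r] <- base_auc - auroc(pp, y[hold])
        }
        imp_mat[j, fi] <- mean(drop)
      }
    })
  }
  imp <- rowMeans(imp_mat, na.rm = TRUE)
  ord <- order(-imp, seq_along(imp)) # ties -> earlier column
  retained <- names(x)[ord[seq_len(n_keep)]]
  selection_result("permutation", retained,
                   data.frame(feature = names(x), importance = unname(imp)),
                   split_id)
}

# Nearest-neighbor mutual information between a continuous feature and a
# discrete label (Ross 2014 estimator): for sample i in class c,
# d_i = distance to its k-th nearest same-class neighbour, m_i = number of
# samples of any class strictly within d_i;
# MI = psi(N) - <psi(N_c)> + psi(k) - <psi(m_i)>. One-dimensional case.
mi_discrete_continuous <- function(v, y, k = 3) {
  n <- length(v)
  classes <- levels(y)
  m_i <- numeric(n)
  k_i <- integer(n)
  ord_all <- sort(v)
  for (cl in classes) {
    idx <- which(y == cl)
    nc <- length(idx)
    kk <- min(k, nc - 1)
    if (kk < 1) return(0)
    vs <- sort(v[idx])
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      d <- sort(abs(vs - v[i]))[kk + 1] # kth neighbour excluding self
      # points of any class strictly within d, self included (the standard
      # nearest-neighbour discrete-continuous estimator's convention)
      m_i[i] <- max(sum(abs(ord_all - v[i]) < d), 1)
      k_i[i] <- kk
    }
  }
  nc_of <- as.numeric(table(y)[as.character(y)])
  mi <- digamma(n) - mean(digamma(nc_of)) + mean(digamma(k_i)) -
    mean(digamma(m_i))
  max(mi, 0)
}

#' Mutual-information feature selection
#'
#' Ranks features by a nearest-neighbor estimate of the mutual information
#' between each feature and the binary label (3rd-neighbour estimator for
#' mixed discrete-continuous variables; a tiny seeded jitter breaks ties in
#' the order statistics). The top `n_keep` are retained, ties broken by
#' column order.
#'
#' @param x Feature table; `y` labels.
#' @param n_keep Number retained (default 10).
#' @param k Neighbour order of the estimator (default 3).
#' @param seed Seed for the tie-breaking jitter.
#' @param split_id Bookkeeping tag.
#' @return `selection_result` with MI estimates in `diagnostics`.
#' @export
select_mutual_info <- function(x, y, n_keep = 10, k = 3, seed = 1,
                               split_id = NA) {
  y <- as_label_factor(y)
  x <- as.data.frame(x)
  if (n_keep > ncol(x)) stopf("n_keep (%d) exceeds available features (%d)",
                              n_keep, ncol(x))
  mi <- with_seed(seed, {
    vapply(x, function(v) {
      s <- stats::sd(v)
      jit <- if (is.finite(s) && s > 0) stats::rnorm(length(v), 0, 1e-10 * s)
             else stats::rnorm(length(v), 0, 1e-12)
      mi_discrete_continuous(v + jit, y, k)
    }, numeric(1))
  })
  ord <- order(-mi, seq_along(mi))
  retained <- names(x)[ord[seq_len(n_keep)]]
  selection_result("mutual_info", retained,
                   data.frame(feature = names(x), mi = unname(mi)),
                   split_id)
}

#' Consensus feature set across selection trials
#'
#' Counts how often each feature was retained across all trials (methods x
#' splits) and keeps those selected in at least `min_frequency` of them
#' (boundary inclusive), ordered by descending frequency then registry order.
#'
#' @param results List of `selection_result` objects.
#' @param min_frequency Minimum selection frequency (default 0.5).
#' @param registry Feature name order used for tie-breaks (default
#'   [feature_registry()]).
#' @return Character vector of consensus features, with the per-feature
#'   frequency table as attribute `"frequency"` and the trial count as
#'   attribute `"n_trials"`.
#' @export
consensus_features <- function(results, min_frequency = 0.5,
                               registry = feature_registry()) {
  if (!length(results)) stopf("need at least one selection result")
  n_trials <- length(results)
  counts <- table(unlist(lapply(results, `[[`, "retained")))
  freq <- stats::setNames(numeric(length(registry)), registry)
  freq[names(counts)[names(counts) %in% registry]] <-
    counts[names(counts) %in% registry] / n_trials
  keep <- names(freq)[freq >= min_frequency]
  keep <- keep[order(-freq[keep], match(keep, registry))]
  structure(keep, frequency = freq, n_trials = n_trials)
}

#' Run all four selection methods on one training split
#'
#' @param x,y Training features and labels.
#' @param fold_id Fold assignment per row (for the permutation method).
#' @param n_keep Features retained by the non-statistical methods.
#' @param seed Seed.
#' @param ntree Trees for forest-based selectors.
#' @param split_id Bookkeeping tag.
#' @return Named list of four `selection_result` objects.
#' @export
select_all_methods <- function(x, y, fold_id, n_keep = 10, seed = 1,
                               ntree = 200, split_id = NA) {
  list(
    statistical = select_statistical(x, y, split_id = split_id),
    rfe = select_rfe(x, y, n_keep, seed = derive_seed(seed, 1L),
                     ntree = ntree, split_id = split_id),
    permutation = select_permutation(x, y, fold_id, n_keep,
                                     seed = derive_seed(seed, 2L),
                                     ntree = ntree, split_id = split_id),
    mutual_info = select_mutual_info(x, y, n_keep,
                                     seed = derive_seed(seed, 3L),
                                     split_id = split_id)
  )
}
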