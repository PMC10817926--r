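# Holdout evaluation: AUROC / AUPRC, threshold sweeps with confusion-matrix
# metrics, calibration deciles, cross-split aggregation with normal-theory
# confidence intervals, and the three error analyses (grey zone, injury mix,
# train/test distribution shift).

#' Area under the ROC curve (trapezoidal rule)
#'
#' Computed by sweeping all distinct score thresholds and integrating TPR over
#' FPR with the trapezoidal rule; with ties this equals the Mann-Whitney
#' probability-of-correct-ranking statistic with half-credit for tied scores.
#'
#' @param scores Numeric predictions (higher = more FR-like).
#' @param labels `"FR"`/`"NR"` vector (or factor).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_label_factor(labels)
  pos <- y == "FR"
  if (!any(pos) || all(pos)) stopf("AUROC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(as.numeric(p), grp, sum))
  fp <- unname(tapply(as.numeric(!p), grp, sum))
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  tpr <- ctp / sum(p); fpr <- cfp / sum(!p)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Area under the precision-recall curve (step-wise interpolation)
#'
#' Average-precision form: the sum over distinct-score thresholds of the
#' recall increment times the precision at that threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_label_factor(labels)
  pos <- y == "FR"
  if (!any(pos) || all(pos)) stopf("AUPRC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(as.numeric(p), grp, sum))
  n_at <- unname(tapply(rep(1, length(p)), grp, sum))
  ctp <- cumsum(tp); cn <- cumsum(n_at)
  recall <- ctp / sum(p); precision <- ctp / cn
  sum(diff(c(0, recall)) * precision)
}

confusion_row <- function(pred_pos, pos) {
  tp <- sum(pred_pos & pos); fp <- sum(pred_pos & !pos)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & !pos)
  data.frame(
    accuracy = (tp + tn) / length(pos),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = tp / (tp + fn),
    specificity = tn / (tn + fp),
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Evaluate predictions on one holdout set
#'
#' Computes AUROC, AUPRC, a threshold sweep of confusion-matrix metrics
#' (positive rule: score >= threshold; undefined cells such as precision with
#' zero positive calls are reported as `NA`, never 0), and, when the scores
#' are probabilities, a calibration table.
#'
#' @param scores Predicted probabilities (or PPV values for the comparator).
#' @param labels `"FR"`/`"NR"` labels; both classes must be present.
#' @param thresholds Decision thresholds to sweep (default deciles 0..1).
#' @param method Tag carried in the report (e.g. `"mlfra_rf"` or `"ppv"`).
#' @param split_id Bookkeeping tag.
#' @return An `evaluation_report`: `auroc`, `auprc`, `thresholds` data.frame,
#'   `calibration` (or `NULL`), `n_test`, `prevalence`, `method`, `split_id`.
#' @export
evaluate_holdout <- function(scores, labels, thresholds = seq(0, 1, by = 0.1),
                             method = "model", split_id = NA) {
  y <- as_label_factor(labels)
  pos <- y == "FR"
  if (!any(pos) || all(pos)) stopf("evaluation undefined: single-class test set")
  if (length(scores) < 10)
    warning("holdout smaller than 10 boluses; metrics will be unstable",
            call. = FALSE)
  sweep <- do.call(rbind, lapply(thresholds, function(t) {
    cbind(threshold = t, confusion_row(scores >= t, pos))
  }))
  calib <- if (all(scores >= 0 & scores <= 1))
    calibration_curve(scores, labels) else NULL
  structure(list(
    method = method, split_id = split_id,
    auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    thresholds = sweep, calibration = calib,
    n_test = length(scores), prevalence = mean(pos)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (split %s): AUROC %.3f, AUPRC %.3f, n=%d\n",
              x$method, as.character(x$split_id), x$auroc, x$auprc, x$n_test))
  invisible(x)
}

#' Calibration curve over fixed-width probability deciles
#'
#' Bins `[0, 0.1), ..., [0.9, 1.0]`; per bin the count, mean predicted
#' probability and observed FR fraction. Empty bins are reported with count 0.
#'
#' @param proba Probabilities in `[0, 1]`.
#' @param labels `"FR"`/`"NR"` labels.
#' @param n_bins Number of fixed-width bins (default 10).
#' @return Data.frame: `bin`, `lower`, `upper`, `count`, `mean_predicted`,
#'   `observed_fr` (`NA` for empty bins).
#' @export
calibration_curve <- function(proba, labels, n_bins = 10) {
  if (any(proba < 0 | proba > 1)) stopf("probabilities must lie in [0, 1]")
  y <- factor(labels, levels = c("NR", "FR"))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(proba, edges, rightmost.closed = TRUE), n_bins)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1],
               count = sum(sel),
               mean_predicted = if (any(sel)) mean(proba[sel]) else NA_real_,
               observed_fr = if (any(sel)) mean(y[sel] == "FR") else NA_real_)
  }))
  out
}

#' Aggregate evaluation reports across splits
#'
#' Per metric, the mean and the normal-approximation 95% CI half-width
#' `1.96 * SD / sqrt(n)` over splits, computed over defined values only; plus
#' the threshold sweep averaged across splits (a metric undefined in a split,
#' e.g. precision with no positive calls, is skipped for that split and the
#' average is flagged `NA` when undefined everywhere).
#'
#' @param reports List of `evaluation_report` objects (>= 2).
#' @return List with `metrics` (data.frame: metric, mean, ci_half_width, n)
#'   and `thresholds` (averaged sweep with CI half-widths).
#' @export
aggregate_splits <- function(reports) {
  if (length(reports) < 2) stopf("need >= 2 reports to aggregate")
  ci <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, 0))
    c(mean(v), if (length(v) > 1) 1.96 * stats::sd(v) / sqrt(length(v)) else 0,
      length(v))
  }
  top <- sapply(c("auroc", "auprc"), function(m)
    ci(vapply(reports, `[[`, numeric(1), m)))
  metrics <- data.frame(metric = colnames(top), mean = top[1, ],
                        ci_half_width = top[2, ], n = top[3, ])
  rownames(metrics) <- NULL
  thr <- reports[[1]]$thresholds$threshold
  cols <- c("accuracy", "precision", "recall", "specificity", "npv")
  sweep <- do.call(rbind, lapply(seq_along(thr), function(i) {
    row <- data.frame(threshold = thr[i])
    for (cn in cols) {
      v <- vapply(reports, function(r) r$thresholds[[cn]][i], numeric(1))
      s <- ci(v)
      row[[cn]] <- s[1]; row[[paste0(cn, "_ci")]] <- s[2]
    }
    row
  }))
  list(metrics = metrics, thresholds = sweep)
}

#' Fraction of features with shifted train/test distributions
#'
#' Per feature, a two-sample KS test between the training and test columns;
#' returns the fraction with `p < alpha` (the same discriminative-direction
#' policy as statistical feature selection).
#'
#' @param train_x,test_x Feature tables over the same columns.
#' @param alpha KS level (default 0.1).
#' @return Fraction in `[0, 1]`.
#' @export
feature_shift_fraction <- function(train_x, test_x, alpha = 0.1) {
  cols <- intersect(names(as.data.frame(train_x)), names(as.data.frame(test_x)))
  ps <- vapply(cols, function(cn) {
    a <- as.numeric(train_x[[cn]]); a <- a[is.finite(a)]
    b <- as.numeric(test_x[[cn]]); b <- b[is.finite(b)]
    if (length(a) < 3 || length(b) < 3) return(NA_real_)
    suppressWarnings(stats::ks.test(a, b)$p.value)
  }, numeric(1))
  mean(ps < alpha, na.rm = TRUE)
}

#' Error analysis: regress per-split AUROC on candidate difficulty factors
#'
#' For each predictor (grey-zone bolus proportion, per-injury-model
#' proportions, train/test feature shift fraction), fits a least-squares line
#' of holdout AUROC on the predictor across splits and reports slope,
#' intercept and the Pearson correlation (`NA` with a zero-variance
#' predictor).
#'
#' @param reports List of `evaluation_report` objects (>= 3 splits).
#' @param split_meta Data.frame with one row per report: any of
#'   `grey_zone_prop`, `prop_HEM`, `prop_IRI`, `prop_EPACC`, `shift_fraction`.
#' @return Data.frame: `predictor`, `slope`, `intercept`, `pearson_r`, `n`.
#' @export
error_analysis <- function(reports, split_meta) {
  if (length(reports) < 3) stopf("need >= 3 splits for error analysis")
  au <- vapply(reports, `[[`, numeric(1), "auroc")
  preds <- intersect(c("grey_zone_prop", "prop_HEM", "prop_IRI", "prop_EPACC",
                       "shift_fraction"), names(split_meta))
  do.call(rbind, lapply(preds, function(pn) {
    v <- split_meta[[pn]]
    if (stats::sd(v) == 0 || stats::sd(au) == 0) {
      return(data.frame(predictor = pn, slope = NA_real_, intercept = NA_real_,
                        pearson_r = NA_real_, n = length(v)))
    }
    fit <- stats::lm(au ~ v)
    data.frame(predictor = pn, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               pearson_r = stats::cor(v, au), n = length(v))
  }))
}
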