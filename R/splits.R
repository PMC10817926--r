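# Pig-level stratified train/test splitting (no bolus-level leakage) and
# pig-level stratified cross-validation fold assignment.

split_score <- function(pigs, train_ids, target, lambda_injury) {
  tr <- pigs$pig_id %in% train_ids
  prev <- function(sel) {
    nb <- sum(pigs$n_boluses[sel])
    if (nb == 0) return(NA_real_)
    sum(pigs$n_fr[sel]) / nb
  }
  p_tr <- prev(tr); p_te <- prev(!tr)
  mix <- function(sel) {
    tab <- tapply(pigs$n_boluses[sel], factor(pigs$injury_model[sel],
                                              levels = unique(pigs$injury_model)),
                  sum, default = 0)
    tab / sum(tab)
  }
  imbalance <- 0.5 * sum(abs(mix(tr) - mix(!tr)))
  abs(p_tr - target) + abs(p_te - target) + lambda_injury * imbalance
}

#' Generate stratified pig-level train/test splits
#'
#' For each of `n_splits` splits, draws `n_candidates` random half-partitions
#' of the pigs and keeps the one minimizing
#' `|prev_train - target| + |prev_test - target| + lambda * injury-mix imbalance`
#' (ties broken by lower candidate index). Prevalences are bolus-weighted.
#' With an odd pig count the extra pig goes to training. Split `s` uses seed
#' `seed + s`, so individual splits are reproducible in isolation.
#'
#' @param pigs Pig label table: columns `pig_id`, `injury_model`, `n_boluses`,
#'   `n_fr` (see [pig_label_table()]). Every pig needs >= 1 bolus.
#' @param n_splits Number of splits (default 29).
#' @param target_prevalence Target FR prevalence on both sides (default 0.5).
#' @param seed Master seed.
#' @param n_candidates Candidate partitions scored per split (default 200).
#' @param lambda_injury Weight of the injury-mix imbalance term (default 0.25).
#' @return List of `split_plan` objects: `split_id`, `train_pigs`,
#'   `test_pigs`, `seed`, realized `fr_prevalence_train/test`,
#'   `injury_mix_train/test`, `score`.
#' @export
make_splits <- function(pigs, n_splits = 29, target_prevalence = 0.5, seed = 1,
                        n_candidates = 200, lambda_injury = 0.25) {
  if (n_splits < 1) stopf("n_splits must be >= 1")
  if (nrow(pigs) < 4) stopf("need at least 4 pigs to split")
  if (any(pigs$n_boluses < 1)) stopf("every pig needs at least one labeled bolus")
  n <- nrow(pigs)
  n_test <- n %/% 2          # odd pig counts: the extra pig trains
  lapply(seq_len(n_splits), function(s) {
    split_seed <- seed + s
    best <- with_seed(split_seed, {
      best_score <- Inf; best_train <- NULL
      for (cand in seq_len(n_candidates)) {
        te <- sample(pigs$pig_id, n_test)
        tr <- setdiff(pigs$pig_id, te)
        sc <- split_score(pigs, tr, target_prevalence, lambda_injury)
        if (is.finite(sc) && sc < best_score) { # strict: ties keep lower index
          best_score <- sc; best_train <- tr
        }
      }
      list(train = best_train, score = best_score)
    })
    tr <- pigs$pig_id %in% best$train
    prev <- function(sel) sum(pigs$n_fr[sel]) / sum(pigs$n_boluses[sel])
    mix <- function(sel) {
      tab <- tapply(pigs$n_boluses[sel],
                    factor(pigs$injury_model, levels = unique(pigs$injury_model))[sel],
                    sum, default = 0)
      tab / sum(tab)
    }
    structure(list(
      split_id = s, train_pigs = sort(best$train),
      test_pigs = sort(setdiff(pigs$pig_id, best$train)),
      seed = split_seed, score = best$score,
      fr_prevalence_train = prev(tr), fr_prevalence_test = prev(!tr),
      injury_mix_train = mix(tr), injury_mix_test = mix(!tr)
    ), class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %d> %d train / %d test pigs; FR prev %.2f / %.2f\n",
              x$split_id, length(x$train_pigs), length(x$test_pigs),
              x$fr_prevalence_train, x$fr_prevalence_test))
  invisible(x)
}

#' Assign training pigs of a split to cross-validation folds
#'
#' Greedy stratified allocation: pigs are ordered by bolus count (descending;
#' equal counts shuffled by `seed`) and each is assigned to the fold that
#' minimizes the post-assignment deviation of fold FR and NR counts from their
#' per-fold targets, then fold size, ties to the lowest fold index. Boluses of
#' one pig never span folds.
#'
#' @param plan A `split_plan`.
#' @param pigs Pig label table (as for [make_splits()]).
#' @param k Number of folds (default 5).
#' @param seed Seed for the tie-shuffle.
#' @return A `fold_plan`: data.frame with `pig_id`, `fold` (1..k), plus
#'   attribute `split_id`.
#' @export
make_cv_folds <- function(plan, pigs, k = 5, seed = 1) {
  tp <- pigs[pigs$pig_id %in% plan$train_pigs, , drop = FALSE]
  if (nrow(tp) < k) stopf("fewer training pigs (%d) than folds (%d)", nrow(tp), k)
  ord <- with_seed(seed, {
    jitter_rank <- sample(nrow(tp))
    order(-tp$n_boluses, jitter_rank)
  })
  tp <- tp[ord, , drop = FALSE]
  cap <- ceiling(nrow(tp) / k) # pig-count cap keeps fold sizes maximally even
  fold_fr <- numeric(k); fold_nr <- numeric(k); fold_n <- numeric(k)
  fold_pigs <- integer(k)
  assign_fold <- integer(nrow(tp))
  spread <- function(v) max(v) - min(v)
  for (i in seq_len(nrow(tp))) {
    fr <- tp$n_fr[i]; nr <- tp$n_boluses[i] - fr
    open <- which(fold_pigs < cap)
    # among folds with room: minimize the cross-fold spread of FR and NR
    # bolus counts after the assignment, then bolus-count spread, then index
    score <- vapply(open, function(f) {
      a <- fold_fr; b <- fold_nr
      a[f] <- a[f] + fr; b[f] <- b[f] + nr
      spread(a) + spread(b)
    }, numeric(1))
    best <- open[score == min(score)]
    if (length(best) > 1) {
      sz_score <- vapply(best, function(f) {
        n2 <- fold_n; n2[f] <- n2[f] + fr + nr; spread(n2)
      }, numeric(1))
      best <- best[sz_score == min(sz_score)]
    }
    f <- best[1]
    assign_fold[i] <- f
    fold_fr[f] <- fold_fr[f] + fr; fold_nr[f] <- fold_nr[f] + nr
    fold_n[f] <- fold_n[f] + fr + nr
    fold_pigs[f] <- fold_pigs[f] + 1L
  }
  out <- data.frame(pig_id = tp$pig_id, fold = assign_fold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pig_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "split_id") <- plan$split_id
  class(out) <- c("fold_plan", "data.frame")
  out
}

#' Serialize split and fold plans to a long-format table
#'
#' @param splits List of `split_plan` objects.
#' @param folds Optional list of `fold_plan` objects aligned with `splits`.
#' @return Data.frame with `split_id`, `pig_id`, `role` (train/test), `fold`
#'   (`NA` for test pigs); sufficient to reproduce an experiment exactly.
#' @export
splits_to_table <- function(splits, folds = NULL) {
  do.call(rbind, lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    df <- data.frame(
      split_id = sp$split_id,
      pig_id = c(sp$train_pigs, sp$test_pigs),
      role = rep(c("train", "test"),
                 c(length(sp$train_pigs), length(sp$test_pigs))),
      fold = NA_integer_, stringsAsFactors = FALSE)
    if (!is.null(folds)) {
      fp <- folds[[i]]
      df$fold <- fp$fold[match(df$pig_id, fp$pig_id)]
    }
    df
  }))
}
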