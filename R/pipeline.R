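# End-to-end orchestration with a single config object holding every numeric
# constant of the pipeline, stage-wise artifact files, and seeded determinism.

#' Default pipeline configuration
#'
#' Every tunable constant of the pipeline appears here exactly once:
#' simulator conditions, preprocessing (1000 -> 100 Hz, Savitzky-Golay window
#' 19 / order 2), detector constants, selection settings (KS alpha 0.1,
#' correlation 0.9, 10 features, consensus 0.5), split settings (29 splits,
#' k = 5 folds, target prevalence 0.5), model grids, and decision thresholds
#' (FR at 15% delta-SV, grey zone 10-20%, PPV at 12%, model at 0.5). The
#' config round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    simulator = list(n_pigs = 58, boluses_per_pig = 6.8,
                     fr_prevalence_target = 0.5),
    preprocess = list(source_rate_hz = 1000, analysis_rate_hz = 100,
                      sg_window = 19, sg_polyorder = 2),
    detector = list(min_distance_s = 0.3, prominence_frac = 0.25,
                    notch_window = c(0.1, 0.5)),
    beat_filter = list(period_range = c(0.3, 1.5), min_pp_mmhg = 5,
                       rel_period_max = 1.5),
    labeling = list(fr_threshold_pct = 15, grey_zone_pct = c(10, 20)),
    ppv = list(threshold_pct = 12),
    splits = list(n_splits = 29, target_prevalence = 0.5, n_candidates = 200,
                  lambda_injury = 0.25, k_folds = 5),
    selection = list(alpha = 0.1, corr_threshold = 0.9, n_keep = 10,
                     consensus_min_frequency = 0.5, ntree = 200),
    model = list(algorithm = "RF", decision_threshold = 0.5),
    evaluation = list(thresholds = seq(0, 1, by = 0.1), n_bins = 10)
  )
}

#' Write / read a pipeline config as YAML
#' @param config Nested config list.
#' @param path YAML file path.
#' @return `path` / the config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

# Short stable fingerprint of a config (polynomial rolling hash over its
# deparsed form, modulo a Mersenne prime).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_log <- function(dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE)
}

#' Run the full pipeline (or a subset of stages)
#'
#' Stages: `simulate` (cohort directory), `featurize` (preprocess, detect
#' beats, 50 features, PPV, stroke-volume labels -> `features.csv`), `split`
#' (pig-level splits and folds -> `splits.csv`), `select` (four selection
#' methods per split -> `selection.csv`), `train` (one model bundle per split
#' under `models/`), `evaluate` (holdout reports, aggregate summary,
#' threshold sweep, calibration, error analysis -> delimited text). Each
#' stage reads its predecessor's artifact from `out_dir`, so stages can be
#' rerun independently; a missing upstream artifact is an error naming the
#' file. Reruns with the same config and seed are deterministic.
#'
#' @param config Config list (see [default_config()]).
#' @param out_dir Artifact directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "featurize", "split", "select", "train", "evaluate")`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "featurize", "split",
                                    "select", "train", "evaluate")) {
  all_stages <- c("simulate", "featurize", "split", "select", "train", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  hash <- config_hash(config)
  need <- function(path) {
    if (!file.exists(path)) stopf("missing upstream artifact: %s", path)
    path
  }
  seed <- config$seed

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(config$simulator$n_pigs,
                              config$simulator$boluses_per_pig,
                              config$simulator$fr_prevalence_target, seed)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    pipeline_log(out_dir, "simulate",
                 sprintf("config %s: %d pigs, %d boluses", hash,
                         nrow(cohort$profiles), length(cohort$boluses)))
  }
  if ("featurize" %in% stages) {
    cohort <- read_cohort(need(file.path(out_dir, "cohort", "manifest.csv")) |>
                            dirname())
    features <- featurize_cohort(cohort)
    features$config_hash <- hash
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    pipeline_log(out_dir, "featurize", sprintf("%d boluses featurized", nrow(features)))
  }
  if ("split" %in% stages) {
    features <- utils::read.csv(need(file.path(out_dir, "features.csv")),
                                stringsAsFactors = FALSE)
    pigs <- pig_label_table(features)
    splits <- make_splits(pigs, config$splits$n_splits,
                          config$splits$target_prevalence, seed,
                          config$splits$n_candidates,
                          config$splits$lambda_injury)
    folds <- lapply(splits, function(sp)
      make_cv_folds(sp, pigs, config$splits$k_folds, seed + sp$split_id))
    utils::write.csv(splits_to_table(splits, folds),
                     file.path(out_dir, "splits.csv"), row.names = FALSE)
    pipeline_log(out_dir, "split", sprintf("%d splits over %d pigs",
                                           length(splits), nrow(pigs)))
  }
  if ("select" %in% stages || "train" %in% stages || "evaluate" %in% stages) {
    features <- utils::read.csv(need(file.path(out_dir, "features.csv")),
                                stringsAsFactors = FALSE)
    split_tab <- utils::read.csv(need(file.path(out_dir, "splits.csv")),
                                 stringsAsFactors = FALSE)
  }
  if ("select" %in% stages) {
    sel_rows <- list()
    for (s in unique(split_tab$split_id)) {
      d <- training_view(features, split_tab, s)
      sel <- select_all_methods(d$x, d$y, d$fold, config$selection$n_keep,
                                seed = derive_seed(seed, s, 77L),
                                ntree = config$selection$ntree, split_id = s)
      for (r in sel) {
        sel_rows[[length(sel_rows) + 1L]] <-
          data.frame(split_id = s, method = r$method,
                     feature = r$retained, rank = seq_along(r$retained),
                     stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, sel_rows),
                     file.path(out_dir, "selection.csv"), row.names = FALSE)
    pipeline_log(out_dir, "select",
                 sprintf("%d selection trials", length(sel_rows)))
  }
  if ("train" %in% stages) {
    sel_tab <- utils::read.csv(need(file.path(out_dir, "selection.csv")),
                               stringsAsFactors = FALSE)
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (s in unique(split_tab$split_id)) {
      d <- training_view(features, split_tab, s)
      feats <- sel_tab$feature[sel_tab$split_id == s & sel_tab$method == "rfe"]
      bundle <- tune_and_fit(d$x[feats], d$y, d$fold,
                             config$model$algorithm,
                             seed = derive_seed(seed, s, 88L),
                             selection_method = "rfe")
      save_bundle(bundle, file.path(out_dir, "models",
                                    sprintf("split%02d.rds", s)))
    }
    pipeline_log(out_dir, "train",
                 sprintf("%d bundles trained", length(unique(split_tab$split_id))))
  }
  if ("evaluate" %in% stages) {
    reports <- list(); ppv_reports <- list(); meta <- list()
    for (s in unique(split_tab$split_id)) {
      bundle <- load_bundle(need(file.path(out_dir, "models",
                                           sprintf("split%02d.rds", s))))
      d <- holdout_view(features, split_tab, s)
      dt <- training_view(features, split_tab, s)
      proba <- predict_proba(bundle, impute_features(d$x, dt$x))
      reports[[s]] <- evaluate_holdout(proba, d$y,
                                       config$evaluation$thresholds,
                                       method = "mlfra_rf", split_id = s)
      ppv_reports[[s]] <- evaluate_holdout(d$ppv / 100, d$y,
                                           config$evaluation$thresholds,
                                           method = "ppv", split_id = s)
      meta[[s]] <- data.frame(
        split_id = s,
        grey_zone_prop = mean(d$zone == "grey"),
        prop_HEM = mean(d$injury == "HEM"),
        prop_IRI = mean(d$injury == "IRI"),
        prop_EPACC = mean(d$injury == "EPACC"),
        shift_fraction = feature_shift_fraction(dt$x, d$x,
                                                config$selection$alpha))
    }
    agg <- aggregate_splits(reports)
    utils::write.csv(agg$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(agg$thresholds, file.path(out_dir, "threshold_sweep.csv"),
                     row.names = FALSE)
    if (length(reports) >= 3) {
      ea <- error_analysis(reports, do.call(rbind, meta))
      utils::write.csv(ea, file.path(out_dir, "error_analysis.csv"),
                       row.names = FALSE)
    }
    per_split <- data.frame(
      split_id = vapply(reports, `[[`, numeric(1), "split_id"),
      mlfra_auroc = vapply(reports, `[[`, numeric(1), "auroc"),
      ppv_auroc = vapply(ppv_reports, `[[`, numeric(1), "auroc"))
    utils::write.csv(per_split, file.path(out_dir, "per_split_auroc.csv"),
                     row.names = FALSE)
    pipeline_log(out_dir, "evaluate",
                 sprintf("mean MLFRA AUROC %.3f vs PPV %.3f",
                         mean(per_split$mlfra_auroc), mean(per_split$ppv_auroc)))
  }
  invisible(out_dir)
}

# Internal views of the labeled feature table restricted to one side of a
# split; features returned as the 50 registry columns, imputed from the
# training side only.
training_view <- function(features, split_tab, s) {
  st <- split_tab[split_tab$split_id == s, ]
  train_pigs <- st$pig_id[st$role == "train"]
  d <- features[features$pig_id %in% train_pigs, ]
  x <- impute_features(d[feature_registry()], d[feature_registry()])
  fold <- st$fold[match(d$pig_id, st$pig_id)]
  list(x = x, y = d$label, fold = fold, ppv = d$ppv_pct,
       zone = d$sv_zone, injury = d$injury_model)
}

holdout_view <- function(features, split_tab, s) {
  st <- split_tab[split_tab$split_id == s, ]
  test_pigs <- st$pig_id[st$role == "test"]
  d <- features[features$pig_id %in% test_pigs, ]
  list(x = d[feature_registry()], y = d$label, ppv = d$ppv_pct,
       zone = d$sv_zone, injury = d$injury_model)
}
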