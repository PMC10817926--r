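# Per-beat physiologic features of the arterial pressure waveform, their
# median/SD aggregation over the 60 s pre-bolus window (the 50-feature
# vector), and the pulse pressure variation comparator.

# The fixed registry of 25 per-beat base features. This vector is the single
# source of truth for feature names and order; the 50-feature vector is
# median and SD of each, interleaved (<name>_median, <name>_sd).
base_feature_names <- c(
  "sbp",                # systolic pressure (peak)
  "dbp",                # diastolic pressure (foot)
  "notch_p",            # dicrotic notch pressure
  "pp",                 # pulse pressure
  "map_beat",           # mean pressure over the beat
  "period",             # beat period (s)
  "hr_inst",            # instantaneous heart rate 60/period
  "rise_time",          # foot -> peak (s)
  "systolic_duration",  # foot -> notch (s)
  "diastolic_duration", # notch -> next foot (s)
  "sys_dia_ratio",      # systolic / diastolic duration
  "dpdt_max",           # max dP/dt over the beat
  "dpdt_min",           # min dP/dt over the beat
  "area_systolic",      # integral above DBP, foot -> notch
  "area_diastolic",     # integral above DBP, notch -> next foot
  "area_total",         # integral above DBP, foot -> next foot
  "area_sys_frac",      # systolic / total area
  "notch_rel_height",   # (notch - DBP) / pulse pressure
  "peak_notch_amp",     # peak - notch pressure
  "tau_decay",          # diastolic decay time constant (s)
  "peak_notch_time",    # peak -> notch (s)
  "sd_within",          # within-beat pressure SD
  "skew_within",        # within-beat pressure skewness
  "pulse_width_half",   # width at half pulse amplitude (s)
  "dia_slope_mean"      # mean diastolic dP/dt
)

# Base features that require a valid dicrotic notch.
notch_feature_names <- c(
  "notch_p", "systolic_duration", "diastolic_duration", "sys_dia_ratio",
  "area_systolic", "area_diastolic", "area_sys_frac", "notch_rel_height",
  "peak_notch_amp", "tau_decay", "peak_notch_time", "dia_slope_mean"
)

#' The 50-feature registry
#'
#' @return Character vector of the 50 aggregated feature names in canonical
#'   order: for each of the 25 per-beat base features, its across-beat median
#'   then its across-beat standard deviation.
#' @export
feature_registry <- function() {
  as.vector(rbind(paste0(base_feature_names, "_median"),
                  paste0(base_feature_names, "_sd")))
}

# Diastolic decay time constant by least-squares fit of the exponential decay
# ODE: regress dP/dt on P; slope = -1/tau, invariant to the (unknown)
# pressure asymptote. Returns NA for non-decaying or degenerate windows.
fit_decay_tau <- function(p_seg, fs) {
  n <- length(p_seg)
  if (n < 5) return(NA_real_)
  dpdt <- (p_seg[3:n] - p_seg[1:(n - 2)]) * fs / 2
  pm <- p_seg[2:(n - 1)]
  vp <- stats::var(pm)
  if (!is.finite(vp) || vp <= 0) return(NA_real_)
  slope <- stats::cov(pm, dpdt) / vp
  if (!is.finite(slope) || slope >= -1e-8) return(NA_real_)
  -1 / slope
}

#' Compute the 25 per-beat base features
#'
#' @param beat One row of a `beat_fiducials` data.frame (quality-filtered).
#' @param seg The preprocessed ABP `waveform_segment` the beat was detected in.
#' @return Named numeric vector of length 25; notch-dependent entries are `NA`
#'   when the beat's notch detection failed.
#' @export
compute_beat_features <- function(beat, seg) {
  x <- seg$samples
  fs <- seg$sample_rate_hz
  foot <- beat$foot_idx; peak <- beat$peak_idx; nxt <- beat$next_foot_idx
  period <- beat$period_s
  if (!is.finite(period) || period <= 0) stopf("degenerate beat: period <= 0")
  dbp <- x[foot]; sbp <- x[peak]; pp <- sbp - dbp
  seg_beat <- x[foot:nxt]
  dpdt <- diff(seg_beat) * fs
  dt <- 1 / fs
  out <- stats::setNames(rep(NA_real_, length(base_feature_names)),
                         base_feature_names)
  out["sbp"] <- sbp
  out["dbp"] <- dbp
  out["pp"] <- pp
  out["map_beat"] <- mean(seg_beat)
  out["period"] <- period
  out["hr_inst"] <- 60 / period
  out["rise_time"] <- (peak - foot) / fs
  out["dpdt_max"] <- max(dpdt)
  out["dpdt_min"] <- min(dpdt)
  out["area_total"] <- trapz_uniform(seg_beat - dbp, dt)
  out["sd_within"] <- stats::sd(seg_beat)
  out["skew_within"] <- sample_skewness(seg_beat)
  half_level <- dbp + pp / 2
  out["pulse_width_half"] <- sum(seg_beat >= half_level) * dt
  if (isTRUE(beat$notch_ok)) {
    notch <- beat$notch_idx
    notch_p <- x[notch]
    out["notch_p"] <- notch_p
    out["systolic_duration"] <- (notch - foot) / fs
    out["diastolic_duration"] <- (nxt - notch) / fs
    out["sys_dia_ratio"] <- out["systolic_duration"] / out["diastolic_duration"]
    out["area_systolic"] <- trapz_uniform(x[foot:notch] - dbp, dt)
    out["area_diastolic"] <- trapz_uniform(x[notch:nxt] - dbp, dt)
    out["area_sys_frac"] <- if (out["area_total"] > 0)
      out["area_systolic"] / out["area_total"] else NA_real_
    out["notch_rel_height"] <- (notch_p - dbp) / pp
    out["peak_notch_amp"] <- sbp - notch_p
    out["peak_notch_time"] <- (notch - peak) / fs
    dia <- x[notch:nxt]
    # fit the decay constant on the diastolic runoff, starting just past the
    # dicrotic crest (the maximum after the notch)
    crest <- which.max(dia)
    start_i <- min(crest + 2L, length(dia))
    stop_i <- length(dia) - ceiling(0.1 * length(dia))
    out["tau_decay"] <- if (stop_i - start_i >= 5)
      fit_decay_tau(dia[start_i:stop_i], fs) else NA_real_
    out["dia_slope_mean"] <- mean(diff(dia) * fs)
  }
  out
}

#' Aggregate per-beat features into the 50-feature pre-bolus vector
#'
#' Computes the median and sample standard deviation (n - 1 denominator) of
#' each of the 25 base features across all quality-filtered beats in the
#' window, skipping `NA` beats per feature. A notch-dependent feature with
#' fewer than 3 non-missing beats yields `NA` median/SD entries (to be imputed
#' downstream with training-cohort medians, never test statistics).
#'
#' @param beats Quality-filtered `beat_fiducials` (>= 3 beats).
#' @param seg The preprocessed ABP segment.
#' @param bolus_id,pig_id Identifiers carried into the output row.
#' @return One-row data.frame: ids, the 50 features in registry order,
#'   `ppv_pct`, `n_beats_used`.
#' @export
aggregate_features <- function(beats, seg, bolus_id = NA_character_,
                               pig_id = NA_character_) {
  if (nrow(beats) < 3) stopf("insufficient beats: need >= 3, have %d", nrow(beats))
  mat <- vapply(seq_len(nrow(beats)),
                function(k) compute_beat_features(beats[k, ], seg),
                numeric(length(base_feature_names)))
  vals <- stats::setNames(rep(NA_real_, 50), feature_registry())
  for (f in base_feature_names) {
    v <- mat[f, ]
    v <- v[is.finite(v)]
    if (length(v) >= 3) {
      vals[paste0(f, "_median")] <- stats::median(v)
      vals[paste0(f, "_sd")] <- stats::sd(v)
    }
  }
  out <- data.frame(bolus_id = bolus_id, pig_id = pig_id,
                    stringsAsFactors = FALSE)
  out[names(vals)] <- as.list(vals)
  out$ppv_pct <- compute_ppv(beats)
  out$n_beats_used <- nrow(beats)
  out
}

#' Pulse pressure variation over a beat window
#'
#' PPV% = 100 (PPmax - PPmin) / ((PPmax + PPmin) / 2), with the extrema taken
#' over all quality-filtered beats in the window (the literal monitor-free
#' formula; no per-respiratory-cycle averaging).
#'
#' @param beats Quality-filtered `beat_fiducials` (>= 3 beats with valid PP).
#' @return PPV in percent (>= 0).
#' @export
compute_ppv <- function(beats) {
  pp <- beats$pulse_pressure
  pp <- pp[is.finite(pp)]
  if (length(pp) < 3) stopf("insufficient beats for PPV: need >= 3 pulse pressures")
  ppmax <- max(pp); ppmin <- min(pp)
  denom <- (ppmax + ppmin) / 2
  if (denom == 0) stopf("PPV undefined: PPmax + PPmin = 0")
  100 * (ppmax - ppmin) / denom
}

#' Classify fluid responsiveness from PPV
#'
#' @param ppv_pct PPV in percent.
#' @param threshold_pct Decision threshold (default 12; the boundary is
#'   inclusive, PPV >= threshold predicts responsiveness).
#' @return `"FR"` or `"NR"`.
#' @export
classify_ppv <- function(ppv_pct, threshold_pct = 12) {
  if (!is.finite(ppv_pct)) stopf("ppv_pct must be finite")
  ifelse(ppv_pct >= threshold_pct, "FR", "NR")
}

#' Extract the feature vector for one bolus from its raw pre-bolus ABP
#'
#' Runs the full chain: preprocess (decimate + smooth), detect beats, quality
#' filter, aggregate. Convenience wrapper used by the pipeline.
#'
#' @param abp_pre Raw ABP `waveform_segment` (e.g. 1000 Hz).
#' @param bolus_id,pig_id Identifiers.
#' @param analysis_rate_hz,window,polyorder Preprocessing settings.
#' @return One-row feature data.frame as from [aggregate_features()].
#' @export
featurize_bolus <- function(abp_pre, bolus_id = NA_character_,
                            pig_id = NA_character_, analysis_rate_hz = 100,
                            window = 19, polyorder = 2) {
  seg <- preprocess_segment(abp_pre, analysis_rate_hz, window, polyorder)
  beats <- beat_quality_filter(detect_beats(seg))
  aggregate_features(beats, seg, bolus_id, pig_id)
}

#' Build the labeled feature table for a simulated cohort
#'
#' One row per bolus: identifiers, the 50 features, PPV, beat count, measured
#' stroke volumes and the fluid-responsiveness label derived from the CO and
#' HR channels.
#'
#' @param cohort A `sim_cohort`.
#' @return Data.frame with features plus `sv_pre_ml`, `sv_post_ml`,
#'   `delta_sv_pct`, `label`, `sv_zone`, `injury_model`, `phase`.
#' @export
featurize_cohort <- function(cohort) {
  rows <- lapply(cohort$boluses, function(b) {
    feats <- featurize_bolus(b$abp_pre, b$bolus_id, b$pig_id)
    lab <- label_bolus(compute_sv(b$co_pre, b$hr_pre),
                       compute_sv(b$co_post, b$hr_post))
    feats$sv_pre_ml <- lab$sv_pre_ml
    feats$sv_post_ml <- lab$sv_post_ml
    feats$delta_sv_pct <- lab$delta_sv_pct
    feats$label <- lab$label
    feats$sv_zone <- lab$sv_zone
    feats$injury_model <- b$injury_model
    feats$phase <- b$phase %||% NA_character_
    feats
  })
  do.call(rbind, rows)
}

#' Impute missing feature values with reference (training) medians
#'
#' @param x Feature data.frame (rows = boluses) containing the 50 registry
#'   columns, possibly with `NA` from rare notch-detection failures.
#' @param reference Either a feature data.frame to take medians from (the
#'   training cohort) or a named numeric vector of medians.
#' @return `x` with `NA` registry entries replaced.
#' @export
impute_features <- function(x, reference) {
  cols <- feature_registry()
  med <- if (is.data.frame(reference)) {
    vapply(cols, function(cn) stats::median(reference[[cn]], na.rm = TRUE),
           numeric(1))
  } else reference[cols]
  for (cn in cols) {
    miss <- !is.finite(x[[cn]])
    if (any(miss)) {
      fill <- med[[cn]]
      if (!is.finite(fill)) fill <- 0 # feature absent in the whole cohort
      x[[cn]][miss] <- fill
    }
  }
  x
}
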