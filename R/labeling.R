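# Stroke-volume derivation from the cardiac output and heart rate channels,
# and fluid-responsiveness labeling with the grey-zone partition.

#' Stroke volume from cardiac output and heart rate segments
#'
#' SV (ml) = median CO (L/min) / median HR (bpm) x 1000, both medians taken
#' over the same 60 s measurement window.
#'
#' @param co_seg Cardiac output `waveform_segment` (L/min).
#' @param hr_seg Heart rate `waveform_segment` (bpm).
#' @return Stroke volume in ml per beat.
#' @export
compute_sv <- function(co_seg, hr_seg) {
  if (co_seg$channel != "CO" || hr_seg$channel != "HR")
    stopf("compute_sv expects a CO and an HR segment")
  if (abs(segment_duration(co_seg) - segment_duration(hr_seg)) > 0.5)
    stopf("CO and HR segments must span the same window")
  med_hr <- stats::median(hr_seg$samples)
  if (med_hr <= 0) stopf("median heart rate must be positive")
  1000 * stats::median(co_seg$samples) / med_hr
}

#' Label a fluid bolus from pre/post stroke volumes
#'
#' Fluid responsiveness (FR) is a post-bolus stroke-volume increase of at
#' least 15% (boundary inclusive). The grey zone is the closed interval
#' 10-20% change, where the binary label is least certain.
#'
#' @param sv_pre,sv_post Stroke volumes before and after the bolus (`sv_pre > 0`);
#'   any consistent unit.
#' @param fr_threshold_pct FR threshold on the percent SV change (default 15).
#' @param grey_zone_pct Closed grey-zone interval (default `c(10, 20)`).
#' @return List with `sv_pre_ml`, `sv_post_ml`, `delta_sv_pct`, `label`
#'   (`"FR"`/`"NR"`), `sv_zone` (`"below"`/`"grey"`/`"above"`).
#' @export
label_bolus <- function(sv_pre, sv_post, fr_threshold_pct = 15,
                        grey_zone_pct = c(10, 20)) {
  if (!is.finite(sv_pre) || sv_pre <= 0) stopf("sv_pre must be positive")
  delta <- 100 * (sv_post - sv_pre) / sv_pre
  zone <- if (delta < grey_zone_pct[1]) "below"
          else if (delta > grey_zone_pct[2]) "above" else "grey"
  list(sv_pre_ml = sv_pre, sv_post_ml = sv_post, delta_sv_pct = delta,
       label = if (delta >= fr_threshold_pct) "FR" else "NR",
       sv_zone = zone)
}

#' Per-pig label summary of a labeled feature table
#'
#' @param features Labeled feature table (e.g. from [featurize_cohort()]):
#'   needs `pig_id`, `injury_model`, `label`.
#' @return Data.frame with one row per pig: `pig_id`, `injury_model`,
#'   `n_boluses`, `n_fr`.
#' @export
pig_label_table <- function(features) {
  sp <- split(features, features$pig_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(pig_id = d$pig_id[1], injury_model = d$injury_model[1],
               n_boluses = nrow(d), n_fr = sum(d$label == "FR"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
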