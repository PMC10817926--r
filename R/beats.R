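# Beat fiducial detection on preprocessed (100 Hz, smoothed) arterial
# pressure: systolic peak by prominence-thresholded local-maximum search,
# diastolic foot as the minimum between consecutive peaks, dicrotic notch as
# the deepest pressure local minimum in a window after the peak (inflection
# fallback for damped waveforms). All detector constants are arguments with
# the pipeline defaults.

# Strict-then-flat local maxima indices of x (x[i] >= x[i-1], x[i] > x[i+1]).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Topographic prominence of each candidate peak: height above the higher of
# the two key saddles (lowest point walking to the nearest higher terrain on
# each side, or to the segment edge).
peak_prominence <- function(x, peaks) {
  vapply(seq_along(peaks), function(k) {
    i <- peaks[k]; h <- x[i]
    left_higher <- peaks[peaks < i][x[peaks[peaks < i]] > h]
    lo <- if (length(left_higher)) max(left_higher) else 1L
    right_higher <- peaks[peaks > i][x[peaks[peaks > i]] > h]
    hi <- if (length(right_higher)) min(right_higher) else length(x)
    h - max(min(x[lo:i]), min(x[i:hi]))
  }, numeric(1))
}

#' Detect beats and their fiducial points in an ABP segment
#'
#' Finds systolic peaks by local-maximum search with relative prominence and a
#' refractory distance, then per beat the diastolic foot (minimum between
#' consecutive peaks; for the first beat, the minimum preceding its peak) and
#' the dicrotic notch (deepest local pressure minimum in the window
#' `peak + notch_window * beat_period`; if the waveform has no local minimum
#' there, the inflection of maximal second derivative). Beats whose notch
#' search fails keep `NA` notch fields and `notch_ok = FALSE`. Partial beats
#' at the segment edges are dropped.
#'
#' @param seg Preprocessed ABP `waveform_segment` (nominally 100 Hz, smoothed),
#'   duration at least 2 s.
#' @param min_distance_s Refractory period between systolic peaks (s).
#' @param prominence_frac Minimum peak prominence as a fraction of the median
#'   pulse amplitude (detection is therefore amplitude-scale invariant).
#' @param notch_window Search window for the notch as fractions of the beat
#'   period past the peak.
#' @param edge_guard_s Beats whose feet fall within this margin of a segment
#'   edge are treated as partial (the anti-alias and smoothing filters
#'   distort the first/last fraction of a second) and dropped.
#' @return A data.frame of class `beat_fiducials`, one row per complete beat:
#'   indices (1-based), times (s), pressures (mmHg) for foot/peak/notch,
#'   `next_foot_idx`, `period_s`, `pulse_pressure`, `notch_ok`.
#' @export
detect_beats <- function(seg, min_distance_s = 0.3, prominence_frac = 0.25,
                         notch_window = c(0.1, 0.5), edge_guard_s = 0) {
  if (seg$channel != "ABP") stopf("detect_beats expects an ABP segment")
  x <- seg$samples
  fs <- seg$sample_rate_hz
  if (length(x) < 2 * fs) stopf("segment too short for beat detection")
  cand <- local_maxima(x)
  if (length(cand) < 3) stopf("insufficient beats: fewer than 3 peaks found")
  prom <- peak_prominence(x, cand)
  # discard micro-maxima, then estimate the median pulse amplitude from the
  # upper quartile of candidate prominences: sub-pulse maxima (dicrotic
  # crests, noise ripples) are at most one per beat, so the upper quartile
  # always falls in the systolic mode and is a robust estimate of the median
  # systolic prominence even when candidates are bimodal
  floor_rel <- 0.05 * diff(range(x))
  keep0 <- prom >= floor_rel
  if (!any(keep0)) stopf("insufficient beats: no prominent peaks")
  med_amp <- unname(stats::quantile(prom[keep0], 0.75))
  ok <- which(prom >= prominence_frac * med_amp & keep0)
  # enforce refractory distance, keeping the more prominent peak
  ord <- ok[order(prom[ok], decreasing = TRUE)]
  min_dist <- as.integer(round(min_distance_s * fs))
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - cand[taken]) >= min_dist))
      taken <- c(taken, i)
  }
  peaks <- sort(cand[taken])
  if (length(peaks) < 3) stopf("insufficient beats: fewer than 3 peaks retained")

  argmin_between <- function(a, b) a - 1L + which.min(x[a:b])
  n_pk <- length(peaks)
  # foot preceding peak k: minimum between peak k-1 and peak k (global minimum
  # before the first peak for k = 1)
  feet <- integer(n_pk)
  feet[1] <- argmin_between(1L, peaks[1])
  if (n_pk > 1) {
    for (k in 2:n_pk) feet[k] <- argmin_between(peaks[k - 1], peaks[k])
  }
  # complete beats: foot_k -> peak_k -> foot_{k+1}; beats whose feet fall
  # within the filter startup region at either segment edge are partial
  nb <- n_pk - 1L
  if (nb < 3) stopf("insufficient beats: fewer than 3 complete beats")
  edge_guard <- as.integer(round(edge_guard_s * fs))
  rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    if (feet[k] <= edge_guard || feet[k + 1] > length(x) - edge_guard) next
    foot <- feet[k]; peak <- peaks[k]; nxt <- feet[k + 1]
    period <- (nxt - foot) / fs
    w0 <- peak + as.integer(floor(notch_window[1] * period * fs))
    w1 <- peak + as.integer(ceiling(notch_window[2] * period * fs))
    w0 <- max(w0, peak + 1L); w1 <- min(w1, nxt - 1L)
    notch <- NA_integer_; notch_ok <- FALSE
    if (w1 - w0 >= 2) {
      win <- x[w0:w1]
      mins <- local_minima(win)
      if (length(mins)) {
        notch <- w0 - 1L + mins[which.min(win[mins])]
        notch_ok <- TRUE
      } else {
        d2 <- diff(win, differences = 2)
        if (length(d2) && max(d2) > 0) {
          notch <- w0 + which.max(d2) # centre sample of the maximal curvature
          notch_ok <- TRUE
        }
      }
    }
    if (notch_ok) {
      # enforce the pressure-ordering invariant; otherwise flag the notch out
      if (!(x[notch] > min(x[foot], x[nxt]) - 1e-9 && x[notch] < x[peak])) {
        notch <- NA_integer_; notch_ok <- FALSE
      }
    }
    rows[[k]] <- data.frame(
      beat = k, foot_idx = foot, peak_idx = peak, notch_idx = notch,
      next_foot_idx = nxt,
      foot_time_s = (foot - 1) / fs + seg$start_time_s,
      peak_time_s = (peak - 1) / fs + seg$start_time_s,
      notch_time_s = if (notch_ok) (notch - 1) / fs + seg$start_time_s else NA_real_,
      foot_p_mmhg = x[foot], peak_p_mmhg = x[peak],
      notch_p_mmhg = if (notch_ok) x[notch] else NA_real_,
      period_s = period, pulse_pressure = x[peak] - x[foot],
      notch_ok = notch_ok
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3) stopf("insufficient beats: fewer than 3 complete beats")
  out <- do.call(rbind, rows)
  out$beat <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("beat_fiducials", "data.frame")
  out
}

#' Filter detected beats on physiologic plausibility
#'
#' Drops beats with a period outside `period_range`, a pulse pressure below
#' `min_pp_mmhg`, or a period exceeding `rel_period_max` times the median
#' period (a guard against merged beats from a missed detection). Order is
#' preserved.
#'
#' @param beats A `beat_fiducials` data.frame from [detect_beats()].
#' @param period_range Admissible beat period range (s).
#' @param min_pp_mmhg Minimum pulse pressure (mmHg).
#' @param rel_period_max Multiple of the median period above which a beat is
#'   treated as a missed-detection artifact.
#' @return The filtered `beat_fiducials` data.frame.
#' @export
beat_quality_filter <- function(beats, period_range = c(0.3, 1.5),
                                min_pp_mmhg = 5, rel_period_max = 1.5) {
  if (!nrow(beats)) return(beats)
  med_period <- stats::median(beats$period_s)
  keep <- beats$period_s >= period_range[1] &
    beats$period_s <= period_range[2] &
    beats$pulse_pressure >= min_pp_mmhg &
    beats$period_s <= rel_period_max * med_period
  out <- beats[keep, , drop = FALSE]
  class(out) <- c("beat_fiducials", "data.frame")
  out
}

#' Match detected fiducials against planted ground truth
#'
#' Utility for simulator-backed validation: pairs each ground-truth beat (by
#' nearest foot time) with a detected beat and reports per-fiducial absolute
#' timing errors in milliseconds.
#'
#' @param beats Detected `beat_fiducials`.
#' @param truth Data.frame with `foot_time_s`, `peak_time_s`, `notch_time_s`.
#' @return Data.frame with one row per matched beat and columns
#'   `foot_err_ms`, `peak_err_ms`, `notch_err_ms`.
#' @export
match_fiducials <- function(beats, truth) {
  idx <- vapply(beats$foot_time_s, function(t) which.min(abs(truth$foot_time_s - t)),
                integer(1))
  data.frame(
    foot_err_ms = 1000 * abs(beats$foot_time_s - truth$foot_time_s[idx]),
    peak_err_ms = 1000 * abs(beats$peak_time_s - truth$peak_time_s[idx]),
    notch_err_ms = 1000 * abs(beats$notch_time_s - truth$notch_time_s[idx])
  )
}
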