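# Waveform containers, file I/O and the preprocessing chain: decimation from
# the acquisition rate (1000 Hz) to the analysis rate (100 Hz), then
# Savitzky-Golay smoothing (window 19 samples, polynomial order 2).

#' Construct a uniformly sampled waveform segment
#'
#' The basic container for one channel of monitor data: arterial blood
#' pressure (mmHg), cardiac output (L/min) or heart rate (bpm), sampled at a
#' fixed rate.
#'
#' @param samples Numeric vector of samples, no missing values.
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param start_time_s Time of the first sample in seconds.
#' @param channel One of `"ABP"`, `"CO"`, `"HR"`.
#' @return An object of class `waveform_segment`.
#' @export
waveform_segment <- function(samples, sample_rate_hz, start_time_s = 0,
                             channel = c("ABP", "CO", "HR")) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stopf("waveform segment has no samples")
  if (anyNA(samples)) stopf("waveform segment contains missing values")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stopf("sample_rate_hz must be a positive number")
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz),
         start_time_s = as.numeric(start_time_s), channel = channel),
    class = "waveform_segment"
  )
}

#' @export
print.waveform_segment <- function(x, ...) {
  cat(sprintf("<waveform_segment> %s: %d samples @ %g Hz (%.2f s) from t=%g s\n",
              x$channel, length(x$samples), x$sample_rate_hz,
              segment_duration(x), x$start_time_s))
  invisible(x)
}

#' Duration of a segment in seconds
#' @param seg A `waveform_segment`.
#' @return Duration in seconds (n / rate).
#' @export
segment_duration <- function(seg) length(seg$samples) / seg$sample_rate_hz

#' Sample times of a segment
#' @param seg A `waveform_segment`.
#' @return Numeric vector of times in seconds.
#' @export
segment_times <- function(seg) {
  seg$start_time_s + (seq_along(seg$samples) - 1) / seg$sample_rate_hz
}

#' Load a waveform segment from a two-column delimited text file
#'
#' Files carry a header row and two comma-separated columns, `time_s` and
#' `value`, with strictly uniform sampling. This is the interchange dialect
#' written by [write_segment()] and [write_cohort()].
#'
#' @param path File path.
#' @param channel Channel tag, one of `"ABP"`, `"CO"`, `"HR"`.
#' @param expected_rate_hz Optional rate check; the load fails if the inferred
#'   rate differs by more than 1%.
#' @return A `waveform_segment`.
#' @export
load_segment <- function(path, channel = c("ABP", "CO", "HR"),
                         expected_rate_hz = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stopf("waveform file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("numeric", "numeric")),
    error = function(e) stopf("cannot parse waveform file %s: %s", path,
                              conditionMessage(e))
  )
  if (nrow(df) == 0) stopf("empty waveform file: %s", path)
  if (ncol(df) < 2) stopf("waveform file %s must have two columns", path)
  tt <- df[[1]]; vv <- df[[2]]
  if (anyNA(tt) || anyNA(vv)) stopf("non-numeric rows in waveform file: %s", path)
  if (nrow(df) < 2) stopf("waveform file %s has fewer than 2 samples", path)
  dts <- diff(tt)
  period <- stats::median(dts)
  if (period <= 0 || any(abs(dts - period) > 0.01 * period))
    stopf("non-uniform sampling in waveform file: %s", path)
  rate <- 1 / period
  if (!is.null(expected_rate_hz) &&
      abs(rate - expected_rate_hz) > 0.01 * expected_rate_hz)
    stopf("unexpected sample rate in %s: found %.3f Hz, expected %g Hz",
          path, rate, expected_rate_hz)
  waveform_segment(vv, rate, start_time_s = tt[1], channel = channel)
}

#' Write a waveform segment as two-column delimited text
#' @param seg A `waveform_segment`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(seg, path) {
  df <- data.frame(time_s = segment_times(seg), value = seg$samples)
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("failed to write waveform file: %s", path)
  invisible(path)
}

#' Downsample a segment by an integer factor with anti-alias filtering
#'
#' The target rate must divide the source rate evenly (the standard chain is
#' 1000 to 100 Hz, factor 10). A Butterworth low-pass at 0.8 x the target
#' Nyquist (4th order, applied forward-backward: 8th-order zero-phase
#' magnitude, maximally flat so constants and slow waves pass unattenuated)
#' precedes decimation, so standard-deviation type features are not
#' contaminated by aliasing.
#'
#' @param seg A `waveform_segment`.
#' @param target_rate_hz Target rate; must divide `seg$sample_rate_hz` evenly.
#' @return The decimated `waveform_segment` at `target_rate_hz`.
#' @export
downsample <- function(seg, target_rate_hz) {
  if (target_rate_hz <= 0) stopf("target rate must be positive")
  factor <- seg$sample_rate_hz / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9)
    stopf("target rate %g Hz does not divide source rate %g Hz evenly",
          target_rate_hz, seg$sample_rate_hz)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(seg)
  # reflect-pad before filtering so the zero-phase filter startup transient
  # falls on the padding, not on the first/last beats
  x <- seg$samples
  n <- length(x)
  npad <- min(n - 1, as.integer(seg$sample_rate_hz)) # up to 1 s each side
  npad <- (npad %/% factor) * factor
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  # 4th-order Butterworth applied forward-backward: 8th-order zero-phase
  # magnitude, maximally flat passband (constants pass exactly)
  bf <- signal::butter(4, 0.8 / factor)
  yf <- signal::filtfilt(bf, xp)
  y <- yf[seq.int(npad + 1L, npad + n, by = factor)]
  waveform_segment(y, target_rate_hz, seg$start_time_s, seg$channel)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with the pipeline defaults
#' (window 19 samples, order 2). At the segment boundaries the fit is
#' evaluated off-center within the first/last full window, so no samples are
#' invented. Constants and polynomials up to the filter order pass unchanged.
#'
#' @param seg A `waveform_segment`.
#' @param window Odd window length in samples (> `polyorder`).
#' @param polyorder Polynomial order.
#' @return Smoothed `waveform_segment` (same length and rate).
#' @export
smooth_segment <- function(seg, window = 19, polyorder = 2) {
  if (window %% 2 == 0) stopf("smoothing window must be odd")
  if (window <= polyorder) stopf("smoothing window must exceed polynomial order")
  if (polyorder < 0) stopf("polynomial order must be nonnegative")
  if (length(seg$samples) < window)
    stopf("segment shorter than smoothing window (%d < %d)",
          length(seg$samples), window)
  y <- signal::sgolayfilt(seg$samples, p = polyorder, n = window)
  waveform_segment(y, seg$sample_rate_hz, seg$start_time_s, seg$channel)
}

#' Automated quality control for an arterial pressure segment
#'
#' A machine substitute for manual artifact review. A segment fails on any of:
#' samples outside the physiologic pressure range, a flatline (a window longer
#' than `flatline_s` whose range is below `flatline_range_mmhg`), or pulse
#' pressure collapse (any `pp_window_s` window whose range falls below
#' `min_pp_mmhg`).
#'
#' @param seg An ABP `waveform_segment`.
#' @param pressure_range Open interval of admissible pressures (mmHg).
#' @param flatline_s Flatline window length (s).
#' @param flatline_range_mmhg Range below which a window counts as flat.
#' @param min_pp_mmhg Minimum admissible windowed pulse pressure.
#' @param pp_window_s Window used for the pulse-pressure collapse check.
#' @return A list with `pass` (logical) and `reasons` (character vector drawn
#'   from `"range"`, `"flatline"`, `"pulse_pressure"`).
#' @export
qc_segment <- function(seg, pressure_range = c(0, 300), flatline_s = 2,
                       flatline_range_mmhg = 1, min_pp_mmhg = 5,
                       pp_window_s = 4) {
  if (seg$channel != "ABP") stopf("qc_segment expects an ABP segment")
  x <- seg$samples
  reasons <- character(0)
  if (any(x <= pressure_range[1] | x >= pressure_range[2]))
    reasons <- c(reasons, "range")
  # Strided window scan (0.1 s stride) for flatline and PP collapse.
  stride <- max(1L, as.integer(round(0.1 * seg$sample_rate_hz)))
  scan_ranges <- function(width_s) {
    w <- as.integer(round(width_s * seg$sample_rate_hz))
    if (w >= length(x)) return(diff(range(x)))
    starts <- seq.int(1L, length(x) - w, by = stride)
    vapply(starts, function(s) {
      xi <- x[s:(s + w - 1L)]
      max(xi) - min(xi)
    }, numeric(1))
  }
  if (any(scan_ranges(flatline_s) < flatline_range_mmhg))
    reasons <- c(reasons, "flatline")
  if (any(scan_ranges(pp_window_s) < min_pp_mmhg))
    reasons <- c(reasons, "pulse_pressure")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Standard preprocessing chain for an ABP segment
#'
#' Decimate to the analysis rate, then Savitzky-Golay smooth. Downsampling to
#' the current rate is the identity, so the chain is idempotent at the
#' analysis rate.
#'
#' @param seg A `waveform_segment` (usually ABP at 1000 Hz).
#' @param analysis_rate_hz Target rate (default 100 Hz).
#' @param window,polyorder Savitzky-Golay parameters.
#' @return Preprocessed `waveform_segment`.
#' @export
preprocess_segment <- function(seg, analysis_rate_hz = 100, window = 19,
                               polyorder = 2) {
  smooth_segment(downsample(seg, analysis_rate_hz), window, polyorder)
}
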