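#' Blink-free average EAR
#'
#' Average eye openness measured away from blinks: the mean of the trace over
#' the union of the first `window_s` seconds of every blink-free interval
#' (intervals shorter than `window_s` contribute wholly). With no events the
#' whole trace is one interval and its first `window_s` seconds are used.
#' The caller normally passes the smoothed trace so the estimate matches the
#' signal the detector saw.
#'
#' @param trace An [ear_trace()] (typically smoothed).
#' @param events A `blink_events` table on the same clock.
#' @param window_s Length of the window taken at the start of every
#'   blink-free interval, seconds (default 3).
#' @return The mean EAR over the selected samples.
#' @export
blink_free_average_ear <- function(trace, events, window_s = 3) {
  stopifnot(inherits(trace, "ear_trace"))
  t <- trace_times(trace)
  dur <- trace$duration_s
  if (is.null(events) || nrow(events) == 0L) {
    starts <- 0
    ends <- dur
  } else {
    ev <- events[order(events$onset_s), , drop = FALSE]
    starts <- c(0, ev$offset_s)
    ends <- c(ev$onset_s, dur)
  }
  keep <- ends > starts
  starts <- starts[keep]
  ends <- pmin(ends[keep], starts + window_s)
  fps <- trace$fps
  n <- length(t)
  # sample i sits at (i - 1) / fps; select i with start <= t_i < end
  ia <- pmax(1L, as.integer(ceiling(starts * fps - 1e-9)) + 1L)
  ib <- pmin(n, as.integer(ceiling(ends * fps - 1e-9)))
  ok <- ib >= ia
  if (!any(ok)) {
    stop_input("no blink-free samples available")
  }
  idx <- unlist(mapply(seq.int, ia[ok], ib[ok], SIMPLIFY = FALSE))
  mean(trace$values[idx])
}

#' Per-eye blink summary
#'
#' Reduces a recording (one eye) to the standard clinimetric summary: the
#' blink-free average EAR, the recording-wide minimum and maximum of the
#' smoothed trace, blink counts normalised to 20 minutes, blink frequency per
#' minute, mean blink duration, and the same count/frequency figures for the
#' subset of blinks with complete eye closure. `min_ear_blinkmean`, the mean
#' of the per-blink EAR minima, is also reported as an alternative reading of
#' "minimum EAR" (the recording-global minimum is the headline field).
#'
#' Counts are normalised as `count * 1200 / duration_s` so recordings that
#' deviate from the 20-minute protocol stay comparable; mean durations over
#' an empty event set are `NA`, never 0.
#'
#' @param trace An [ear_trace()].
#' @param events The `blink_events` detected on this trace.
#' @param params The [detection_params()] used (for the smoothing window).
#' @return A one-row `data.frame` of class `eye_blink_summary`.
#' @export
summarize_eye <- function(trace, events, params = detection_params()) {
  stopifnot(inherits(trace, "ear_trace"))
  if (length(trace$values) == 0L) stop_input("zero-length trace")
  sm <- smooth_trace(trace, params$smooth_window_ms)
  dur <- trace$duration_s
  counted <- events[events$counted, , drop = FALSE]
  comp <- counted[counted$complete, , drop = FALSE]
  n <- nrow(counted)
  nc <- nrow(comp)
  out <- data.frame(
    side = trace$side,
    recording_duration_s = dur,
    avg_ear = blink_free_average_ear(sm, counted),
    min_ear = min(sm$values),
    max_ear = max(sm$values),
    min_ear_blinkmean = if (n > 0L) mean(counted$min_ear) else NA_real_,
    n_blinks = n,
    n_blinks_20min = n * 1200 / dur,
    freq_per_min = n / (dur / 60),
    mean_duration_ms = if (n > 0L) mean(counted$duration_ms) else NA_real_,
    n_complete = nc,
    n_complete_20min = nc * 1200 / dur,
    freq_complete_per_min = nc / (dur / 60),
    stringsAsFactors = FALSE
  )
  class(out) <- c("eye_blink_summary", "data.frame")
  out
}

#' Per-minute blink time course
#'
#' Bins blink events by onset into half-open one-minute bins
#' `[60 * (k - 1), 60 * k)` — an onset exactly on a minute boundary goes to
#' the later bin — and reports the count and mean duration of counted blinks
#' per bin. Empty bins have count 0 and `NA` mean duration.
#'
#' @param events A `blink_events` table.
#' @param duration_s Recording length in seconds (> 0).
#' @return A `data.frame` with columns `minute` (1-based bin index), `count`,
#'   `mean_duration_ms`.
#' @export
per_minute_timecourse <- function(events, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_input("duration_s must be > 0")
  }
  nbins <- as.integer(ceiling(duration_s / 60))
  ev <- events[events$counted, , drop = FALSE]
  if (nrow(ev) > 0L &&
    (any(ev$onset_s < 0) || any(ev$onset_s >= duration_s))) {
    stop_input("event onset outside [0, duration_s)")
  }
  bin <- floor(ev$onset_s / 60) + 1
  counts <- tabulate(bin, nbins)
  mean_dur <- rep(NA_real_, nbins)
  if (nrow(ev) > 0L) {
    agg <- tapply(ev$duration_ms, factor(bin, levels = seq_len(nbins)), mean)
    mean_dur <- as.numeric(agg)
  }
  data.frame(
    minute = seq_len(nbins),
    count = counts,
    mean_duration_ms = mean_dur
  )
}
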