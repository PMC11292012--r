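#' Blink detection parameters
#'
#' Tuning knobs for the hysteresis blink detector. A blink candidate opens
#' when the smoothed EAR falls to or below `theta_p` times the local baseline
#' (the counting threshold, a proxy for "at least the pupil is covered") and
#' closes when the EAR recovers to at least `hysteresis_fraction` times the
#' baseline; the higher release level prevents chatter around the counting
#' threshold. The local baseline is a rolling upper percentile of the
#' smoothed trace, so thresholds track slow drifts in eye openness and differ
#' between a wide-open and a narrowed eye.
#'
#' @param smooth_window_ms Width of the centred moving average applied before
#'   thresholding, in milliseconds (default 25 ms, about 6 samples at
#'   240 fps). 0 disables smoothing.
#' @param baseline_window_s Length of the rolling window for the baseline
#'   estimate, seconds (default 30 s).
#' @param baseline_percentile Upper percentile used as baseline within each
#'   window (default 75); blinks occupy a small minority of any window, so an
#'   upper percentile tracks the open-eye level.
#' @param theta_p Counting threshold as a fraction of the local baseline
#'   (default 0.7). A blink is counted when the EAR reaches
#'   `theta_p * baseline`.
#' @param theta_c Absolute complete-closure threshold on the minimum EAR of
#'   an event (default 0.10): at or below it the lids are taken to meet.
#' @param hysteresis_fraction Release threshold as a fraction of the baseline
#'   (default 0.85); must exceed `theta_p`.
#' @param min_duration_ms,max_duration_ms Events with full width at the
#'   counting threshold outside this range are discarded (defaults 33 ms —
#'   about 8 samples at 240 fps, rejecting single-sample noise — and
#'   2000 ms, excluding sustained closures).
#' @param merge_gap_ms Events separated by less than this are merged
#'   (default 50 ms).
#' @param baseline_hop_s Stride of the rolling-percentile evaluation; the
#'   percentile is computed on windows centred every `baseline_hop_s` seconds
#'   and linearly interpolated in between (default 1 s).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smooth_window_ms = 25,
                             baseline_window_s = 30,
                             baseline_percentile = 75,
                             theta_p = 0.7,
                             theta_c = 0.10,
                             hysteresis_fraction = 0.85,
                             min_duration_ms = 33,
                             max_duration_ms = 2000,
                             merge_gap_ms = 50,
                             baseline_hop_s = 1) {
  p <- list(
    smooth_window_ms = smooth_window_ms,
    baseline_window_s = baseline_window_s,
    baseline_percentile = baseline_percentile,
    theta_p = theta_p,
    theta_c = theta_c,
    hysteresis_fraction = hysteresis_fraction,
    min_duration_ms = min_duration_ms,
    max_duration_ms = max_duration_ms,
    merge_gap_ms = merge_gap_ms,
    baseline_hop_s = baseline_hop_s
  )
  num <- vapply(p, function(v) {
    is.numeric(v) && length(v) == 1L && is.finite(v)
  }, logical(1L))
  if (!all(num)) {
    stop_input("all detection parameters must be single finite numbers")
  }
  if (!(theta_p > 0 && theta_p < hysteresis_fraction &&
    hysteresis_fraction <= 1)) {
    stop_input("need 0 < theta_p < hysteresis_fraction <= 1")
  }
  if (theta_c < 0) stop_input("theta_c must be >= 0")
  if (min_duration_ms >= max_duration_ms) {
    stop_input("min_duration_ms must be smaller than max_duration_ms")
  }
  if (smooth_window_ms < 0 || baseline_window_s <= 0 || merge_gap_ms < 0 ||
    baseline_hop_s <= 0) {
    stop_input("window, gap and hop parameters must be non-negative")
  }
  if (baseline_percentile <= 0 || baseline_percentile > 100) {
    stop_input("baseline_percentile must be in (0, 100]")
  }
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Moving-average smoothing of an EAR trace
#'
#' Centred moving average with a window of `round(window_ms * fps / 1000)`
#' samples (at least 1; `window_ms = 0` is the identity). Edges use the
#' partial window that fits inside the trace, so length is preserved and a
#' constant trace is returned unchanged.
#'
#' @param trace An [ear_trace()].
#' @param window_ms Window width in milliseconds.
#' @return The smoothed [ear_trace()].
#' @export
smooth_trace <- function(trace, window_ms) {
  stopifnot(inherits(trace, "ear_trace"))
  if (window_ms < 0) stop_input("window_ms must be >= 0")
  n <- length(trace$values)
  w <- max(1L, as.integer(round(window_ms * trace$fps / 1000)))
  if (w > n) stop_input("smoothing window (%d samples) longer than trace", w)
  if (w == 1L) {
    return(trace)
  }
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- c(0, cumsum(trace$values))
  i <- seq_len(n)
  a <- pmax(i - left, 1L)
  b <- pmin(i + right, n)
  sm <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  out <- trace
  out$values <- sm
  out
}

#' Rolling-percentile baseline of an EAR trace
#'
#' Estimates the per-sample open-eye level as a rolling upper percentile
#' (default 75th over 30 s) of the trace. The percentile is evaluated on
#' windows centred every `baseline_hop_s` seconds and linearly interpolated
#' to every sample; since blinks occupy a small minority of any window, the
#' upper percentile is insensitive to them while tracking slow drift. An
#' all-zero trace yields an all-zero baseline with a warning (downstream
#' detection then returns no counted blinks).
#'
#' @param trace A (typically smoothed) [ear_trace()].
#' @param params A [detection_params()] object.
#' @return Numeric vector, one baseline value per sample.
#' @export
estimate_baseline <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "ear_trace"))
  x <- trace$values
  n <- length(x)
  w <- as.integer(round(params$baseline_window_s * trace$fps))
  if (w > n) {
    stop_short_trace(
      "trace (%.1f s) shorter than the baseline window (%g s)",
      trace$duration_s, params$baseline_window_s
    )
  }
  if (all(x == 0)) {
    warning("all-zero EAR trace: returning an all-zero baseline")
    return(rep(0, n))
  }
  rolling_quantile(x, trace$fps, w, params$baseline_hop_s,
    params$baseline_percentile / 100
  )
}

# Rolling quantile with a stride, evaluated on a ~60 Hz decimated view of
# the trace (a 30 s window still holds ~1800 samples, so the window quantile
# is essentially unchanged while high-frame-rate traces stay cheap) and
# linearly interpolated back to every sample. `drop_mask` marks samples to
# exclude (e.g. blink frames); windows left empty by the mask fall back to
# the `fallback` per-sample estimate.
rolling_quantile <- function(x, fps, w, hop_s, prob, drop_mask = NULL,
                             fallback = NULL) {
  n <- length(x)
  dec <- max(1L, as.integer(floor(fps / 60)))
  sel <- seq.int(1L, n, by = dec)
  xd <- x[sel]
  if (!is.null(drop_mask)) {
    xd[drop_mask[sel]] <- NA_real_
  }
  nd <- length(xd)
  wd <- max(2L, as.integer(round(w / dec)))
  hop <- max(1L, as.integer(round(hop_s * fps / dec)))
  centers <- unique(c(seq.int(1L, nd, by = hop), nd))
  half <- wd / 2
  q <- vapply(centers, function(cc) {
    a <- max(1L, as.integer(ceiling(cc - half)))
    b <- min(nd, as.integer(floor(cc + half)))
    win <- xd[a:b]
    if (all(is.na(win))) {
      return(NA_real_)
    }
    stats::quantile(win, prob, names = FALSE, na.rm = TRUE)
  }, numeric(1L))
  if (anyNA(q)) {
    if (is.null(fallback)) {
      stop_input("baseline window contains no usable samples")
    }
    q[is.na(q)] <- fallback[(centers[is.na(q)] - 1L) * dec + 1L]
  }
  if (length(centers) == 1L) {
    return(rep(q, n))
  }
  stats::approx((centers - 1L) * dec + 1L, q,
    xout = seq_len(n), rule = 2
  )$y
}

#' Detect blink events on an EAR trace
#'
#' Runs the hysteresis state machine on the smoothed trace against the
#' rolling-percentile baseline: a candidate event opens when the EAR is at or
#' below `theta_p * baseline` and closes when it recovers to at least
#' `hysteresis_fraction * baseline`. Event onset and offset are the crossing
#' times of the `theta_p * baseline` level, linearly interpolated between
#' samples (first down-crossing and last up-crossing inside the candidate).
#' Candidates separated by less than `merge_gap_ms` are merged (minimum EAR
#' taken over the parts) and candidates with duration outside
#' `[min_duration_ms, max_duration_ms]` are discarded. Every returned event
#' is counted by construction; completeness is classified against `theta_c`.
#' Ties at a threshold resolve toward closure (comparison is `<=`).
#'
#' Candidates that start on the very first sample or have not released by the
#' end of the trace (the recording starts or ends mid-blink) have no
#' interpolable crossing and are dropped.
#'
#' @param trace An [ear_trace()] at least `baseline_window_s` long.
#' @param params A [detection_params()] object.
#' @return A `blink_events` data frame with one row per blink: `side`,
#'   `onset_s`, `offset_s` (half-open interval), `duration_ms`, `min_ear`,
#'   `baseline_ear` (local baseline at onset), `counted`, `complete`.
#' @examples
#' pre <- preset_registry()$healthy_eye
#' g <- generate_ear_trace(pre, duration_s = 60, fps = 240, seed = 1)
#' detect_blinks(g$trace)
#' @export
detect_blinks <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "ear_trace"))
  if (!inherits(params, "detection_params")) {
    stop_input("'params' must be a detection_params object")
  }
  if (trace$duration_s < params$baseline_window_s) {
    stop_short_trace(
      "trace (%.1f s) shorter than the baseline window (%g s)",
      trace$duration_s, params$baseline_window_s
    )
  }
  sm <- smooth_trace(trace, params$smooth_window_ms)
  x <- sm$values
  fps <- trace$fps
  empty <- blink_events_frame(trace$side)

  # pass 1: detect candidates against the robust upper-percentile baseline
  base <- suppressWarnings(estimate_baseline(sm, params))
  ev <- hysteresis_scan(x, base, fps, params)

  # pass 2: re-derive the crossing thresholds from a blink-free rolling
  # median of the open-eye level. The upper percentile is robust for
  # *finding* blinks but overestimates the open level by a fraction of the
  # noise and drift spread, which biases the measured widths of slow,
  # shallow blink waveforms; the median over blink-free samples is unbiased
  # for a symmetric noise distribution.
  if (!is.null(ev) && nrow(ev) > 0L) {
    margin <- 0.05
    drop <- rep(FALSE, length(x))
    ia <- pmax(1L, as.integer(floor((ev$onset_s - margin) * fps)) + 1L)
    ib <- pmin(length(x), as.integer(ceiling((ev$offset_s + margin) * fps)) + 1L)
    for (k in seq_len(nrow(ev))) {
      drop[ia[k]:ib[k]] <- TRUE
    }
    w <- as.integer(round(params$baseline_window_s * trace$fps))
    base <- rolling_quantile(x, fps, w, params$baseline_hop_s, 0.5,
      drop_mask = drop, fallback = base
    )
    ev <- hysteresis_scan(x, base, fps, params)
  }
  if (is.null(ev) || nrow(ev) == 0L) {
    return(empty)
  }

  # merge events closer than merge_gap_ms
  gap_s <- params$merge_gap_ms / 1000
  keep <- list(ev[1L, ])
  if (nrow(ev) > 1L) {
    for (k in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if (ev$onset_s[k] - last$offset_s < gap_s) {
        last$offset_s <- ev$offset_s[k]
        last$min_ear <- min(last$min_ear, ev$min_ear[k])
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1L]] <- ev[k, ]
      }
    }
  }
  ev <- do.call(rbind, keep)

  ev$duration_ms <- (ev$offset_s - ev$onset_s) * 1000
  ev <- ev[ev$duration_ms >= params$min_duration_ms &
    ev$duration_ms <= params$max_duration_ms, , drop = FALSE]
  out <- data.frame(
    side = rep(trace$side, nrow(ev)),
    onset_s = ev$onset_s,
    offset_s = ev$offset_s,
    duration_ms = ev$duration_ms,
    min_ear = ev$min_ear,
    baseline_ear = ev$baseline_ear
  )
  rownames(out) <- NULL
  classify_blink(as_blink_events(out), params)
}

# hysteresis state machine: candidates open at the first sample at or below
# theta_p * baseline and close at the first later sample at or above
# hysteresis_fraction * baseline; onset/offset are the interpolated
# crossings of the counting level (first down-crossing, last up-crossing
# inside the candidate). Candidates without both crossings (trace starts or
# ends mid-blink) are dropped.
hysteresis_scan <- function(x, base, fps, params) {
  n <- length(x)
  thr <- params$theta_p * base
  rel <- params$hysteresis_fraction * base
  below <- x <= thr
  entries <- which(below & !c(FALSE, below[-n]))
  if (length(entries) == 0L) {
    return(NULL)
  }
  rel_idx <- which(x >= rel)
  # first release strictly after each entry
  pos <- findInterval(entries, rel_idx) + 1L
  release <- ifelse(pos <= length(rel_idx), rel_idx[pos], NA_integer_)
  ok <- !is.na(release) & entries > 1L
  entries <- entries[ok]
  release <- release[ok]
  if (length(entries) == 0L) {
    return(NULL)
  }
  g <- x - thr # signed distance to the counting threshold
  rows <- lapply(split(entries, release), function(es) {
    i0 <- min(es)
    r <- release[match(i0, entries)]
    if (base[i0] <= 0) {
      return(NULL)
    }
    span <- i0:(r - 1L)
    j1 <- span[max(which(below[span]))]
    a_on <- g[i0 - 1L]
    al <- a_on / (a_on - g[i0])
    t_on <- (i0 - 2L + al) / fps
    a_off <- g[j1]
    al2 <- a_off / (a_off - g[j1 + 1L])
    t_off <- (j1 - 1L + al2) / fps
    data.frame(
      onset_s = t_on, offset_s = t_off,
      min_ear = min(x[i0:j1]), baseline_ear = base[i0]
    )
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0L) {
    return(NULL)
  }
  ev[order(ev$onset_s), , drop = FALSE]
}

blink_events_frame <- function(side = character(0)) {
  as_blink_events(data.frame(
    side = side,
    onset_s = numeric(length(side)),
    offset_s = numeric(length(side)),
    duration_ms = numeric(length(side)),
    min_ear = numeric(length(side)),
    baseline_ear = numeric(length(side)),
    counted = logical(length(side)),
    complete = logical(length(side))
  )[0L, ])
}

as_blink_events <- function(df) {
  class(df) <- c("blink_events", "data.frame")
  df
}

#' Classify blink events as counted / complete
#'
#' Writes the two classification flags onto an event table: an event is
#' `counted` when its minimum EAR is at or below `theta_p` times its local
#' baseline (the pupil was at least covered) and `complete` when the minimum
#' EAR is at or below the absolute threshold `theta_c` (the lids met). Under
#' the default parameters every complete blink is also counted for any
#' baseline at or above `theta_c / theta_p`.
#'
#' @param events A `blink_events` data frame with `min_ear` and
#'   `baseline_ear` columns (one or many rows).
#' @param params A [detection_params()] object.
#' @return The event table with `counted` and `complete` set.
#' @export
classify_blink <- function(events, params = detection_params()) {
  if (!all(c("min_ear", "baseline_ear") %in% names(events))) {
    stop_input("events need 'min_ear' and 'baseline_ear' columns")
  }
  events$counted <- events$min_ear <= params$theta_p * events$baseline_ear
  events$complete <- events$min_ear <= params$theta_c
  as_blink_events(events)
}

#' @export
print.blink_events <- function(x, ...) {
  cat(sprintf(
    "<blink_events> %d event(s), %d complete\n",
    nrow(x), sum(x$complete)
  ))
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Full blink analysis of one EAR trace
#'
#' High-level wrapper running the whole per-eye pipeline —
#' smoothing, baseline estimation, hysteresis blink detection and
#' classification, summary metrics, and the per-minute time course — and
#' returning everything in one object with `print`, `summary` and `plot`
#' methods.
#'
#' @param trace An [ear_trace()].
#' @param params A [detection_params()] object.
#' @return An object of class `blink_analysis` with elements `trace`,
#'   `smoothed`, `baseline`, `events`, `summary` (see [summarize_eye()]),
#'   `timecourse` (see [per_minute_timecourse()]), and `params`.
#' @examples
#' g <- generate_ear_trace(preset_registry()$healthy_eye,
#'   duration_s = 120, fps = 240, seed = 7
#' )
#' fit <- blink_analysis(g$trace)
#' fit
#' summary(fit)
#' @export
blink_analysis <- function(trace, params = detection_params()) {
  events <- detect_blinks(trace, params)
  sm <- smooth_trace(trace, params$smooth_window_ms)
  structure(
    list(
      trace = trace,
      smoothed = sm,
      baseline = suppressWarnings(estimate_baseline(sm, params)),
      events = events,
      summary = summarize_eye(trace, events, params),
      timecourse = per_minute_timecourse(events, trace$duration_s),
      params = params
    ),
    class = "blink_analysis"
  )
}

#' @export
print.blink_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<blink_analysis> %s eye, %.1f min at %g fps\n",
    x$trace$side, x$trace$duration_s / 60, x$trace$fps
  ))
  cat(sprintf(
    "  blinks: %d (%.1f/min), complete: %d (%.1f/min)\n",
    s$n_blinks, s$freq_per_min, s$n_complete, s$freq_complete_per_min
  ))
  cat(sprintf(
    "  mean duration %.1f ms; EAR avg %.3f, min %.3f, max %.3f\n",
    s$mean_duration_ms, s$avg_ear, s$min_ear, s$max_ear
  ))
  invisible(x)
}

#' @export
summary.blink_analysis <- function(object, ...) {
  object$summary
}

#' @export
plot.blink_analysis <- function(x, window_s = NULL, ...) {
  t <- trace_times(x$trace)
  sel <- if (is.null(window_s)) {
    rep(TRUE, length(t))
  } else {
    t >= window_s[1] & t <= window_s[2]
  }
  graphics::plot(t[sel], x$smoothed$values[sel],
    type = "l",
    xlab = "time [s]", ylab = "EAR", ...
  )
  graphics::lines(t[sel], x$baseline[sel], col = "grey60", lty = 2)
  graphics::lines(t[sel], x$params$theta_p * x$baseline[sel],
    col = "steelblue", lty = 3
  )
  if (nrow(x$events) > 0L) {
    graphics::abline(v = x$events$onset_s, col = "tomato", lty = 3)
  }
  invisible(x)
}
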