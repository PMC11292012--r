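# Shared fixtures: all synthetic, built in code at test time.

# the worked six-landmark eye: width 4, both lid separations 2 -> EAR 0.5
worked_eye <- function() {
  eye_landmarks(
    p1 = c(0, 0), p2 = c(1, 1), p3 = c(3, 1),
    p4 = c(4, 0), p5 = c(3, -1), p6 = c(1, -1)
  )
}

# constant-level trace with triangular (V-shaped) dips; width_at_thr is the
# full width of each dip at the counting level theta_p * base
make_v_trace <- function(duration_s, fps, base = 0.3, centers = numeric(0),
                         bottoms = numeric(0), widths_at_thr = numeric(0),
                         theta_p = 0.7, side = "left") {
  t <- (seq_len(round(duration_s * fps)) - 1) / fps
  v <- rep(base, length(t))
  lev <- theta_p * base
  for (k in seq_along(centers)) {
    # triangle from base to bottom: full width at level L is
    # w * (L - bottom) / (base - bottom)
    w <- widths_at_thr[k] * (base - bottoms[k]) / (lev - bottoms[k])
    tri <- pmax(0, 1 - abs(t - centers[k]) / (w / 2))
    v <- v - tri * (base - bottoms[k])
  }
  ear_trace(v, fps = fps, side = side)
}

# independent brute-force oracle: scan runs of samples at or below a constant
# threshold, linearly interpolate the crossing times, measure run widths
bf_blink_scan <- function(values, fps, thr, min_dur_ms = 0,
                          max_dur_ms = Inf) {
  below <- values <= thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]
    j1 <- ends[k]
    if (i0 == 1L || j1 == length(values)) next
    a <- values[i0 - 1L]
    b <- values[i0]
    t_on <- (i0 - 2L + (a - thr) / (a - b)) / fps
    a2 <- values[j1]
    b2 <- values[j1 + 1L]
    t_off <- (j1 - 1L + (thr - a2) / (b2 - a2)) / fps
    dur <- (t_off - t_on) * 1000
    if (dur < min_dur_ms || dur > max_dur_ms) next
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = t_on, offset_s = t_off, duration_ms = dur,
      min_ear = min(values[i0:j1])
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(
      onset_s = numeric(0), offset_s = numeric(0),
      duration_ms = numeric(0), min_ear = numeric(0)
    ))
  }
  do.call(rbind, rows)
}

# randomized V-dip trace with well-separated dips (no merge conflicts, full
# recovery above the hysteresis level between dips)
random_dip_trace <- function(seed, duration_s = 30, fps = 100, base = 0.3) {
  set.seed(seed)
  n_dip <- sample(0:8, 1)
  centers <- numeric(0)
  bottoms <- numeric(0)
  widths <- numeric(0)
  tc <- 1.5
  for (k in seq_len(n_dip)) {
    tc <- tc + runif(1, 1.2, 3)
    if (tc > duration_s - 1.5) break
    centers <- c(centers, tc)
    bottoms <- c(bottoms, runif(1, 0.02, 0.15))
    widths <- c(widths, runif(1, 0.1, 0.4))
  }
  list(
    trace = make_v_trace(duration_s, fps, base, centers, bottoms, widths),
    centers = centers, bottoms = bottoms, widths = widths
  )
}

# detection parameters suitable for short test traces
short_params <- function(...) {
  detection_params(smooth_window_ms = 0, baseline_window_s = 5, ...)
}

# fabricated per-eye summary rows for group-statistics tests (no pipeline
# run needed); blink frequencies scale with `freq`, paretic side scaled by
# `paretic_factor`
fake_summaries <- function(ids, freq, paretic_factor = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_along(ids)) {
    for (side in c("left", "right")) {
      f <- freq[i] * ifelse(side == "left", paretic_factor, 1) *
        exp(rnorm(1, 0, 0.05))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], side = side,
        recording_duration_s = 1200,
        avg_ear = 0.29 + rnorm(1, 0, 0.02),
        min_ear = abs(rnorm(1, 0.05, 0.02)),
        max_ear = 0.39 + rnorm(1, 0, 0.03),
        min_ear_blinkmean = abs(rnorm(1, 0.08, 0.02)),
        n_blinks = round(f * 20),
        n_blinks_20min = f * 20,
        freq_per_min = f,
        mean_duration_ms = 200 + rnorm(1, 0, 20),
        n_complete = round(f * 10),
        n_complete_20min = f * 10,
        freq_complete_per_min = f / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
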