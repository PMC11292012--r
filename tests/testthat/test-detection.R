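test_that("moving-average smoothing preserves constants and handles spikes", {
  flat <- ear_trace(rep(0.3, 500), fps = 100)
  expect_equal(smooth_trace(flat, 80)$values, flat$values)
  tr <- ear_trace(runif(100, 0.1, 0.4), fps = 100)
  expect_identical(smooth_trace(tr, 0)$values, tr$values)

  # single-sample spike 0.3 -> 0.0 -> 0.3 under a 3-sample window
  spike <- ear_trace(c(0.3, 0.3, 0, 0.3, 0.3), fps = 1000)
  expect_equal(smooth_trace(spike, 3)$values[3], 0.2, tolerance = 1e-12)
  expect_equal(length(smooth_trace(spike, 3)), 5L)

  expect_error(smooth_trace(spike, 100), "longer than trace")
})

test_that("rolling-percentile baseline tracks the open-eye level", {
  p <- short_params()
  flat <- ear_trace(rep(0.3, 3000), fps = 100)
  expect_equal(estimate_baseline(flat, p), rep(0.3, 3000))

  # brief dips covering a minority of every window leave the baseline at 0.3
  dipped <- make_v_trace(30, 100,
    centers = c(5, 12, 21), bottoms = c(0.05, 0.1, 0.02),
    widths_at_thr = c(0.3, 0.2, 0.3)
  )
  expect_equal(estimate_baseline(dipped, p), rep(0.3, 3000))

  zero <- ear_trace(rep(0, 1000), fps = 100)
  expect_warning(b <- estimate_baseline(zero, p), "all-zero")
  expect_identical(b, rep(0, 1000))

  expect_error(
    estimate_baseline(ear_trace(rep(0.3, 10), fps = 100), p),
    class = "blinkr_short_trace_error"
  )
})

test_that("detector finds V-dips with the right count, depth and width", {
  p <- short_params()
  flat <- ear_trace(rep(0.3, 3000), fps = 100)
  expect_identical(nrow(detect_blinks(flat, p)), 0L)

  # three 200 ms dips to 0.05: all counted and complete
  tr <- make_v_trace(20, 240,
    centers = c(5, 10, 15), bottoms = rep(0.05, 3),
    widths_at_thr = rep(0.2, 3)
  )
  ev <- detect_blinks(tr, p)
  expect_identical(nrow(ev), 3L)
  expect_true(all(ev$counted))
  expect_true(all(ev$complete))
  expect_equal(ev$duration_ms, rep(200, 3), tolerance = 5 / 200)
  expect_equal(ev$min_ear, rep(0.05, 3), tolerance = 0.01)
  expect_equal(ev$onset_s + ev$duration_ms / 2000, c(5, 10, 15),
    tolerance = 1e-3
  )

  # a shallow dip to 0.25 never reaches 0.7 * 0.30 = 0.21
  ts <- (seq_len(20 * 240) - 1) / 240
  shallow <- ear_trace(
    0.3 - 0.05 * pmax(0, 1 - abs(ts - 10) / 0.2),
    fps = 240
  )
  expect_identical(nrow(detect_blinks(shallow, p)), 0L)
})

test_that("hysteresis merges partial re-openings into one event", {
  p <- short_params()
  # two dips 600 ms apart; the recovery between them is capped at
  # `recover_to` so it either stays below or clears the release level
  mk <- function(recover_to) {
    tr <- make_v_trace(20, 240,
      centers = c(10, 10.6), bottoms = c(0.05, 0.05),
      widths_at_thr = c(0.162, 0.162)
    )
    t <- trace_times(tr)
    mid <- t > 10.1 & t < 10.5
    tr$values[mid] <- pmin(tr$values[mid], recover_to)
    tr
  }
  # recovery stays below the release level 0.85 * 0.3 = 0.255: one event
  one <- detect_blinks(mk(0.24), p)
  expect_identical(nrow(one), 1L)
  # full recovery above release, gap > merge_gap: two events
  two <- detect_blinks(mk(0.30), p)
  expect_identical(nrow(two), 2L)
})

test_that("detector matches the brute-force run scan on random traces", {
  p <- short_params()
  checked <- 0L
  for (seed in 1:220) {
    rd <- random_dip_trace(seed)
    ev <- detect_blinks(rd$trace, p)
    bf <- bf_blink_scan(rd$trace$values, rd$trace$fps,
      thr = 0.7 * 0.3,
      min_dur_ms = p$min_duration_ms, max_dur_ms = p$max_duration_ms
    )
    expect_identical(nrow(ev), nrow(bf))
    if (nrow(bf) > 0L) {
      expect_equal(ev$onset_s, bf$onset_s, tolerance = 1e-9)
      expect_equal(ev$offset_s, bf$offset_s, tolerance = 1e-9)
      expect_equal(ev$duration_ms, bf$duration_ms, tolerance = 1e-9)
      expect_equal(ev$min_ear, bf$min_ear, tolerance = 1e-12)
      checked <- checked + nrow(bf)
    }
  }
  expect_gt(checked, 200)
})

test_that("adding a disjoint dip never decreases the event count", {
  p <- short_params()
  for (seed in 1:30) {
    rd <- random_dip_trace(seed)
    n0 <- nrow(detect_blinks(rd$trace, p))
    # append one more dip in the guaranteed-free tail region
    tr2 <- make_v_trace(30, 100,
      centers = c(rd$centers, 29), bottoms = c(rd$bottoms, 0.05),
      widths_at_thr = c(rd$widths, 0.2)
    )
    n1 <- nrow(detect_blinks(tr2, p))
    expect_gte(n1, n0)
  }
})

test_that("detection is deterministic and flags are consistent", {
  g <- generate_ear_trace(preset_registry()$healthy_eye,
    duration_s = 60, fps = 240, seed = 3
  )
  e1 <- detect_blinks(g$trace)
  e2 <- detect_blinks(g$trace)
  expect_identical(e1, e2)
  expect_true(all(e1$counted))
  expect_true(all(e1$complete <= e1$counted)) # complete is a subset
  expect_true(all(e1$min_ear <= e1$baseline_ear))
  expect_true(all(diff(e1$onset_s) > 0))
  expect_true(all(e1$offset_s > e1$onset_s))
})

test_that("classification thresholds follow the counting and closure rules", {
  p <- detection_params()
  ev <- data.frame(
    min_ear = c(0.02, 0.13, 0.24),
    baseline_ear = c(0.29, 0.24, 0.24)
  )
  got <- classify_blink(ev, p)
  # healthy deep closure: counted and complete
  expect_identical(got$counted, c(TRUE, TRUE, FALSE))
  # acute-palsy partial blink: counted (0.13 <= 0.168) but not complete
  expect_identical(got$complete, c(TRUE, FALSE, FALSE))
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(detection_params(theta_p = 0.9, hysteresis_fraction = 0.8))
  expect_error(detection_params(theta_c = -0.1))
  expect_error(
    detection_params(min_duration_ms = 500, max_duration_ms = 100)
  )
  short <- ear_trace(rep(0.3, 100), fps = 100)
  expect_error(detect_blinks(short, detection_params()),
    class = "blinkr_short_trace_error"
  )
})
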