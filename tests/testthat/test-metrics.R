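no_events <- function() {
  data.frame(
    onset_s = numeric(0), offset_s = numeric(0),
    duration_ms = numeric(0), min_ear = numeric(0),
    baseline_ear = numeric(0), counted = logical(0), complete = logical(0)
  )
}

fake_events <- function(onsets, offsets, min_ear = 0.05, complete = TRUE) {
  data.frame(
    onset_s = onsets, offset_s = offsets,
    duration_ms = (offsets - onsets) * 1000,
    min_ear = min_ear, baseline_ear = 0.3,
    counted = TRUE, complete = complete
  )
}

test_that("blink-free average uses the first seconds of each free interval", {
  flat <- ear_trace(rep(0.3, 2000), fps = 100)
  expect_equal(blink_free_average_ear(flat, no_events()), 0.3)

  # 0.2 during the first 3 s after each blink (and at the start), 0.4
  # elsewhere -> the estimate must be exactly 0.2
  fps <- 100
  t <- (seq_len(30 * fps) - 1) / fps
  ev <- fake_events(c(8, 20), c(8.3, 20.25))
  v <- rep(0.4, length(t))
  for (st in c(0, 8.3, 20.25)) {
    v[t >= st & t < st + 3] <- 0.2
  }
  # blink samples themselves are irrelevant; poison them to prove it
  for (k in seq_len(nrow(ev))) {
    v[t >= ev$onset_s[k] & t < ev$offset_s[k]] <- 9
  }
  tr <- ear_trace(v, fps = fps)
  expect_equal(blink_free_average_ear(tr, ev), 0.2, tolerance = 1e-12)

  # an interval shorter than the window contributes wholly
  ev2 <- fake_events(c(1, 2), c(1.9, 2.5))
  tr2 <- ear_trace(rep(0.25, 10 * fps), fps = fps)
  expect_equal(blink_free_average_ear(tr2, ev2), 0.25)
})

test_that("per-eye summary reduces counts, durations and EAR stats", {
  p <- detection_params()
  flat <- ear_trace(rep(0.3, 240 * 60), fps = 240)
  s <- summarize_eye(flat, no_events(), p)
  expect_identical(s$n_blinks, 0L)
  expect_identical(s$freq_per_min, 0)
  expect_true(is.na(s$mean_duration_ms))
  expect_true(is.na(s$min_ear_blinkmean))
  expect_equal(s$avg_ear, 0.3)
  expect_equal(s$min_ear, 0.3)
  expect_equal(s$max_ear, 0.3)

  # 254 counted events in exactly 20 min -> frequency 12.7 / min
  ons <- seq(0.5, 1199, length.out = 254)
  ev <- fake_events(ons, ons + 0.2)
  tr <- ear_trace(rep(0.3, 240 * 1200), fps = 240)
  s2 <- summarize_eye(tr, ev, p)
  expect_equal(s2$freq_per_min, 12.7)
  expect_equal(s2$n_blinks_20min, 254)

  # 3 events of 180/200/220 ms -> mean duration 200 ms
  ev3 <- fake_events(c(10, 20, 30), c(10, 20, 30) + c(0.18, 0.2, 0.22))
  s3 <- summarize_eye(flat, ev3, p)
  expect_equal(s3$mean_duration_ms, 200)
  expect_identical(s3$n_complete, 3L)
})

test_that("count/frequency consistency holds for any recording length", {
  set.seed(99)
  for (rep in 1:20) {
    tr <- ear_trace(rep(0.3, sample(450:40000, 1)), fps = 10)
    dur <- tr$duration_s
    n_ev <- sample(0:40, 1)
    ons <- sort(runif(n_ev, 0, dur - 1))
    ev <- fake_events(ons, ons + 0.2)
    s <- summarize_eye(tr, ev, detection_params(baseline_window_s = 30))
    expect_equal(s$freq_per_min, s$n_blinks / (s$recording_duration_s / 60),
      tolerance = 1e-9
    )
    expect_equal(s$n_blinks_20min, s$n_blinks * 1200 / dur, tolerance = 1e-9)
    expect_lte(s$n_complete_20min, s$n_blinks_20min)
  }
})

test_that("per-minute binning is half-open and conserves events", {
  ons <- seq(30, 1170, by = 60)
  tc <- per_minute_timecourse(fake_events(ons, ons + 0.2), 1200)
  expect_identical(tc$count, rep(1L, 20))
  expect_equal(sum(tc$count), length(ons))

  # an onset exactly on the minute boundary goes to the later bin
  tc2 <- per_minute_timecourse(fake_events(60, 60.2), 1200)
  expect_identical(tc2$count[1:2], c(0L, 1L))

  tc3 <- per_minute_timecourse(no_events(), 600)
  expect_identical(tc3$count, rep(0L, 10))
  expect_true(all(is.na(tc3$mean_duration_ms)))

  expect_error(
    per_minute_timecourse(fake_events(1300, 1300.2), 1200),
    "outside"
  )

  # conservation for random event sets
  set.seed(4)
  for (rep in 1:10) {
    ons <- sort(runif(sample(1:60, 1), 0, 1199))
    tc <- per_minute_timecourse(fake_events(ons, ons + 0.1), 1200)
    expect_identical(sum(tc$count), length(ons))
  }
})

test_that("recovered metrics approach preset values as recordings lengthen", {
  pre <- preset_registry()$healthy_eye
  p <- detection_params()
  rec <- function(duration_s, seed) {
    g <- generate_ear_trace(pre, duration_s, fps = 240, seed = seed)
    s <- summarize_eye(g$trace, detect_blinks(g$trace, p), p)
    c(freq = s$freq_per_min, dur = s$mean_duration_ms, avg = s$avg_ear)
  }
  seeds <- 31:40
  short <- vapply(seeds, function(s) rec(300, s), numeric(3))
  long <- vapply(seeds, function(s) rec(1200, s), numeric(3))
  # recovery is unbiased at both lengths ...
  expect_equal(mean(short["freq", ]), pre$rate_per_min, tolerance = 0.10)
  expect_equal(mean(long["freq", ]), pre$rate_per_min, tolerance = 0.05)
  expect_equal(mean(long["dur", ]), pre$duration_mean_ms, tolerance = 0.05)
  expect_equal(mean(long["avg", ]), pre$baseline_ear, tolerance = 0.05)
  # ... and the seed-to-seed spread of the recovered rate and duration
  # shrinks with recording length (the recording-global minimum EAR is an
  # extreme statistic and deliberately not part of this check)
  expect_lt(sd(long["freq", ]), sd(short["freq", ]))
  expect_lt(sd(long["dur", ]), sd(short["dur", ]))
})
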