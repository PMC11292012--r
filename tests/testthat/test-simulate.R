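test_that("the preset registry holds the five condition profiles", {
  reg <- preset_registry()
  expect_identical(length(reg), 5L)
  expect_setequal(
    names(reg),
    c("healthy_eye", "acute_paretic", "acute_contra",
      "synk_paretic", "synk_contra")
  )
  expect_identical(reg$healthy_eye$rate_per_min, 12.7)
  for (pre in reg) {
    expect_true(pre$floor_complete >= 0)
    expect_true(pre$floor_complete <= pre$floor_partial)
    expect_lt(pre$floor_partial, 0.7 * pre$baseline_ear)
    expect_true(pre$p_complete >= 0 && pre$p_complete <= 1)
    expect_gt(pre$duration_mean_ms, 0)
    # mean inter-onset interval reproduces the target rate
    expect_equal(60 / (pre$refractory_s + pre$mean_extra_gap_s),
      pre$rate_per_min,
      tolerance = 1e-9
    )
  }
  # floors at or above the counting threshold are rejected
  expect_error(preset_registry(theta_p = 0.3), "counting threshold")
})

test_that("trace generation is seed-deterministic", {
  pre <- preset_registry()$healthy_eye
  a <- generate_ear_trace(pre, 30, 240, seed = 42)
  b <- generate_ear_trace(pre, 30, 240, seed = 42)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$truth, b$truth)
  c <- generate_ear_trace(pre, 30, 240, seed = 43)
  expect_false(identical(a$trace$values, c$trace$values))
})

test_that("a zero-rate preset yields a flat noisy trace with empty truth", {
  pre <- preset_registry()$healthy_eye
  pre$rate_per_min <- 0
  pre$mean_extra_gap_s <- Inf
  pre$max_excursion <- 0
  g <- generate_ear_trace(pre, 60, 240, seed = 1)
  expect_identical(nrow(g$truth), 0L)
  expect_lt(max(abs(g$trace$values - mean(g$trace$values))), 0.1)
  expect_identical(nrow(detect_blinks(g$trace)), 0L)
})

test_that("detector events match generator ground truth one-to-one", {
  p <- detection_params()
  for (nm in names(preset_registry())) {
    pre <- preset_registry()[[nm]]
    g <- generate_ear_trace(pre, 300, 240, seed = 17)
    ev <- detect_blinks(g$trace, p)
    truth <- g$truth
    expect_identical(nrow(ev), nrow(truth))
    matched <- abs(ev$onset_s - truth$onset_s) <= 0.020
    expect_gte(mean(matched), 0.99)
    # completeness classification agrees with the generator's draw wherever
    # the blink floor sits clear of the closure threshold (a floor *at* the
    # threshold, as for synkinetic partial blinks, is a measurement-noise
    # coin flip by construction)
    clear <- abs(truth$floor - p$theta_c) > 0.02
    expect_identical(ev$complete[clear], truth$complete[clear])
  }
})

test_that("synthetic landmarks invert the EAR formula", {
  tr <- ear_trace(c(0.5, 0.25, 0), fps = 100)
  fr <- emit_landmarks(tr, eye_width_px = 4)
  # first frame is the worked landmark set up to symmetry
  eye1 <- matrix(
    c(
      fr$left_p1_x[1], fr$left_p1_y[1], fr$left_p2_x[1], fr$left_p2_y[1],
      fr$left_p3_x[1], fr$left_p3_y[1], fr$left_p4_x[1], fr$left_p4_y[1],
      fr$left_p5_x[1], fr$left_p5_y[1], fr$left_p6_x[1], fr$left_p6_y[1]
    ),
    nrow = 6, ncol = 2, byrow = TRUE
  )
  expect_equal(compute_ear(eye1), 0.5, tolerance = 1e-12)
  expect_equal(compute_fissure_height(eye1), 2, tolerance = 1e-12)
  expect_equal(sqrt(sum((eye1[1, ] - eye1[4, ])^2)), 4, tolerance = 1e-12)
  # closed eye: lid pairs coincide
  expect_identical(fr$left_p2_y[3], fr$left_p6_y[3])

  expect_error(
    emit_landmarks(structure(
      list(
        values = c(0.3, -0.1), fps = 10, side = "left",
        gap_mask = c(FALSE, FALSE), duration_s = 0.2
      ),
      class = "ear_trace"
    )),
    "negative"
  )
})

test_that("fissure_scale scales heights but not the EAR", {
  tr <- ear_trace(rep(c(0.3, 0.28), 50), fps = 100)
  fr <- emit_landmarks(tr, fissure_scale = c(left = 0.96, right = 1))
  traces <- build_ear_traces(fr, fps = 100)
  expect_equal(traces$left$values, traces$right$values, tolerance = 1e-12)
  hp <- fissure_heights(fr, "left")
  hc <- fissure_heights(fr, "right")
  expect_equal(palpebral_height_ratio(hp, hc, fr$time_s), 96,
    tolerance = 1e-9
  )
})

test_that("cohort generation mirrors the study composition", {
  co <- generate_cohort(30, 6, 24, seed = 10)
  expect_identical(nrow(co), 60L)
  expect_identical(sum(co$group == "healthy"), 30L)
  expect_identical(sum(co$group == "acute"), 6L)
  expect_identical(sum(co$group == "synkinesis"), 24L)
  expect_true(all(co$paretic_side[co$group == "healthy"] == "none"))
  expect_true(all(co$paretic_side[co$group != "healthy"] %in%
    c("left", "right")))
  # healthy subjects carry the healthy preset on both eyes
  expect_true(all(co$preset_left[co$group == "healthy"] == "healthy_eye"))
  # patients carry the paretic preset on the paretic side
  pat <- co[co$group == "acute", ]
  expect_true(all(ifelse(pat$paretic_side == "left",
    pat$preset_left, pat$preset_right
  ) == "acute_paretic"))
  # PROM scores respect instrument bounds
  expect_true(all(co$face_total >= 0 & co$face_total <= 100))
  expect_true(all(co$fdi_physical >= -25 & co$fdi_physical <= 100))
  # reproducible
  co2 <- generate_cohort(30, 6, 24, seed = 10)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  expect_error(generate_cohort(-1, 6, 24), class = "blinkr_cohort_error")
})

test_that("the coupling knob injects a monotone blink-PROM dependence", {
  co0 <- generate_cohort(40, 0, 0, seed = 3, coupling = 0)
  r0 <- spearman_prom(co0$rate_multiplier, co0$face_eye_comfort)
  expect_lt(abs(r0$statistic), 0.45)
  co1 <- generate_cohort(40, 0, 0, seed = 3, coupling = 1)
  r1 <- spearman_prom(co1$rate_multiplier, co1$face_eye_comfort)
  expect_gt(r1$statistic, 0.95)
})

test_that("cohort analysis produces one summary per subject and eye", {
  co <- generate_cohort(2, 1, 1, seed = 6)
  sm <- analyze_cohort(co,
    params = detection_params(baseline_window_s = 20),
    duration_s = 60, fps = 120
  )
  expect_identical(nrow(sm), 8L)
  expect_setequal(unique(sm$side), c("left", "right"))
  expect_true(all(sm$freq_per_min >= 0))
  expect_true(all(is.finite(sm$avg_ear)))
})
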