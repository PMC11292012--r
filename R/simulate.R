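#' Synthetic blink generator presets
#'
#' One preset per clinical eye condition, parameterised so that the pipeline
#' recovers the published group profiles of a 20-minute, 240 fps spontaneous
#' blinking recording: an open-eye baseline EAR `baseline_ear`, a blink rate
#' (`rate_per_min`, realised as a renewal process with a refractory period
#' plus an exponential extra gap), a mean blink duration (full width at the
#' detector's counting threshold), the probability of complete closure
#' `p_complete`, and the EAR floors of complete (`floor_complete`) and
#' partial (`floor_partial`) blinks. `fissure_scale` is the palpebral fissure
#' height of the condition relative to a healthy contralateral eye, used by
#' [emit_landmarks()].
#'
#' The five presets:
#' * `healthy_eye` — baseline 0.29, 12.7 blinks/min, 199.7 ms, 58 percent
#'   complete closures (7.4/min), complete floor 0.02, partial floor 0.15;
#' * `acute_paretic` — baseline 0.24, 2.3 blinks/min, 364 ms, no complete
#'   closures, partial floor 0.13, fissure scale 0.96;
#' * `acute_contra` — baseline 0.27, 12.2 blinks/min, 234 ms;
#' * `synk_paretic` — baseline 0.30, 6.6 blinks/min, 240.8 ms, 26 percent
#'   complete (1.7/min), complete floor 0.06, partial floor 0.10, fissure
#'   scale 0.88;
#' * `synk_contra` — baseline 0.32, 11.1 blinks/min, 218.1 ms, 70 percent
#'   complete (7.8/min).
#'
#' @param theta_p Counting-threshold fraction the floors are validated
#'   against (floors must lie strictly below `theta_p * baseline_ear`,
#'   otherwise the preset would generate blinks undetectable by
#'   construction).
#' @return Named list of `blink_preset` objects.
#' @export
preset_registry <- function(theta_p = 0.7) {
  mk <- function(name, b, rate, dur_mean, dur_sd, p_complete, c_c, c_p,
                 max_excursion, fissure_scale = 1) {
    p <- list(
      name = name,
      baseline_ear = b,
      noise_sd = 0.01,
      drift_amplitude = 0.02,
      drift_period_s = 300,
      refractory_s = 0.5,
      rate_per_min = rate,
      mean_extra_gap_s = if (rate > 0) 60 / rate - 0.5 else Inf,
      duration_mean_ms = dur_mean,
      duration_sd_ms = dur_sd,
      duration_min_ms = 60,
      p_complete = p_complete,
      floor_complete = c_c,
      floor_partial = c_p,
      max_excursion = max_excursion,
      excursion_rate_per_min = 1,
      excursion_width_ms = 400,
      fissure_scale = fissure_scale
    )
    validate_preset(p, theta_p)
    structure(p, class = "blink_preset")
  }
  list(
    healthy_eye = mk("healthy_eye",
      b = 0.29, rate = 12.7, dur_mean = 199.7, dur_sd = 40,
      p_complete = 0.58, c_c = 0.02, c_p = 0.15, max_excursion = 0.10
    ),
    acute_paretic = mk("acute_paretic",
      b = 0.24, rate = 2.3, dur_mean = 364, dur_sd = 80,
      p_complete = 0, c_c = 0.02, c_p = 0.13, max_excursion = 0.21,
      fissure_scale = 0.96
    ),
    acute_contra = mk("acute_contra",
      b = 0.27, rate = 12.2, dur_mean = 234, dur_sd = 40,
      p_complete = 0.99, c_c = 0.01, c_p = 0.15, max_excursion = 0.08
    ),
    synk_paretic = mk("synk_paretic",
      b = 0.30, rate = 6.6, dur_mean = 240.8, dur_sd = 50,
      p_complete = 0.26, c_c = 0.06, c_p = 0.10, max_excursion = 0.16,
      fissure_scale = 0.88
    ),
    synk_contra = mk("synk_contra",
      b = 0.32, rate = 11.1, dur_mean = 218.1, dur_sd = 40,
      p_complete = 0.70, c_c = 0.02, c_p = 0.12, max_excursion = 0.16
    )
  )
}

validate_preset <- function(p, theta_p = 0.7) {
  with(p, {
    if (!(floor_complete >= 0 && floor_complete <= floor_partial)) {
      stop_input("preset '%s': need 0 <= floor_complete <= floor_partial", name)
    }
    if (!(floor_partial < theta_p * baseline_ear)) {
      stop_input(
        "preset '%s': floors must lie below the counting threshold %.3f",
        name, theta_p * baseline_ear
      )
    }
    if (p_complete < 0 || p_complete > 1) {
      stop_input("preset '%s': p_complete must be in [0, 1]", name)
    }
    if (duration_mean_ms <= 0 || duration_min_ms <= 0) {
      stop_input("preset '%s': durations must be positive", name)
    }
    if (rate_per_min < 0) stop_input("preset '%s': rate must be >= 0", name)
  })
  invisible(p)
}

#' @export
print.blink_preset <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<blink_preset> %s: baseline %.2f, %.1f blinks/min, ",
      "%.1f ms, p(complete) %.2f, floors %.2f/%.2f\n"
    ),
    x$name, x$baseline_ear, x$rate_per_min, x$duration_mean_ms,
    x$p_complete, x$floor_complete, x$floor_partial
  ))
  invisible(x)
}

# width parameter of the raised-cosine dip whose full width at the level
# theta_p * local-baseline equals the drawn duration
cosine_period <- function(duration_s, baseline_local, floor, theta_p) {
  q <- (1 - theta_p) * baseline_local / (baseline_local - floor)
  if (any(q <= 0 | q >= 1)) {
    stop_input("blink floor at or above the counting threshold")
  }
  duration_s * pi / acos(2 * q - 1)
}

#' Generate a synthetic EAR trace with ground-truth blink events
#'
#' Simulates one eye's EAR signal: blink onsets follow a renewal process
#' (refractory period plus exponential extra gap, matching the preset's mean
#' rate); each blink is a raised-cosine dip from the local (slowly drifting)
#' baseline down to the complete or partial closure floor, scaled so that its
#' full width at the counting threshold `theta_p * baseline` equals the
#' drawn duration; occasional raised-cosine wide-opening excursions and
#' additive Gaussian sample noise are superimposed and the signal is clamped
#' at 0. Blink supports never overlap (an onset falling inside the previous
#' blink's waveform is pushed forward), so every ground-truth event is
#' recoverable one-to-one by the detector.
#'
#' The same `seed` reproduces the trace bit-for-bit.
#'
#' @param preset A `blink_preset` (see [preset_registry()]).
#' @param duration_s Recording length in seconds (default 1200, the
#'   20-minute protocol).
#' @param fps Sampling rate (default 240).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param theta_p Counting-threshold fraction shared with the detector
#'   (default 0.7); the drawn duration is defined at this level.
#' @param rate_multiplier Subject-level multiplier on the blink rate
#'   (default 1), used by the cohort generator.
#' @return A list with `trace` (an [ear_trace()]) and `truth`, a data frame
#'   of ground-truth events (`onset_s`, `offset_s`, `duration_ms`, `floor`,
#'   `complete`).
#' @export
generate_ear_trace <- function(preset, duration_s = 1200, fps = 240,
                               seed = NULL, theta_p = 0.7,
                               rate_multiplier = 1) {
  validate_preset(preset, theta_p)
  if (duration_s <= 0 || fps <= 0) {
    stop_input("duration_s and fps must be positive")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(round(duration_s * fps))
  t <- (seq_len(n) - 1) / fps
  phase <- stats::runif(1, 0, 2 * pi)
  drift <- preset$drift_amplitude *
    sin(2 * pi * t / preset$drift_period_s + phase)
  values <- preset$baseline_ear + drift

  rate <- preset$rate_per_min * rate_multiplier
  truth <- data.frame(
    onset_s = numeric(0), offset_s = numeric(0),
    duration_ms = numeric(0), floor = numeric(0), complete = logical(0)
  )
  gap_margin <- 0.08 # s; keeps supports clear of the detector's merge gap
  if (rate > 0) {
    mean_extra <- max(0.05, 60 / rate - preset$refractory_s)
    tc <- 0
    prev_end <- -Inf
    centers <- floors <- periods <- durs <- numeric(0)
    comps <- logical(0)
    repeat {
      tc <- tc + preset$refractory_s + stats::rexp(1, 1 / mean_extra)
      if (tc >= duration_s) break
      comp <- stats::runif(1) < preset$p_complete
      fl <- if (comp) preset$floor_complete else preset$floor_partial
      d_s <- max(
        preset$duration_min_ms,
        stats::rnorm(1, preset$duration_mean_ms, preset$duration_sd_ms)
      ) / 1000
      b_loc <- preset$baseline_ear + preset$drift_amplitude *
        sin(2 * pi * tc / preset$drift_period_s + phase)
      period <- cosine_period(d_s, b_loc, fl, theta_p)
      if (tc - period / 2 < prev_end + gap_margin) {
        tc <- prev_end + gap_margin + period / 2
      }
      if (tc + period / 2 >= duration_s) break
      centers <- c(centers, tc)
      floors <- c(floors, fl)
      periods <- c(periods, period)
      durs <- c(durs, d_s)
      comps <- c(comps, comp)
      prev_end <- tc + period / 2
    }
    for (k in seq_along(centers)) {
      ia <- max(1L, as.integer(ceiling((centers[k] - periods[k] / 2) * fps)) + 1L)
      ib <- min(n, as.integer(floor((centers[k] + periods[k] / 2) * fps)) + 1L)
      if (ib < ia) next
      idx <- ia:ib
      h <- 0.5 * (1 + cos(2 * pi * (t[idx] - centers[k]) / periods[k]))
      values[idx] <- values[idx] * (1 - h) + floors[k] * h
    }
    truth <- data.frame(
      onset_s = centers - durs / 2,
      offset_s = centers + durs / 2,
      duration_ms = durs * 1000,
      floor = floors,
      complete = comps
    )
  }

  # occasional wide-opening excursions, kept clear of blink supports
  if (preset$max_excursion > 0 && preset$excursion_rate_per_min > 0) {
    n_exc <- stats::rpois(1, preset$excursion_rate_per_min * duration_s / 60)
    if (n_exc > 0) {
      cand <- stats::runif(n_exc, 0, duration_s)
      hts <- stats::runif(n_exc, 0.7, 1) * preset$max_excursion
      wd <- preset$excursion_width_ms / 1000
      for (k in seq_len(n_exc)) {
        if (nrow(truth) > 0L && any(
          cand[k] > truth$onset_s - wd - 0.5 &
            cand[k] < truth$offset_s + wd + 0.5
        )) {
          next
        }
        ia <- max(1L, as.integer(ceiling((cand[k] - wd / 2) * fps)) + 1L)
        ib <- min(n, as.integer(floor((cand[k] + wd / 2) * fps)) + 1L)
        if (ib < ia) next
        idx <- ia:ib
        values[idx] <- values[idx] +
          hts[k] * 0.5 * (1 + cos(2 * pi * (t[idx] - cand[k]) / wd))
      }
    }
  }

  values <- values + stats::rnorm(n, 0, preset$noise_sd)
  values <- pmax(values, 0)
  list(
    trace = ear_trace(values, fps = fps, side = "left"),
    truth = truth
  )
}

#' Emit synthetic landmark frames reproducing an EAR trace
#'
#' Inverse of the EAR computation, for geometry-level round-trip testing:
#' for every sample of the trace it places the six eye landmarks (both eyes)
#' so that [compute_ear()] returns exactly the trace value. The corners sit
#' at distance `eye_width_px * fissure_scale` and the two lid pairs at
#' vertical separation `EAR * eye_width_px * fissure_scale`, symmetric about
#' the corner line; `fissure_scale` is a uniform scale of the whole eye, so
#' the (scale-invariant) EAR is preserved while the absolute palpebral
#' fissure height scales linearly — a narrowed paretic fissure.
#'
#' @param trace An [ear_trace()] with non-negative samples.
#' @param eye_width_px Nominal corner distance in pixels (default 40).
#' @param fissure_scale Length-1 or length-2 (`left`, `right`) uniform scale
#'   factor per eye (default 1).
#' @return A `landmark_frames` table (see [read_landmark_table()]).
#' @examples
#' tr <- ear_trace(c(0.5, 0.3, 0.0), fps = 240)
#' fr <- emit_landmarks(tr, eye_width_px = 4)
#' build_ear_traces(fr, fps = 240)$left$values # 0.5 0.3 0.0
#' @export
emit_landmarks <- function(trace, eye_width_px = 40, fissure_scale = 1) {
  stopifnot(inherits(trace, "ear_trace"))
  if (eye_width_px <= 0) stop_input("eye_width_px must be positive")
  if (any(trace$values < 0)) stop_input("negative EAR sample")
  if (length(fissure_scale) == 1L) {
    fissure_scale <- c(left = fissure_scale, right = fissure_scale)
  }
  if (length(fissure_scale) != 2L || any(fissure_scale <= 0)) {
    stop_input("fissure_scale must be 1 or 2 positive values")
  }
  if (is.null(names(fissure_scale))) {
    names(fissure_scale) <- c("left", "right")
  }
  v <- trace$values
  n <- length(v)
  tab <- data.frame(frame = seq_len(n) - 1L, time_s = trace_times(trace))
  for (side in c("left", "right")) {
    s <- fissure_scale[[side]]
    w <- eye_width_px * s
    sep <- v * w # vertical lid separation; EAR = sep / w
    coords <- list(
      p1 = cbind(0, 0), p4 = cbind(w, 0),
      p2 = cbind(0.25 * w, -sep / 2), p6 = cbind(0.25 * w, sep / 2),
      p3 = cbind(0.75 * w, -sep / 2), p5 = cbind(0.75 * w, sep / 2)
    )
    for (pk in names(coords)) {
      xy <- coords[[pk]]
      if (nrow(xy) == 1L) xy <- xy[rep(1L, n), , drop = FALSE]
      tab[[paste0(side, "_", pk, "_x")]] <- xy[, 1L]
      tab[[paste0(side, "_", pk, "_y")]] <- xy[, 2L]
    }
  }
  as_landmark_frames(tab)
}

prom_profile <- function() {
  # group-wise PROM means/SDs (truncated-normal sampling at the instrument
  # bounds); FaCE domains 0-100, FDI physical -25-100, FDI social 0-100
  list(
    healthy = list(
      face_eye_comfort = c(93.6, 17.6), face_total = c(99.1, 2.4),
      fdi_physical = c(99.2, 2.3), fdi_social = c(84.5, 15.4),
      fdi_total = c(91.9, 7.8)
    ),
    acute = list(
      face_eye_comfort = c(39.6, 29), face_total = c(62.2, 16.5),
      fdi_physical = c(58.3, 15.4), fdi_social = c(74.7, 14.9),
      fdi_total = c(66.5, 11.5)
    ),
    synkinesis = list(
      face_eye_comfort = c(43.2, 36.5), face_total = c(49.8, 21.7),
      fdi_physical = c(62.1, 16.5), fdi_social = c(58.7, 24.7),
      fdi_total = c(60.4, 18.4)
    )
  )
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, pl, ph), mean, sd)
}

prom_bounds <- function(col) {
  if (col == "fdi_physical") c(-25, 100) else c(0, 100)
}

#' Generate a synthetic study cohort
#'
#' Builds a cohort specification mirroring the study composition (default
#' 30 healthy / 6 acute palsy / 24 synkinesis): healthy subjects carry the
#' `healthy_eye` preset on both sides, patients the paretic/contralateral
#' preset pair of their group with the paretic side drawn per the observed
#' side proportions (acute 1/3 left, synkinesis 5/8 left). Each subject gets
#' a lognormal blink-rate multiplier (sdlog 0.7, mean 1) shared by both
#' eyes — spontaneous blink rates vary enormously between people — and
#' per-eye trace seeds, so the whole cohort is reproducible from one seed.
#'
#' PROM scores are drawn from truncated normals with the published group
#' means/SDs, independent of the blink parameters by default. The `coupling`
#' knob (0..1) injects a monotone dependence between a subject's blink-rate
#' multiplier and the FaCE eye-comfort score within each group, for
#' power-testing the correlation analysis: at `coupling = 1` the eye-comfort
#' ranks equal the rate ranks.
#'
#' @param n_healthy,n_acute,n_synk Group sizes (>= 0).
#' @param seed Integer seed.
#' @param coupling Blink-PROM coupling strength in `[0, 1]` (default 0).
#' @param rate_spread_sdlog sdlog of the subject rate multiplier
#'   (default 0.7).
#' @return A `data.frame` of class `blink_cohort`: `subject_id`, `group`,
#'   `paretic_side`, `rate_multiplier`, per-eye preset names and seeds, and
#'   the PROM columns.
#' @export
generate_cohort <- function(n_healthy = 30, n_acute = 6, n_synk = 24,
                            seed = NULL, coupling = 0,
                            rate_spread_sdlog = 0.7) {
  sizes <- c(n_healthy, n_acute, n_synk)
  if (any(sizes < 0)) stop_cohort("group sizes must be >= 0")
  if (coupling < 0 || coupling > 1) stop_input("coupling must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- sum(sizes)
  if (n == 0L) stop_cohort("empty cohort requested")
  group <- rep(c("healthy", "acute", "synkinesis"), sizes)
  paretic <- rep("none", n)
  paretic[group == "acute"] <- sample(c("left", "right"),
    sum(group == "acute"),
    replace = TRUE, prob = c(2, 4)
  )
  paretic[group == "synkinesis"] <- sample(c("left", "right"),
    sum(group == "synkinesis"),
    replace = TRUE, prob = c(15, 9)
  )
  mult <- stats::rlnorm(n,
    meanlog = -rate_spread_sdlog^2 / 2,
    sdlog = rate_spread_sdlog
  )
  pre_par <- ifelse(group == "healthy", "healthy_eye",
    ifelse(group == "acute", "acute_paretic", "synk_paretic")
  )
  pre_con <- ifelse(group == "healthy", "healthy_eye",
    ifelse(group == "acute", "acute_contra", "synk_contra")
  )
  ref <- ifelse(paretic == "none", "left", paretic)
  preset_left <- ifelse(ref == "left", pre_par, pre_con)
  preset_right <- ifelse(ref == "left", pre_con, pre_par)
  eye_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    paretic_side = paretic,
    rate_multiplier = mult,
    preset_left = preset_left,
    preset_right = preset_right,
    seed_left = eye_seeds[seq_len(n)],
    seed_right = eye_seeds[n + seq_len(n)],
    stringsAsFactors = FALSE
  )
  prof <- prom_profile()
  for (col in names(prof$healthy)) {
    v <- numeric(n)
    for (g in unique(group)) {
      sel <- group == g
      ms <- prof[[g]][[col]]
      bounds <- prom_bounds(col)
      v[sel] <- rtruncnorm(sum(sel), ms[1], ms[2], bounds[1], bounds[2])
    }
    meta[[col]] <- v
  }
  if (coupling > 0) {
    for (g in unique(group)) {
      sel <- which(group == g)
      ec <- meta$face_eye_comfort[sel]
      matched <- sort(ec)[rank(mult[sel], ties.method = "first")]
      meta$face_eye_comfort[sel] <-
        (1 - coupling) * ec + coupling * matched
    }
  }
  class(meta) <- c("blink_cohort", "data.frame")
  meta
}

#' @export
print.blink_cohort <- function(x, ...) {
  cat(sprintf(
    "<blink_cohort> %d subjects: %s\n", nrow(x),
    paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Render and analyse a synthetic cohort
#'
#' Runs the full per-eye pipeline over every subject of a cohort
#' specification: each eye's trace is generated from its preset, subject
#' rate multiplier and stored seed, blinks are detected and summarised, and
#' the traces are discarded, keeping memory flat. Use
#' [build_comparison_tables()] on the result for the group reports.
#'
#' @param cohort A `blink_cohort` from [generate_cohort()].
#' @param params [detection_params()] for the detector.
#' @param duration_s,fps Recording geometry per eye (defaults: 20 min at
#'   240 fps).
#' @return A per-eye summary `data.frame`: `subject_id`, `side`, plus all
#'   [summarize_eye()] columns.
#' @export
analyze_cohort <- function(cohort, params = detection_params(),
                           duration_s = 1200, fps = 240) {
  reg <- preset_registry(params$theta_p)
  rows <- vector("list", 2L * nrow(cohort))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (side in c("left", "right")) {
      pre <- reg[[cohort[[paste0("preset_", side)]][i]]]
      g <- generate_ear_trace(
        pre,
        duration_s = duration_s, fps = fps,
        seed = cohort[[paste0("seed_", side)]][i],
        theta_p = params$theta_p,
        rate_multiplier = cohort$rate_multiplier[i]
      )
      tr <- g$trace
      tr$side <- side
      ev <- detect_blinks(tr, params)
      sm <- summarize_eye(tr, ev, params)
      sm <- cbind(subject_id = cohort$subject_id[i], sm)
      k <- k + 1L
      rows[[k]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
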