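#' Eye landmark set
#'
#' Bundles the six eye landmarks used by the eye-aspect-ratio formula into a
#' 6 x 2 matrix with rows `p1` (temporal corner), `p2`/`p6` and `p3`/`p5`
#' (upper/lower lid pairs) and `p4` (nasal corner). Coordinates are in pixels,
#' image convention (origin top-left, y increasing downward); all distances
#' used downstream are absolute, so the y direction is observationally
#' irrelevant.
#'
#' @param p1,p2,p3,p4,p5,p6 Numeric length-2 vectors `(x, y)`.
#' @return A 6 x 2 numeric matrix of class `eye_landmarks`.
#' @examples
#' eye <- eye_landmarks(
#'   p1 = c(0, 0), p2 = c(1, 1), p3 = c(3, 1),
#'   p4 = c(4, 0), p5 = c(3, -1), p6 = c(1, -1)
#' )
#' compute_ear(eye) # 0.5
#' @export
eye_landmarks <- function(p1, p2, p3, p4, p5, p6) {
  pts <- rbind(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6)
  if (ncol(pts) != 2L || !is.numeric(pts)) {
    stop_input("each landmark must be a numeric (x, y) pair")
  }
  if (any(!is.finite(pts))) {
    stop_input("all landmark coordinates must be finite")
  }
  structure(pts, class = c("eye_landmarks", class(pts)))
}

#' Eye aspect ratio of one landmark set
#'
#' EAR is the ratio of the mean vertical lid-landmark distance to the
#' horizontal corner distance:
#' `EAR = (||p2 - p6|| + ||p3 - p5||) / (2 * ||p1 - p4||)`.
#' It is dimensionless, roughly 0.25-0.35 for an open eye, approaches 0 as
#' the lids meet, and is invariant under translation, rotation, and uniform
#' scaling of the landmark set (hence invariant to the eye-camera distance).
#'
#' @param eye An [eye_landmarks()] set (any 6 x 2 numeric matrix in p1..p6
#'   row order is accepted).
#' @return A single non-negative number.
#' @examples
#' eye <- eye_landmarks(
#'   p1 = c(0, 0), p2 = c(1, 1), p3 = c(3, 1),
#'   p4 = c(4, 0), p5 = c(3, -1), p6 = c(1, -1)
#' )
#' compute_ear(eye)       # (2 + 2) / (2 * 4) = 0.5
#' compute_ear(eye * 3)   # unchanged: scale invariant
#' @export
compute_ear <- function(eye) {
  eye <- as_eye_matrix(eye)
  width <- sqrt(sum((eye[1L, ] - eye[4L, ])^2))
  if (width == 0) {
    stop_input("degenerate eye geometry: corner distance ||p1 - p4|| is zero")
  }
  v1 <- sqrt(sum((eye[2L, ] - eye[6L, ])^2))
  v2 <- sqrt(sum((eye[3L, ] - eye[5L, ])^2))
  (v1 + v2) / (2 * width)
}

#' Palpebral fissure height of one landmark set
#'
#' The palpebral fissure is the opening between the eyelids; its height here
#' is the maximal vertical extent between the upper-lid and lower-lid
#' landmarks, i.e. the larger of the two vertical lid-pair separations
#' `|y2 - y6|` and `|y3 - y5|`, in pixels. Unlike the EAR this is an absolute
#' length and scales with the eye geometry.
#'
#' @inheritParams compute_ear
#' @return Height in pixels (>= 0).
#' @export
compute_fissure_height <- function(eye) {
  eye <- as_eye_matrix(eye)
  max(abs(eye[2L, 2L] - eye[6L, 2L]), abs(eye[3L, 2L] - eye[5L, 2L]))
}

as_eye_matrix <- function(eye) {
  if (!is.matrix(eye) || !is.numeric(eye) ||
    nrow(eye) != 6L || ncol(eye) != 2L) {
    stop_input("an eye landmark set must be a numeric 6 x 2 matrix (p1..p6)")
  }
  if (any(!is.finite(eye))) {
    stop_input("all landmark coordinates must be finite")
  }
  eye
}

landmark_cols <- function() {
  eyes <- c("left", "right")
  pts <- paste0("p", 1:6)
  cols <- c(outer(
    eyes, pts,
    function(e, p) paste0(e, "_", p)
  ))
  c(paste0(cols, "_x"), paste0(cols, "_y"))
}

#' Read a per-frame eye landmark table
#'
#' Reads a CSV with one row per video frame and the six eye landmarks per eye
#' in pixel coordinates. Expected header: `frame,time_s` followed by
#' `<eye>_p<k>_x` and `<eye>_p<k>_y` for `eye` in `left`,`right` and
#' `k` in 1..6 (UTF-8, "." decimal separator). A row with any non-finite
#' coordinate is flagged `valid = FALSE`, not dropped, so downstream gap
#' handling can interpolate over it. A depth (`_z`) column, if an upstream
#' face-mesh exporter wrote one, is ignored: the EAR is planar.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `landmark_frames`: columns `frame`,
#'   `time_s`, the 24 coordinate columns, and `valid`.
#' @export
read_landmark_table <- function(path) {
  if (!file.exists(path)) {
    stop_input("landmark file not found: %s", path)
  }
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop_input("cannot parse landmark CSV: %s",
      conditionMessage(e))
  )
  if (nrow(tab) == 0L) {
    stop_input("landmark file is empty: %s", path)
  }
  needed <- c("frame", "time_s", landmark_cols())
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop_input(
      "landmark file is missing required column(s): %s",
      paste(missing, collapse = ", ")
    )
  }
  tab <- tab[order(tab$frame), , drop = FALSE]
  if (any(diff(tab$time_s) <= 0)) {
    stop_input("timestamps must be strictly increasing with frame index")
  }
  as_landmark_frames(tab)
}

as_landmark_frames <- function(tab) {
  coord <- as.matrix(tab[, landmark_cols(), drop = FALSE])
  tab$valid <- apply(is.finite(coord), 1L, all)
  class(tab) <- c("landmark_frames", "data.frame")
  tab
}

#' @export
print.landmark_frames <- function(x, ...) {
  cat(sprintf(
    "<landmark_frames> %d frames (%d valid), %.2f .. %.2f s\n",
    nrow(x), sum(x$valid), min(x$time_s), max(x$time_s)
  ))
  invisible(x)
}

eye_metric_by_frame <- function(frames, side, fun = c("ear", "height")) {
  fun <- match.arg(fun)
  g <- function(k, ax) frames[[paste0(side, "_p", k, "_", ax)]]
  v1 <- abs(g(2, "y") - g(6, "y"))
  v2 <- abs(g(3, "y") - g(5, "y"))
  if (fun == "height") {
    out <- pmax(v1, v2)
  } else {
    d26 <- sqrt((g(2, "x") - g(6, "x"))^2 + (g(2, "y") - g(6, "y"))^2)
    d35 <- sqrt((g(3, "x") - g(5, "x"))^2 + (g(3, "y") - g(5, "y"))^2)
    width <- sqrt((g(1, "x") - g(4, "x"))^2 + (g(1, "y") - g(4, "y"))^2)
    out <- (d26 + d35) / (2 * width)
    out[width == 0] <- NA_real_
  }
  out[!frames$valid] <- NA_real_
  out
}

#' Per-frame palpebral fissure heights
#'
#' Vectorized [compute_fissure_height()] over a landmark frame table; invalid
#' frames yield `NA`.
#'
#' @param frames A `landmark_frames` table (see [read_landmark_table()]).
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of heights in pixels, one per frame.
#' @export
fissure_heights <- function(frames, side = c("left", "right")) {
  side <- match.arg(side)
  eye_metric_by_frame(frames, side, "height")
}

#' Build per-eye EAR traces from landmark frames
#'
#' Computes one EAR sample per frame and eye. Frames flagged invalid (or with
#' degenerate geometry) become gap samples, filled by linear interpolation
#' between the nearest valid neighbours (edge gaps are held at the nearest
#' valid value); the gap mask is preserved on the returned traces for QC.
#'
#' @param frames A `landmark_frames` table.
#' @param fps Nominal sampling rate; must agree with the frame timestamps to
#'   within 1 percent.
#' @return A list with elements `left` and `right`, each an [ear_trace()].
#' @export
build_ear_traces <- function(frames, fps) {
  if (sum(frames$valid) < 2L) {
    stop_input("need at least 2 valid frames to build EAR traces")
  }
  dt <- stats::median(diff(frames$time_s))
  if (abs(dt * fps - 1) > 0.01) {
    stop_input(
      "frame spacing (%.5f s) inconsistent with fps = %g beyond 1%% tolerance",
      dt, fps
    )
  }
  out <- lapply(c(left = "left", right = "right"), function(side) {
    ear <- eye_metric_by_frame(frames, side, "ear")
    gap <- !is.finite(ear)
    if (any(gap)) {
      idx <- seq_along(ear)
      ear[gap] <- stats::approx(idx[!gap], ear[!gap],
        xout = idx[gap], rule = 2
      )$y
    }
    ear_trace(ear, fps = fps, side = side, gap_mask = gap)
  })
  out
}

#' Palpebral fissure height ratio, paretic vs contralateral
#'
#' Ratio (in percent) of the typical blink-free fissure height on the paretic
#' side to the contralateral side, on two height sequences sampled on the
#' same clock. Frames falling inside any blink event of either eye are
#' excluded, and the ratio of medians of the remaining heights is returned;
#' the median makes the estimate robust to residual blink contamination.
#'
#' @param heights_paretic,heights_contra Per-frame fissure heights (pixels)
#'   for the two eyes, equal length.
#' @param time_s Sample times in seconds for both sequences.
#' @param events_paretic,events_contra Blink event tables for the two eyes
#'   (as returned by [detect_blinks()]); `NULL` means no blinks to exclude.
#' @return The percentage `100 * median(paretic) / median(contra)` over
#'   blink-free frames.
#' @export
palpebral_height_ratio <- function(heights_paretic, heights_contra, time_s,
                                   events_paretic = NULL,
                                   events_contra = NULL) {
  n <- length(time_s)
  if (length(heights_paretic) != n || length(heights_contra) != n) {
    stop_input("height sequences and time vector must have equal length")
  }
  in_blink <- rep(FALSE, n)
  for (ev in list(events_paretic, events_contra)) {
    if (is.null(ev) || nrow(ev) == 0L) next
    for (k in seq_len(nrow(ev))) {
      in_blink <- in_blink |
        (time_s >= ev$onset_s[k] & time_s < ev$offset_s[k])
    }
  }
  keep <- !in_blink & is.finite(heights_paretic) & is.finite(heights_contra)
  if (!any(keep)) {
    stop_input("no blink-free frames left to compute the height ratio")
  }
  med_c <- stats::median(heights_contra[keep])
  if (med_c == 0) {
    stop_input("contralateral median fissure height is zero")
  }
  100 * stats::median(heights_paretic[keep]) / med_c
}
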