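#' Construct an EAR trace
#'
#' An `ear_trace` is a uniformly sampled, per-eye eye-openness signal: the eye
#' aspect ratio (EAR) measured once per video frame. It is the central object
#' of the package; blink detection, summary metrics and the synthetic
#' generator all consume or produce it.
#'
#' @param values Numeric vector of EAR samples (dimensionless, >= 0 at every
#'   non-gap sample).
#' @param fps Sampling rate in frames per second (e.g. 240 for high-frame-rate
#'   smartphone video).
#' @param side Which eye the trace belongs to, `"left"` or `"right"`.
#' @param gap_mask Logical vector marking samples that were invalid in the
#'   source video and have been filled by interpolation. Defaults to all
#'   `FALSE`.
#' @return An object of class `ear_trace` with fields `values`, `fps`,
#'   `side`, `gap_mask` and `duration_s` (= `length(values) / fps`).
#' @examples
#' tr <- ear_trace(rep(0.3, 480), fps = 240)
#' tr
#' @export
ear_trace <- function(values, fps, side = c("left", "right"),
                      gap_mask = NULL) {
  side <- match.arg(side)
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_input("an EAR trace needs at least one sample")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_input("'fps' must be a single positive number")
  }
  if (is.null(gap_mask)) {
    gap_mask <- rep(FALSE, length(values))
  }
  gap_mask <- as.logical(gap_mask)
  if (length(gap_mask) != length(values)) {
    stop_input("'gap_mask' must have the same length as 'values'")
  }
  ok <- !gap_mask
  if (any(!is.finite(values[ok])) || any(values[ok] < 0)) {
    stop_input("non-gap EAR samples must be finite and >= 0")
  }
  structure(
    list(
      values = values,
      fps = fps,
      side = side,
      gap_mask = gap_mask,
      duration_s = length(values) / fps
    ),
    class = "ear_trace"
  )
}

#' @export
length.ear_trace <- function(x) length(x$values)

#' Sample times of an EAR trace
#'
#' @param trace An [ear_trace()].
#' @return Numeric vector of sample times in seconds; sample `i` is at
#'   `(i - 1) / fps`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "ear_trace"))
  (seq_along(trace$values) - 1) / trace$fps
}

#' @export
print.ear_trace <- function(x, ...) {
  cat(sprintf(
    "<ear_trace> %s eye: %d samples at %g fps (%.1f s), %d gap sample(s)\n",
    x$side, length(x$values), x$fps, x$duration_s, sum(x$gap_mask)
  ))
  rng <- range(x$values[!x$gap_mask])
  cat(sprintf("  EAR range %.3f .. %.3f\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.ear_trace <- function(x, ..., xlab = "time [s]", ylab = "EAR") {
  graphics::plot(trace_times(x), x$values,
    type = "l", xlab = xlab, ylab = ylab, ...
  )
  if (any(x$gap_mask)) {
    graphics::points(trace_times(x)[x$gap_mask], x$values[x$gap_mask],
      col = "red", pch = 16, cex = 0.4
    )
  }
  invisible(x)
}

#' @export
as.data.frame.ear_trace <- function(x, ...) {
  data.frame(
    time_s = trace_times(x),
    ear = x$values,
    gap = x$gap_mask
  )
}

# condition helpers: the CLI maps these onto its exit-code contract
stop_input <- function(msg, ...) {
  stop(structure(
    class = c("blinkr_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_short_trace <- function(msg, ...) {
  stop(structure(
    class = c("blinkr_short_trace_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_cohort <- function(msg, ...) {
  stop(structure(
    class = c("blinkr_cohort_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
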