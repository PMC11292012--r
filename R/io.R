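#' Write per-eye EAR traces to CSV
#'
#' Header `frame,time_s,ear_left,ear_right,gap_left,gap_right`; gap flags are
#' written as 0/1. Either eye may be absent (its columns are then omitted),
#' e.g. for single-eye simulations.
#'
#' @param traces Named list with elements `left` and/or `right`, each an
#'   [ear_trace()] on the same clock.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ear_csv <- function(traces, path) {
  sides <- intersect(c("left", "right"), names(traces))
  if (length(sides) == 0L) stop_input("no 'left' or 'right' trace to write")
  ref <- traces[[sides[1L]]]
  tab <- data.frame(
    frame = seq_along(ref$values) - 1L,
    time_s = trace_times(ref)
  )
  for (s in sides) {
    tr <- traces[[s]]
    if (length(tr$values) != nrow(tab)) {
      stop_input("left and right traces must have equal length")
    }
    tab[[paste0("ear_", s)]] <- tr$values
    tab[[paste0("gap_", s)]] <- as.integer(tr$gap_mask)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read per-eye EAR traces from CSV
#'
#' Counterpart of [write_ear_csv()]: expects `frame,time_s` plus
#' `ear_<side>` (and optionally `gap_<side>`) for at least one side. The
#' sampling rate is inferred from the median frame spacing unless given.
#'
#' @param path Input CSV path.
#' @param fps Sampling rate; `NULL` infers it from the timestamps.
#' @return Named list of [ear_trace()] objects (elements `left` and/or
#'   `right`).
#' @export
read_ear_csv <- function(path, fps = NULL) {
  if (!file.exists(path)) stop_input("EAR file not found: %s", path)
  tab <- tryCatch(utils::read.csv(path),
    error = function(e) stop_input("cannot parse EAR CSV: %s",
      conditionMessage(e))
  )
  if (nrow(tab) < 2L || !all(c("frame", "time_s") %in% names(tab))) {
    stop_input("EAR CSV needs >= 2 rows and columns frame,time_s")
  }
  if (is.null(fps)) {
    fps <- 1 / stats::median(diff(tab$time_s))
  }
  out <- list()
  for (s in c("left", "right")) {
    col <- paste0("ear_", s)
    if (!col %in% names(tab)) next
    gcol <- paste0("gap_", s)
    gap <- if (gcol %in% names(tab)) as.logical(tab[[gcol]]) else NULL
    out[[s]] <- ear_trace(tab[[col]], fps = fps, side = s, gap_mask = gap)
  }
  if (length(out) == 0L) {
    stop_input("EAR CSV has neither 'ear_left' nor 'ear_right'")
  }
  out
}

#' Write a blink event table to CSV
#'
#' Header `side,onset_s,offset_s,duration_ms,min_ear,baseline_ear,counted,
#' complete`.
#'
#' @param events A `blink_events` data frame (or several rbind-ed together).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c(
    "side", "onset_s", "offset_s", "duration_ms", "min_ear",
    "baseline_ear", "counted", "complete"
  )
  utils::write.csv(as.data.frame(events)[, cols, drop = FALSE], path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a blink event table from CSV
#' @param path Input CSV path.
#' @return A `blink_events` data frame.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_input("events file not found: %s", path)
  as_blink_events(utils::read.csv(path))
}

#' Write a per-minute time course to CSV
#'
#' Header `subject,side,minute,count,mean_duration_ms`.
#'
#' @param timecourse Output of [per_minute_timecourse()].
#' @param path Output file path.
#' @param subject,side Identifier columns prepended to every row.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(timecourse, path, subject = "", side = "") {
  tab <- cbind(subject = subject, side = side, timecourse)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write per-eye summaries to JSON
#'
#' @param summaries Named list (by side) of [summarize_eye()] rows, or a
#'   multi-row summary data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summaries, path) {
  if (is.data.frame(summaries)) {
    summaries <- split(
      as.data.frame(summaries),
      seq_len(nrow(summaries))
    )
    names(summaries) <- vapply(summaries, function(r) r$side, character(1L))
  }
  payload <- lapply(summaries, function(r) as.list(as.data.frame(r)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort metadata table from CSV
#'
#' Expects at least `subject_id,group,paretic_side`; PROM score columns
#' (`face_*`, `fdi_*`) are carried through.
#'
#' @param path Input CSV path.
#' @return A `data.frame`.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop_input("metadata file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "paretic_side")
  if (!all(need %in% names(tab))) {
    stop_input(
      "metadata CSV needs columns: %s",
      paste(need, collapse = ", ")
    )
  }
  tab
}
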