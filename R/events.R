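#' @importFrom rlang abort .data
#' @importFrom stats rexp rpois runif setNames
NULL

# Canonical event vocabulary. The tie rank fixes the order of simultaneous
# events so that a press and its instantaneous pellet delivery classify
# deterministically: press < pellet_delivery < dispenser_cue < foodcup_entry
# < foodcup_exit. CS onsets sort before, CS offsets and session_end after.
EVENT_TYPES <- c(
  cs_onset = 0L,
  press_left = 1L, press_right = 1L,
  pellet_delivery = 2L,
  dispenser_cue = 3L,
  foodcup_entry = 4L,
  foodcup_exit = 5L,
  cs_offset = 6L,
  session_end = 7L
)

SESSION_TYPES <- c(
  "magazine", "instrumental", "pavlovian", "extinction",
  "pit_test", "feedback_test", "devaluation_test"
)

event_rank <- function(event_type) unname(EVENT_TYPES[event_type])

# Stable canonical sort: time, then fixed tie rank.
sort_events <- function(events) {
  events[order(events$time_s, event_rank(events$event_type)), , drop = FALSE]
}

#' Construct a behavioral session log
#'
#' A session log is the canonical container consumed by every analysis
#' function in the package: a time-ordered record of lever presses, food-cup
#' entries/exits, pellet deliveries, dispenser cues and CS onsets/offsets,
#' together with session metadata. Event times are in seconds from session
#' start (t = 0) and are stored at millisecond resolution, which matches the
#' timing granularity of standard operant hardware and makes the CSV
#' round-trip exact.
#'
#' Simultaneous events are ordered by a fixed tie rank (press before
#' pellet_delivery before dispenser_cue before foodcup_entry before
#' foodcup_exit) so downstream classification is deterministic.
#'
#' @param subject_id,session_id Identifier strings.
#' @param session_type One of `"magazine"`, `"instrumental"`, `"pavlovian"`,
#'   `"extinction"`, `"pit_test"`, `"feedback_test"`, `"devaluation_test"`.
#' @param events Data frame with columns `time_s` (numeric), `event_type`
#'   (character) and optionally `arg` (character; cue identity `"CS+"`/`"CS-"`
#'   or lever value tag `"valued"`/`"devalued"`; `""` when unused).
#' @param duration_s Session duration in seconds. If `NULL`, inferred from a
#'   `session_end` event or from the last event time.
#' @param condition_tags Named list of experimental labels (e.g. `group`,
#'   `drug`, `feedback_mode`, `devalued_outcome`).
#' @param validate If `TRUE` (default) run [validate_log()] on the result.
#' @return An object of class `session_log`.
#' @export
#' @examples
#' log <- session_log("r1", "s1", "instrumental",
#'   data.frame(time_s = c(10, 10, 10.4),
#'              event_type = c("press_right", "pellet_delivery", "foodcup_entry")))
#' log
session_log <- function(subject_id, session_id, session_type, events,
                        duration_s = NULL, condition_tags = list(),
                        validate = TRUE) {
  if (!session_type %in% SESSION_TYPES) {
    abort(sprintf("unknown session_type '%s'", session_type),
          class = "operantmicro_validation_error")
  }
  events <- tibble::as_tibble(events)
  if (!"arg" %in% names(events)) events$arg <- ""
  events <- events[, c("time_s", "event_type", "arg")]
  events$arg[is.na(events$arg)] <- ""
  events$time_s <- round(as.numeric(events$time_s), 3)
  events <- sort_events(events)
  if (is.null(duration_s)) {
    end_t <- events$time_s[events$event_type == "session_end"]
    duration_s <- if (length(end_t)) end_t[1] else
      if (nrow(events)) max(events$time_s) else 0
  }
  log <- structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         session_type = session_type,
         condition_tags = condition_tags,
         duration_s = round(duration_s, 3),
         events = events),
    class = "session_log")
  if (validate) validate_log(log) else log
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s / %s (%s), %.1f s, %d events\n",
              x$subject_id, x$session_id, x$session_type,
              x$duration_s, nrow(x$events)))
  if (length(x$condition_tags)) {
    cat("  tags:", paste(names(x$condition_tags), unlist(x$condition_tags),
                         sep = "=", collapse = ", "), "\n")
  }
  tab <- table(x$events$event_type)
  cat("  ", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Validate a session log
#'
#' Checks the structural invariants every downstream computation relies on:
#' event times within `[0, duration_s]`; canonical sort order; at most one
#' `session_end`, located at the session duration; CS windows carrying a cue
#' identity, properly paired and non-overlapping; and strict alternation of
#' food-cup entries and exits (an exit requires a preceding entry; a trailing
#' entry with no exit is allowed, representing cup occupancy at session end).
#'
#' @param log A [session_log()].
#' @return `log`, invisibly unchanged, if all invariants hold; otherwise an
#'   error of class `operantmicro_validation_error`.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "session_log"))
  ev <- log$events
  fail <- function(msg, ...) {
    abort(sprintf("session %s/%s: %s", log$subject_id, log$session_id,
                  sprintf(msg, ...)),
          class = "operantmicro_validation_error")
  }
  bad <- !ev$event_type %in% names(EVENT_TYPES)
  if (any(bad)) fail("unknown event_type '%s'", ev$event_type[which(bad)[1]])
  if (any(ev$time_s < 0)) fail("negative event time")
  if (any(ev$time_s > log$duration_s + 1e-9)) {
    fail("event at %.3f s after session duration %.3f s",
         max(ev$time_s), log$duration_s)
  }
  key <- order(ev$time_s, event_rank(ev$event_type))
  if (is.unsorted(key)) fail("events not in canonical time order")
  ends <- which(ev$event_type == "session_end")
  if (length(ends) > 1) fail("more than one session_end")
  if (length(ends) == 1 && abs(ev$time_s[ends] - log$duration_s) > 1e-9) {
    fail("session_end at %.3f s but duration is %.3f s",
         ev$time_s[ends], log$duration_s)
  }
  # CS windows: onset/offset pairs with matching cue identity, no overlap
  cs <- ev[ev$event_type %in% c("cs_onset", "cs_offset"), ]
  open <- NA_character_
  for (i in seq_len(nrow(cs))) {
    if (!cs$arg[i] %in% c("CS+", "CS-")) {
      fail("%s without cue identity (arg must be 'CS+' or 'CS-')",
           cs$event_type[i])
    }
    if (cs$event_type[i] == "cs_onset") {
      if (!is.na(open)) fail("overlapping CS windows at %.3f s", cs$time_s[i])
      open <- cs$arg[i]
    } else {
      if (is.na(open)) fail("cs_offset at %.3f s with no prior cs_onset",
                            cs$time_s[i])
      if (open != cs$arg[i]) fail("cs_offset cue identity mismatch at %.3f s",
                                  cs$time_s[i])
      open <- NA_character_
    }
  }
  if (!is.na(open)) fail("cs_onset with no matching cs_offset")
  # entry/exit alternation
  cup <- ev$event_type[ev$event_type %in% c("foodcup_entry", "foodcup_exit")]
  occupied <- FALSE
  for (e in cup) {
    if (e == "foodcup_entry") {
      if (occupied) fail("two foodcup_entry events with no intervening exit")
      occupied <- TRUE
    } else {
      if (!occupied) fail("foodcup_exit with no preceding entry")
      occupied <- FALSE
    }
  }
  invisible(log)
}

EVENT_CSV_COLS <- c("subject_id", "session_id", "session_type",
                    "time_s", "event_type", "arg")

#' Read session logs from an event-log CSV
#'
#' The canonical event-log format is a tidy UTF-8 CSV with columns
#' `subject_id, session_id, session_type, time_s, event_type, arg` (one row
#' per event, `arg = ""` when unused). Rows may appear in any order; events
#' are partitioned by `(subject_id, session_id)` and returned in canonical
#' time order. Session durations are taken from `session_end` events, a
#' metadata sidecar, or the last event time, in that order of preference.
#'
#' @param path Path to the CSV file.
#' @param meta_path Optional YAML sidecar holding per-session `duration_s`
#'   and `condition_tags` (as written by [write_events()]).
#' @return A list of [session_log()] objects, one per session.
#' @export
read_events <- function(path, meta_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("event file '%s' does not exist", path),
          class = "operantmicro_io_error")
  }
  raw <- readr::read_csv(path,
                         col_types = readr::cols(
                           .default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing <- setdiff(EVENT_CSV_COLS, names(raw))
  if (length(missing)) {
    abort(sprintf("event file '%s' is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "operantmicro_format_error")
  }
  raw$time_s <- suppressWarnings(as.numeric(raw$time_s))
  if (any(bad <- raw$time_s < 0 | is.na(raw$time_s))) {
    abort(sprintf("invalid time_s at row %d", which(bad)[1]),
          class = "operantmicro_validation_error")
  }
  if (any(bad <- !raw$event_type %in% names(EVENT_TYPES))) {
    abort(sprintf("unknown event_type '%s' at row %d",
                  raw$event_type[which(bad)[1]], which(bad)[1]),
          class = "operantmicro_validation_error")
  }
  meta <- if (!is.null(meta_path) && file.exists(meta_path)) {
    yaml::read_yaml(meta_path)$sessions
  }
  meta_key <- vapply(meta, function(m) {
    paste(m$subject_id, m$session_id, sep = "\r")
  }, character(1))
  keys <- paste(raw$subject_id, raw$session_id, sep = "\r")
  out <- lapply(unique(keys), function(k) {
    rows <- raw[keys == k, ]
    stype <- unique(rows$session_type)
    if (length(stype) != 1) {
      abort(sprintf("session %s has inconsistent session_type",
                    sub("\r", "/", k)),
            class = "operantmicro_validation_error")
    }
    m <- if (length(meta) && k %in% meta_key) meta[[match(k, meta_key)]]
    session_log(
      subject_id = rows$subject_id[1], session_id = rows$session_id[1],
      session_type = stype,
      events = rows[, c("time_s", "event_type", "arg")],
      duration_s = if (!is.null(m)) m$duration_s,
      condition_tags = if (!is.null(m) && length(m$condition_tags)) {
        m$condition_tags
      } else list())
  })
  out
}

#' Write session logs to an event-log CSV
#'
#' Writes the canonical column order with times rendered at fixed 3-decimal
#' precision, so output is bit-stable for fixed input and
#' `read_events(write_events(x))` reproduces `x` exactly.
#'
#' @param logs A [session_log()] or list of them.
#' @param path Output CSV path.
#' @param meta_path Optional path for a YAML sidecar carrying each session's
#'   `duration_s` and `condition_tags` (recommended whenever tags are used).
#' @return `path`, invisibly.
#' @export
write_events <- function(logs, path, meta_path = NULL) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  rows <- purrr::map_dfr(logs, function(log) {
    ev <- log$events
    tibble::tibble(
      subject_id = log$subject_id, session_id = log$session_id,
      session_type = log$session_type,
      time_s = sprintf("%.3f", ev$time_s),
      event_type = ev$event_type, arg = ev$arg)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(subject_id = character(), session_id = character(),
                           session_type = character(), time_s = character(),
                           event_type = character(), arg = character())
  }
  readr::write_csv(rows, path, progress = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(sessions = lapply(logs, function(log) {
      list(subject_id = log$subject_id, session_id = log$session_id,
           duration_s = log$duration_s,
           condition_tags = log$condition_tags)
    }))
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}
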