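# Derived per-experiment measures: CS trial windows, period response tables,
# PIT scores, devaluation tables, Pavlovian conditioning scores, and
# feedback-condition summaries.

#' Extract CS trial windows from a session log
#'
#' Each CS presentation yields a 120 s cue window `(onset, offset]` and its
#' 120 s baseline window `(onset - 120, onset]`. For `pit_test` sessions the
#' canonical structure (8 presentations: 4 CS+ and 4 CS-) is enforced, and
#' an error is raised if a pre-CS window would overlap the preceding CS
#' (impossible under the standard 3-min ITI).
#'
#' @param log A validated [session_log()].
#' @return Tibble with `trial`, `cs_type`, `onset_s`, `offset_s`,
#'   `pre_onset_s`.
#' @export
extract_cs_windows <- function(log) {
  ev <- log$events
  on <- ev[ev$event_type == "cs_onset", ]
  off <- ev[ev$event_type == "cs_offset", ]
  if (nrow(on) != nrow(off)) {
    abort("unpaired CS onset/offset events",
          class = "operantmicro_validation_error")
  }
  win <- tibble::tibble(
    trial = seq_len(nrow(on)),
    cs_type = on$arg,
    onset_s = on$time_s,
    offset_s = off$time_s,
    pre_onset_s = on$time_s - 120)
  if (log$session_type == "pit_test") {
    if (nrow(win) != 8 || sum(win$cs_type == "CS+") != 4) {
      abort(sprintf(
        "pit_test session must contain 4 CS+ and 4 CS- presentations, found %d CS events",
        nrow(win)), class = "operantmicro_validation_error")
    }
  }
  if (nrow(win) > 1 &&
      any(win$pre_onset_s[-1] < win$offset_s[-nrow(win)] - 1e-9)) {
    abort("pre-CS window overlaps the preceding CS presentation",
          class = "operantmicro_validation_error")
  }
  win
}

in_window <- function(times, left, right) times > left & times <= right

#' Per-period response counts around CS presentations
#'
#' Counts presses, press-approach chunks, discrete presses and noncontingent
#' approach-bout starts in the CS and pre-CS periods, summed over the trials
#' of each cue type. Events outside all windows are excluded.
#'
#' @param log A validated [session_log()].
#' @param windows Output of [extract_cs_windows()] for the same log.
#' @param classified Output of [classify_presses()] for the same log.
#' @param cutoff_s Contingency cutoff passed to
#'   [detect_noncontingent_approaches()].
#' @return Tibble keyed by `(subject_id, session_id, cs_type, period)` with
#'   `press_count`, `presses_with_approach`, `presses_without_approach`,
#'   `noncontingent_bouts` and `proportion_with_approach` (`NA` when the
#'   period holds no press).
#' @export
period_response_table <- function(log, windows, classified, cutoff_s = 2.5) {
  bouts <- detect_noncontingent_approaches(log, cutoff_s)
  bout_t <- bouts$start_time_s[!bouts$contingent]
  grid <- tidyr::expand_grid(cs_type = unique(windows$cs_type),
                             period = c("CS", "preCS"))
  rows <- purrr::pmap_dfr(grid, function(cs_type, period) {
    w <- windows[windows$cs_type == cs_type, ]
    left <- if (period == "CS") w$onset_s else w$pre_onset_s
    right <- if (period == "CS") w$offset_s else w$onset_s
    sel <- rep(FALSE, nrow(classified))
    n_bout <- 0L
    for (i in seq_along(left)) {
      sel <- sel | in_window(classified$press_time_s, left[i], right[i])
      n_bout <- n_bout + sum(in_window(bout_t, left[i], right[i]))
    }
    n <- sum(sel)
    n_with <- sum(classified$with_approach[sel])
    tibble::tibble(
      cs_type = cs_type, period = period,
      press_count = n, presses_with_approach = n_with,
      presses_without_approach = n - n_with,
      noncontingent_bouts = n_bout,
      proportion_with_approach = if (n > 0) n_with / n else NA_real_)
  })
  dplyr::bind_cols(
    tibble::tibble(subject_id = log$subject_id, session_id = log$session_id),
    rows)
}

#' PIT score: CS+ minus pre-CS+ presses
#'
#' The focused measure of cue-motivated reward seeking: total presses during
#' CS+ periods minus total presses during pre-CS+ periods (summed over the
#' four CS+ trials), optionally restricted to presses with or without a
#' contingent approach.
#'
#' @param table A [period_response_table()] for one session.
#' @param press_filter `"all"`, `"without_approach"` or `"with_approach"`.
#' @return Integer-valued score (presses). Additivity holds exactly:
#'   `score(all) = score(with_approach) + score(without_approach)`.
#' @export
pit_score <- function(table, press_filter = c("all", "without_approach",
                                              "with_approach")) {
  press_filter <- match.arg(press_filter)
  if (length(unique(paste(table$subject_id, table$session_id))) != 1) {
    abort("pit_score expects a period table for a single session",
          class = "operantmicro_parameter_error")
  }
  col <- switch(press_filter,
                all = "press_count",
                without_approach = "presses_without_approach",
                with_approach = "presses_with_approach")
  cs <- table[[col]][table$cs_type == "CS+" & table$period == "CS"]
  pre <- table[[col]][table$cs_type == "CS+" & table$period == "preCS"]
  if (!length(cs) || !length(pre)) {
    abort("period table lacks CS+ rows", class = "operantmicro_parameter_error")
  }
  sum(cs) - sum(pre)
}

#' Drug-induced change in PIT score
#'
#' @param score_cno,score_vehicle PIT scores for the same subject and press
#'   filter under drug and vehicle.
#' @return `score_cno - score_vehicle` (negative values indicate
#'   suppression of cue-evoked pressing by the drug).
#' @export
cno_suppression <- function(score_cno, score_vehicle) {
  score_cno - score_vehicle
}

#' Devaluation-test response table
#'
#' Extinction-phase (first `phase_end_s` seconds) press counts and
#' proportion-with-approach per lever value, plus the split by press type.
#'
#' @param log A validated devaluation-test [session_log()] with lever value
#'   tags in press `arg`.
#' @param classified Output of [classify_presses()] for the same log.
#' @param phase_end_s End of the nonreinforced phase (default 300 s).
#' @return Tibble keyed by `(subject_id, session_id, lever_value,
#'   press_type)` with `press_count` and `proportion_with_approach`
#'   (populated on the `"all"` rows; `NA` when undefined). Tags from the
#'   log (`drug`, `devalued_outcome`) are carried as columns when present.
#' @export
devaluation_table <- function(log, classified, phase_end_s = 300) {
  cp <- classified[in_window(classified$press_time_s, 0, phase_end_s), ]
  if (nrow(cp) && !all(cp$arg %in% c("valued", "devalued"))) {
    abort("devaluation_table requires lever value tags ('valued'/'devalued')",
          class = "operantmicro_validation_error")
  }
  rows <- tidyr::expand_grid(
    lever_value = c("valued", "devalued"),
    press_type = c("all", "with_approach", "without_approach"))
  rows <- purrr::pmap_dfr(rows, function(lever_value, press_type) {
    sel <- cp$arg == lever_value
    sel <- sel & switch(press_type,
                        all = TRUE,
                        with_approach = cp$with_approach,
                        without_approach = !cp$with_approach)
    n_all <- sum(cp$arg == lever_value)
    tibble::tibble(
      lever_value = lever_value, press_type = press_type,
      press_count = sum(sel),
      proportion_with_approach = if (press_type == "all" && n_all > 0) {
        sum(cp$with_approach & cp$arg == lever_value) / n_all
      } else NA_real_)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = log$subject_id,
                   session_id = log$session_id), rows)
  for (tag in c("drug", "devalued_outcome")) {
    if (!is.null(log$condition_tags[[tag]])) {
      out[[tag]] <- log$condition_tags[[tag]]
    }
  }
  out
}

#' Pavlovian conditioning score
#'
#' Per-trial food-cup entry rates (entries/min) contrasting the early CS
#' period with baseline. To exclude unconditioned (delivery-evoked)
#' responding, the CS rate is computed from cue onset to the first pellet
#' delivery of that trial; trials with no pellet use the full cue window.
#' The baseline rate is computed on the 120 s preceding the onset.
#'
#' @param log A validated Pavlovian [session_log()].
#' @return Tibble with `trial`, `cs_type`, `cs_rate_per_min`,
#'   `pre_rate_per_min`.
#' @export
pavlovian_conditioning_score <- function(log) {
  win <- extract_cs_windows(log)
  ev <- log$events
  entry_t <- ev$time_s[ev$event_type == "foodcup_entry"]
  pellet_t <- ev$time_s[ev$event_type == "pellet_delivery"]
  purrr::pmap_dfr(win, function(trial, cs_type, onset_s, offset_s,
                                pre_onset_s) {
    pel <- pellet_t[in_window(pellet_t, onset_s, offset_s)]
    cs_end <- if (length(pel)) min(pel) else offset_s
    cs_n <- sum(in_window(entry_t, onset_s, cs_end))
    pre_n <- sum(in_window(entry_t, pre_onset_s, onset_s))
    tibble::tibble(
      trial = trial, cs_type = cs_type,
      cs_rate_per_min = cs_n / ((cs_end - onset_s) / 60),
      pre_rate_per_min = pre_n / 2)
  })
}

#' Feedback-condition summary across test sessions
#'
#' Summarizes the three reinforcement-feedback tests (food and cues, cues
#' only, no food or cues) per subject: press counts, press-approach chunk
#' counts and proportion-with-approach, split by reinforcement status. In a
#' no-feedback session every press is nonreinforced by definition.
#'
#' @param logs List of validated [session_log()] objects whose
#'   `condition_tags$feedback_mode` is set (as produced by
#'   [simulate_cohort()] with the `exp1_feedback` script).
#' @param cutoff_s Contingency cutoff passed to [classify_presses()].
#' @return Tibble keyed by `(subject_id, feedback_mode, reinforced)` with
#'   `press_count`, `presses_with_approach`, `proportion_with_approach`.
#' @export
feedback_summary <- function(logs, cutoff_s = 2.5) {
  purrr::map_dfr(logs, function(log) {
    mode <- log$condition_tags$feedback_mode
    if (is.null(mode)) {
      abort(sprintf("session %s/%s lacks a feedback_mode tag",
                    log$subject_id, log$session_id),
            class = "operantmicro_validation_error")
    }
    cp <- classify_presses(log, cutoff_s)
    purrr::map_dfr(c(TRUE, FALSE), function(r) {
      sel <- cp$reinforced == r
      n <- sum(sel)
      tibble::tibble(
        subject_id = log$subject_id, feedback_mode = mode, reinforced = r,
        press_count = n,
        presses_with_approach = sum(cp$with_approach[sel]),
        proportion_with_approach = if (n > 0) {
          sum(cp$with_approach[sel]) / n
        } else NA_real_)
    })
  })
}
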