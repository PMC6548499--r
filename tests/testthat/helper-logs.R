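# Random valid session logs for property tests: presses, feedback events
# tied to a subset of presses, food-cup entries with interleaved exits.
# Times are at millisecond resolution; entry spacing >= 5 ms so exits fit
# strictly between consecutive entries.

random_log <- function(n_events = 100, duration_s = 600, seed = NULL,
                       p_feedback = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  n_press <- max(1, rbinom(1, n_events, 0.45))
  n_entry <- max(1, n_events - n_press)
  press_t <- round(sort(runif(n_press, 0, duration_s)), 3)
  press_t <- press_t[c(TRUE, diff(press_t) >= 0.002)]  # one press per ms
  entry_t <- round(sort(runif(n_entry, 0, duration_s - 1)), 3)
  entry_t <- entry_t[c(TRUE, diff(entry_t) >= 0.005)]
  fed <- runif(length(press_t)) < p_feedback
  exits <- round(entry_t[-length(entry_t)] +
                   diff(entry_t) / 2, 3)
  keep <- exits > entry_t[-length(entry_t)] & exits < entry_t[-1]
  rows <- rbind(
    data.frame(time_s = press_t,
               event_type = sample(c("press_left", "press_right"),
                                   length(press_t), replace = TRUE),
               arg = ""),
    if (any(fed)) data.frame(time_s = press_t[fed],
                             event_type = "pellet_delivery", arg = ""),
    data.frame(time_s = entry_t, event_type = "foodcup_entry", arg = ""),
    if (any(keep)) data.frame(time_s = exits[keep],
                              event_type = "foodcup_exit", arg = ""),
    data.frame(time_s = duration_s, event_type = "session_end", arg = ""))
  session_log(sprintf("sub%03d", sample.int(999, 1)), "s01", "instrumental",
              rows)
}

quiet_pipeline <- function(cfg) {
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
}
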