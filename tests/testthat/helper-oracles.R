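# Independent brute-force oracles, written directly from the verbal
# classification rules and kept deliberately separate from the package
# implementation. brute_classify examines every (press, entry) pair: for
# each press it scans all entries in the cutoff window and, for each
# candidate, explicitly checks that no other press lies strictly between
# press and entry.

brute_classify <- function(log, cutoff_s = 2.5) {
  ev <- log$events
  press <- ev[ev$event_type %in% c("press_left", "press_right"), ]
  entry_t <- ev$time_s[ev$event_type == "foodcup_entry"]
  fb_t <- ev$time_s[ev$event_type %in% c("pellet_delivery", "dispenser_cue")]
  press_t <- press$time_s
  n <- nrow(press)
  reinforced <- logical(n)
  with_approach <- logical(n)
  latency <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- press_t[i]
    reinforced[i] <- any(abs(fb_t - p) < 1e-9)
    gaps <- entry_t - p
    for (j in which(gaps > 0 & gaps <= cutoff_s)) {
      t <- entry_t[j]
      # only if no other press intervened between this press and the entry
      if (!any(press_t > p & press_t < t)) {
        with_approach[i] <- TRUE
        latency[i] <- min(latency[i], gaps[j], na.rm = TRUE)
      }
    }
  }
  data.frame(press_time_s = press_t, reinforced = reinforced,
             with_approach = with_approach, approach_latency_s = latency)
}

# Per-entry episode assignment by sequential application of the rules:
# press within (0, cutoff] before the entry -> press-contingent; within
# cutoff of the previous entry -> continue its episode (a fresh press
# re-anchors a contingent chain); otherwise a new noncontingent bout.
brute_episodes <- function(log, cutoff_s = 2.5) {
  ev <- log$events
  entry_t <- ev$time_s[ev$event_type == "foodcup_entry"]
  press_t <- ev$time_s[ev$event_type %in% c("press_left", "press_right")]
  cat_ <- character(0)
  ep <- integer(0)
  cur <- 0L
  for (i in seq_along(entry_t)) {
    t <- entry_t[i]
    prior_press <- press_t[press_t < t]
    press_close <- length(prior_press) > 0 &&
      (t - max(prior_press)) <= cutoff_s
    prev_close <- i > 1 && (t - entry_t[i - 1]) <= cutoff_s
    if (press_close) {
      cat_[i] <- "contingent"
      same_chain <- prev_close && cat_[i - 1] == "contingent" &&
        max(prior_press) < entry_t[i - 1]
      if (!same_chain) cur <- cur + 1L
    } else if (prev_close) {
      cat_[i] <- cat_[i - 1]
    } else {
      cat_[i] <- "noncontingent"
      cur <- cur + 1L
    }
    ep[i] <- cur
  }
  data.frame(time_s = entry_t, episode = ep,
             contingent = cat_ == "contingent")
}
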