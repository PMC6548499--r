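# Press-approach microstructure: the core event-log computations.
#
# Conventions (used consistently across the package):
#   * "within X s after" means a half-open interval: gap in (0, X].
#   * A food-cup approach is a foodcup_entry event (beam-break onset);
#     foodcup_exit is retained for bout duration but ignored here.
#   * An entry is attributed to the MOST RECENT press, never to an earlier
#     press across an intervening one: the approach completes the
#     immediately preceding press.

press_types <- c("press_left", "press_right")

# CS context of arbitrary times: CS windows are (onset, offset], pre-CS
# windows are (onset - 120, onset]; CS windows take precedence over pre
# windows when they would overlap.
cs_context_of <- function(times, log) {
  ev <- sort_events(log$events)
  on <- ev[ev$event_type == "cs_onset", ]
  ctx <- rep("none", length(times))
  if (nrow(on) == 0 || length(times) == 0) return(ctx)
  off <- ev[ev$event_type == "cs_offset", ]
  for (i in seq_len(nrow(on))) {
    pre <- times > on$time_s[i] - 120 & times <= on$time_s[i] & ctx == "none"
    ctx[pre] <- paste0("pre", on$arg[i])
  }
  for (i in seq_len(nrow(on))) {
    inside <- times > on$time_s[i] & times <= off$time_s[i]
    ctx[inside] <- on$arg[i]
  }
  ctx
}

#' Classify lever presses by reinforcement and contingent approach
#'
#' The central microstructural decomposition: every lever press is annotated
#' with (i) its reinforcement status - whether a pellet delivery or dispenser
#' cue was produced at the press time (in cues-only sessions the dispenser
#' cue alone defines reinforcement) - and (ii) whether it was followed by a
#' press-contingent food-cup approach, i.e. a `foodcup_entry` whose time `t`
#' satisfies `t - press_time` in `(0, cutoff_s]` with no other press
#' intervening. Presses with a contingent approach are press-approach action
#' chunks; presses without are discrete reward-seeking responses.
#'
#' @param log A validated [session_log()].
#' @param cutoff_s Contingency cutoff in seconds (default 2.5, the
#'   conventional bound on the post-press retrieval peak).
#' @return A tibble with one row per press: `press_time_s`, `lever`
#'   (`"left"`/`"right"`), `arg` (lever value tag if assigned), `reinforced`,
#'   `with_approach`, `approach_latency_s` (first attributed entry; `NA` when
#'   none) and `cs_context` (`"CS+"`, `"CS-"`, `"preCS+"`, `"preCS-"`,
#'   `"none"`).
#' @export
#' @examples
#' log <- session_log("r1", "s1", "instrumental", data.frame(
#'   time_s = c(10, 11, 11.5, 20, 23),
#'   event_type = c("press_right", "press_right", "foodcup_entry",
#'                  "press_right", "foodcup_entry")))
#' classify_presses(log)
classify_presses <- function(log, cutoff_s = 2.5) {
  if (cutoff_s < 0) {
    abort("cutoff_s must be non-negative",
          class = "operantmicro_parameter_error")
  }
  ev <- sort_events(log$events)
  is_press <- ev$event_type %in% press_types
  presses <- ev[is_press, ]
  entry_t <- ev$time_s[ev$event_type == "foodcup_entry"]
  fb_t <- ev$time_s[ev$event_type %in% c("pellet_delivery", "dispenser_cue")]

  n <- nrow(presses)
  reinforced <- logical(n)
  with_approach <- logical(n)
  latency <- rep(NA_real_, n)
  if (n > 0) {
    # reinforced = attributed feedback event at the press time (exact tie;
    # times are stored at ms resolution)
    reinforced <- presses$time_s %in% fb_t
    if (length(entry_t)) {
      # most recent press strictly before each entry
      idx <- findInterval(entry_t - 1e-6, presses$time_s)
      gap <- entry_t - presses$time_s[pmax(idx, 1)]
      ok <- idx >= 1 & gap > 0 & gap <= cutoff_s
      ok_idx <- idx[ok]
      ok_gap <- gap[ok]
      first <- !duplicated(ok_idx)  # entries sorted, so first = shortest
      with_approach[ok_idx] <- TRUE
      latency[ok_idx[first]] <- ok_gap[first]
    }
  }
  tibble::tibble(
    subject_id = log$subject_id, session_id = log$session_id,
    press_time_s = presses$time_s,
    lever = sub("press_", "", presses$event_type),
    arg = presses$arg,
    reinforced = reinforced,
    with_approach = with_approach,
    approach_latency_s = latency,
    cs_context = cs_context_of(presses$time_s, log))
}

#' Detect food-cup approach episodes and noncontingent bouts
#'
#' Partitions every `foodcup_entry` into approach episodes. An entry is
#' press-contingent when the most recent press lies within `(0, cutoff_s]`
#' before it (the same rule as [classify_presses()]). An entry within
#' `cutoff_s` of the previous entry continues that entry's episode;
#' otherwise it starts a new one. A new episode whose first entry is not
#' press-contingent is a noncontingent bout: it begins more than `cutoff_s`
#' after the most recent press or approach, the standard operational
#' definition of spontaneous (or cue-evoked) reward retrieval.
#'
#' @param log A validated [session_log()].
#' @param cutoff_s Contingency cutoff in seconds (default 2.5).
#' @return A tibble with one row per episode: `start_time_s`, `n_entries`,
#'   `contingent`. Noncontingent bouts are the rows with
#'   `contingent == FALSE`. The per-entry assignment is available as
#'   attribute `"entries"` (a tibble with `time_s` and `episode` index).
#'   Every entry belongs to exactly one episode, so
#'   `sum(n_entries) == total entries`.
#' @export
detect_noncontingent_approaches <- function(log, cutoff_s = 2.5) {
  ev <- sort_events(log$events)
  entry_t <- ev$time_s[ev$event_type == "foodcup_entry"]
  press_t <- ev$time_s[ev$event_type %in% press_types]
  n <- length(entry_t)
  episode <- integer(n)
  contingent <- logical(n)
  ep_start <- numeric()
  ep_contingent <- logical()
  cur <- 0L
  for (i in seq_len(n)) {
    t <- entry_t[i]
    k <- findInterval(t - 1e-6, press_t)
    press_close <- k >= 1 && (t - press_t[k]) <= cutoff_s
    prev_close <- i > 1 && (t - entry_t[i - 1]) <= cutoff_s
    if (press_close) {
      cont <- TRUE
      # chains onto the previous contingent episode only if uninterrupted
      new_ep <- !(prev_close && contingent[i - 1] &&
                    press_t[k] < entry_t[i - 1])
    } else if (prev_close) {
      cont <- contingent[i - 1]
      new_ep <- FALSE
    } else {
      cont <- FALSE
      new_ep <- TRUE
    }
    if (new_ep || cur == 0L) {
      cur <- cur + 1L
      ep_start[cur] <- t
      ep_contingent[cur] <- cont
    }
    episode[i] <- cur
    contingent[i] <- cont
  }
  out <- tibble::tibble(
    start_time_s = ep_start,
    n_entries = as.integer(tabulate(episode, nbins = length(ep_start))),
    contingent = ep_contingent)
  attr(out, "entries") <- tibble::tibble(time_s = entry_t, episode = episode,
                                         contingent = contingent)
  out
}

#' Peri-event probability of food-cup approach
#'
#' For each alignment event (typically a subset of press times, e.g.
#' reinforced presses), marks which time bins relative to the event contain
#' at least one `foodcup_entry` onset, and reports the fraction of alignment
#' events per bin. Bins are half-open `(left, right]`.
#'
#' @param log A validated [session_log()].
#' @param align_times Numeric vector of alignment event times (seconds). An
#'   empty vector is an error: "no alignment events" is distinguished from a
#'   probability of zero.
#' @param window_s Length-2 window around the event, default `c(-5, 10)`.
#' @param bin_s Bin width in seconds, default 0.5.
#' @return An object of class `peth`: list with `bin_edges_s` (length
#'   `nbin + 1`), `probability` (per-bin fraction in `[0, 1]`) and
#'   `n_events`.
#' @export
peri_event_probability <- function(log, align_times, window_s = c(-5, 10),
                                   bin_s = 0.5) {
  if (length(align_times) == 0) {
    abort("no alignment events: peri-event probability is undefined",
          class = "operantmicro_parameter_error")
  }
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2], bin_s > 0)
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nbin <- length(edges) - 1
  entry_t <- log$events$time_s[log$events$event_type == "foodcup_entry"]
  hit <- matrix(FALSE, length(align_times), nbin)
  for (i in seq_along(align_times)) {
    rel <- entry_t - align_times[i]
    rel <- rel[rel > edges[1] & rel <= edges[nbin + 1]]
    if (length(rel)) {
      k <- ceiling((rel - edges[1]) / bin_s - 1e-9)
      hit[i, unique(pmin(k, nbin))] <- TRUE
    }
  }
  structure(list(bin_edges_s = edges,
                 probability = colMeans(hit),
                 n_events = length(align_times)),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d alignment events, %d bins of %.2f s on (%.1f, %.1f]\n",
              x$n_events, length(x$probability),
              diff(x$bin_edges_s[1:2]), min(x$bin_edges_s),
              max(x$bin_edges_s)))
  cat(sprintf("  peak probability %.3f at (%.1f, %.1f]\n",
              max(x$probability),
              x$bin_edges_s[which.max(x$probability)],
              x$bin_edges_s[which.max(x$probability) + 1]))
  invisible(x)
}

#' Convert a peri-event histogram to a tibble
#'
#' @param x A `peth` object.
#' @param ... Unused.
#' @return Tibble with `bin_left_s`, `bin_right_s`, `probability`.
#' @export
as.data.frame.peth <- function(x, ...) {
  data.frame(bin_left_s = x$bin_edges_s[-length(x$bin_edges_s)],
             bin_right_s = x$bin_edges_s[-1],
             probability = x$probability)
}

#' Proportion of presses followed by a contingent approach
#'
#' The primary normalized measure of press-contingent reward retrieval:
#' among the selected presses, the fraction that were followed by a
#' food-cup approach within the contingency cutoff. When no press is
#' selected the proportion is undefined and `NA` is returned (an empty
#' denominator is not evidence of low retrieval), with the selected count
#' attached.
#'
#' @param classified Output of [classify_presses()].
#' @param selector Optional predicate: a function taking the classified
#'   tibble and returning a logical vector, or a logical vector itself.
#'   Default: all presses.
#' @return A numeric scalar (or `NA` when undefined) with attribute
#'   `n_presses`, the size of the denominator.
#' @export
#' @examples
#' log <- session_log("r1", "s1", "instrumental", data.frame(
#'   time_s = c(10, 10.4, 20), event_type = c("press_right",
#'   "foodcup_entry", "press_right")))
#' cp <- classify_presses(log)
#' proportion_with_approach(cp)
#' proportion_with_approach(cp, function(d) d$reinforced)
proportion_with_approach <- function(classified, selector = NULL) {
  sel <- if (is.null(selector)) {
    rep(TRUE, nrow(classified))
  } else if (is.function(selector)) {
    selector(classified)
  } else {
    selector
  }
  stopifnot(is.logical(sel), length(sel) == nrow(classified))
  n <- sum(sel)
  p <- if (n == 0) NA_real_ else sum(classified$with_approach[sel]) / n
  structure(p, n_presses = n)
}
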