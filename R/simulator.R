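# Virtual-rat session simulator.
#
# The generative model is deliberately minimal: a rat emits lever presses as
# a (possibly CS-modulated) Bernoulli process on a fine time grid; each press
# is followed by a food-cup approach with a probability that depends on
# whether the press produced dispenser feedback (the press-approach "chunk");
# spontaneous food-cup entries arrive as an independent Poisson process.
# Press and approach processes are conditionally independent (no motor
# refractory period), which keeps closed-form Poisson expectations exact.

#' Reinforcement schedule specification
#'
#' @param kind `"CRF"` (continuous reinforcement, identical to RR with
#'   ratio 1), `"RI"` (random interval: a press is reinforced only once a
#'   randomly drawn arming interval has elapsed since the last reinforcer),
#'   `"RR"` (random ratio: each press reinforced independently with
#'   probability `1/parameter`), `"RT"` (random time: response-independent
#'   deliveries at rate `1/parameter`), or `"extinction"` (never reinforced).
#' @param parameter Mean interval in seconds (RI/RT) or ratio (RR). Ignored
#'   for CRF and extinction.
#' @param reward_cap Maximum reinforcers per session (default 20, the
#'   standard session cap for this task). Use `Inf` for no cap.
#' @param feedback_mode What a reinforced press produces: `"food_and_cues"`
#'   (pellet delivery plus dispenser cue), `"cues_only"` (dispenser cue but
#'   no pellet, i.e. delivery into an inaccessible external cup), or
#'   `"no_food_or_cues"` (nothing; behaviorally indistinguishable from
#'   extinction).
#' @param interval_dist RI/RT arming-interval distribution: `"exponential"`
#'   (default; constant-hazard RI) or `"constant"` (degenerate, useful for
#'   deterministic tests).
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(kind = c("RI", "RR", "CRF", "RT", "extinction"),
                          parameter = NULL, reward_cap = 20,
                          feedback_mode = c("food_and_cues", "cues_only",
                                            "no_food_or_cues"),
                          interval_dist = c("exponential", "constant")) {
  kind <- match.arg(kind)
  feedback_mode <- match.arg(feedback_mode)
  interval_dist <- match.arg(interval_dist)
  if (kind == "CRF") {
    kind <- "RR"
    parameter <- 1
  }
  if (kind %in% c("RI", "RR", "RT")) {
    if (is.null(parameter) || parameter <= 0) {
      abort(sprintf("%s schedule requires parameter > 0", kind),
            class = "operantmicro_parameter_error")
    }
  }
  structure(list(kind = kind, parameter = parameter,
                 reward_cap = reward_cap, feedback_mode = feedback_mode,
                 interval_dist = interval_dist),
            class = "schedule_spec")
}

draw_interval <- function(spec) {
  if (spec$interval_dist == "constant") spec$parameter
  else rexp(1, 1 / spec$parameter)
}

#' Initialize schedule state
#'
#' For RI schedules the first arming interval is drawn at session start
#' (t = 0). Consumes random numbers from the current RNG stream.
#'
#' @param spec A [schedule_spec()].
#' @return An opaque state list for [schedule_step()].
#' @export
schedule_init <- function(spec) {
  list(n_reinforced = 0L,
       armed_at = if (spec$kind == "RI") draw_interval(spec) else NA_real_)
}

#' Advance a reinforcement schedule by one press
#'
#' RI: the press is reinforced iff the arming interval has elapsed; on
#' reinforcement a fresh arming interval is drawn from the reinforcement
#' time. RR: reinforced with probability `1/ratio`, independently per press.
#' The reward cap is enforced: after `reward_cap` reinforcers a press is
#' never reinforced.
#'
#' @param spec A [schedule_spec()].
#' @param state State from [schedule_init()] or a previous step.
#' @param press_time Press time in seconds.
#' @return `list(reinforced = logical, state = updated state)`.
#' @export
schedule_step <- function(spec, state, press_time) {
  reinforced <- FALSE
  if (state$n_reinforced < spec$reward_cap) {
    reinforced <- switch(spec$kind,
      RI = press_time >= state$armed_at,
      RR = runif(1) < 1 / spec$parameter,
      RT = FALSE,
      extinction = FALSE)
  }
  if (reinforced) {
    state$n_reinforced <- state$n_reinforced + 1L
    if (spec$kind == "RI") state$armed_at <- press_time + draw_interval(spec)
  }
  list(reinforced = reinforced, state = state)
}

#' Generative parameters of the virtual rat
#'
#' Defaults describe a well-trained rat on a sparse reinforcement schedule:
#' a modest self-paced press rate, near-certain retrieval after dispenser
#' feedback versus sporadic checking after nonreinforced presses, a sharp
#' sub-second press-to-entry latency, and strong multiplicative CS+ effects
#' on both press rate and chunk probability (CS- multipliers are fixed
#' at 1).
#'
#' @param press_rate_per_min Baseline hazard of emitting a press (per min).
#' @param p_chunk_nonreinforced Probability that a nonreinforced, uncued
#'   press is followed by a modeled approach (the spontaneous chunk rate).
#' @param p_approach_feedback Probability that a press with dispenser
#'   feedback (`food_and_cues` or `cues_only`) is followed by an approach.
#' @param approach_latency_mean_s,approach_latency_max_s Mean and truncation
#'   point (seconds) of the truncated-exponential press-to-entry latency.
#' @param background_approach_rate_per_min Poisson rate of spontaneous,
#'   noncontingent food-cup entries (per min).
#' @param cs_press_multiplier,cs_chunk_multiplier Multiplicative CS+ effects
#'   on press hazard and on chunk probability (the latter capped at 1).
#' @param cs_entry_multiplier Multiplicative CS+ effect on the background
#'   entry rate (conditioned food-cup approach).
#' @param deval_press_multiplier_discrete,deval_press_multiplier_chunk
#'   Devaluation suppression factors applied to the devalued lever's press
#'   hazard during extinction testing, separately for discrete presses and
#'   press-approach chunks.
#' @param occupancy_mean_s Mean food-cup occupancy (entry-to-exit) duration.
#' @param time_step_s Simulation time step (seconds).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(press_rate_per_min = 5,
                       p_chunk_nonreinforced = 0.1,
                       p_approach_feedback = 0.9,
                       approach_latency_mean_s = 0.4,
                       approach_latency_max_s = 2.5,
                       background_approach_rate_per_min = 0.5,
                       cs_press_multiplier = 3,
                       cs_chunk_multiplier = 3,
                       cs_entry_multiplier = 3,
                       deval_press_multiplier_discrete = 0.2,
                       deval_press_multiplier_chunk = 0.8,
                       occupancy_mean_s = 1,
                       time_step_s = 0.1,
                       seed = NULL) {
  cfg <- as.list(environment())
  probs <- c("p_chunk_nonreinforced", "p_approach_feedback")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("%s must be in [0, 1]", p),
            class = "operantmicro_parameter_error")
    }
  }
  nonneg <- c("press_rate_per_min", "background_approach_rate_per_min",
              "cs_press_multiplier", "cs_chunk_multiplier",
              "cs_entry_multiplier", "deval_press_multiplier_discrete",
              "deval_press_multiplier_chunk")
  for (p in nonneg) {
    if (cfg[[p]] < 0) {
      abort(sprintf("%s must be >= 0", p),
            class = "operantmicro_parameter_error")
    }
  }
  if (cfg$time_step_s <= 0) {
    abort("time_step_s must be > 0", class = "operantmicro_parameter_error")
  }
  if (cfg$approach_latency_mean_s <= 0 ||
      cfg$approach_latency_max_s <= 0) {
    abort("approach latency parameters must be > 0",
          class = "operantmicro_parameter_error")
  }
  structure(cfg, class = "sim_config")
}

#' Read / write a simulator configuration as YAML
#'
#' Every field is written explicitly so that output files are
#' self-documenting provenance records.
#'
#' @param path YAML file path.
#' @param cfg A [sim_config()].
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals[names(vals) %in% names(formals(sim_config))])
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Truncated exponential latency, bounded away from 0 so a rounded entry
# never ties with its press.
rtruncexp <- function(n, mean, max) {
  u <- runif(n)
  pmax(0.002, -mean * log(1 - u * (1 - exp(-max / mean))))
}

# Turn raw entry times into debounced entry/exit event rows. Entries closer
# than 50 ms to the previous entry are dropped (photobeam debounce); each
# entry gets an exit strictly between it and the next entry (or the session
# end), so the entry/exit alternation invariant holds by construction.
entry_exit_events <- function(entry_times, duration_s, occupancy_mean_s) {
  entry_times <- sort(round(entry_times, 3))
  entry_times <- entry_times[entry_times > 0 & entry_times <= duration_s]
  if (length(entry_times) > 1) {
    keep <- c(TRUE, diff(entry_times) >= 0.05)
    while (!all(keep)) {
      entry_times <- entry_times[keep]
      keep <- c(TRUE, diff(entry_times) >= 0.05)
    }
  }
  n <- length(entry_times)
  if (n == 0) {
    return(tibble::tibble(time_s = numeric(), event_type = character(),
                          arg = character()))
  }
  gap_next <- c(diff(entry_times), Inf)
  occ <- rexp(n, 1 / occupancy_mean_s)
  exits <- pmin(entry_times + occ, entry_times + 0.9 * gap_next, duration_s)
  exits <- round(pmax(exits, entry_times + 0.002), 3)
  ok <- exits > entry_times & exits <= duration_s &
    exits < c(entry_times[-1], Inf)
  tibble::tibble(
    time_s = c(entry_times, exits[ok]),
    event_type = c(rep("foodcup_entry", n), rep("foodcup_exit", sum(ok))),
    arg = "")
}

# Derive a per-session integer seed from (root seed, subject idx, session
# idx); stays far below 2^31 and is injective for session indices < 1009.
derive_seed <- function(seed, subject_idx, session_idx = 1L) {
  (((seed %% 100000) + 1) * 20011 + subject_idx * 1009 + session_idx) %%
    2147483647
}

set_cfg_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' Simulate a self-paced instrumental session
#'
#' Discrete-time scan at `cfg$time_step_s`: at each step a press is emitted
#' with hazard `press_rate_per_min/60 * dt`; each press is run through the
#' reinforcement schedule; reinforced presses emit a pellet and/or dispenser
#' cue at the press time (per `spec$feedback_mode`) and are followed by an
#' approach with probability `p_approach_feedback` at a truncated-exponential
#' latency; nonreinforced presses are followed by an approach with
#' probability `p_chunk_nonreinforced`. Spontaneous entries arrive as an
#' independent Poisson process. The session ends at `duration_s` or shortly
#' after the reward cap is reached (a 5 s grace window lets the terminal
#' retrieval be recorded), whichever comes first.
#'
#' @param cfg A [sim_config()].
#' @param spec A [schedule_spec()].
#' @param duration_s Scheduled session duration (default 1800 s = 30 min).
#' @param subject_id,session_id,session_type,condition_tags Metadata for the
#'   resulting log. `feedback_mode` is added to the tags automatically.
#' @return A validated [session_log()].
#' @export
simulate_instrumental_session <- function(cfg, spec, duration_s = 1800,
                                          subject_id = "rat01",
                                          session_id = "s01",
                                          session_type = "instrumental",
                                          condition_tags = list()) {
  set_cfg_seed(cfg)
  dt <- cfg$time_step_s
  n_step <- floor(duration_s / dt)
  p_press <- cfg$press_rate_per_min / 60 * dt
  press_times <- round(which(runif(n_step) < p_press) * dt, 3)

  state <- schedule_init(spec)
  reinforced <- logical(length(press_times))
  end_t <- duration_s
  keep_upto <- length(press_times)
  for (i in seq_along(press_times)) {
    step <- schedule_step(spec, state, press_times[i])
    state <- step$state
    reinforced[i] <- step$reinforced
    if (step$reinforced && state$n_reinforced >= spec$reward_cap) {
      end_t <- min(duration_s, press_times[i] + 5)
      keep_upto <- i
      break
    }
  }
  press_times <- press_times[seq_len(keep_upto)]
  reinforced <- reinforced[seq_len(keep_upto)]
  # feedback events; in no_food_or_cues mode a "reinforced" press produces
  # nothing and is indistinguishable from a nonreinforced press
  fed <- reinforced & spec$feedback_mode != "no_food_or_cues"
  p_app <- ifelse(fed, cfg$p_approach_feedback, cfg$p_chunk_nonreinforced)
  approach <- runif(length(press_times)) < p_app
  lat <- rtruncexp(length(press_times), cfg$approach_latency_mean_s,
                   cfg$approach_latency_max_s)
  contingent_entries <- press_times[approach] + lat[approach]
  n_bg <- rpois(1, cfg$background_approach_rate_per_min / 60 * end_t)
  entries <- c(contingent_entries, runif(n_bg, 0, end_t))
  entries <- entries[entries <= end_t]

  rows <- list(
    tibble::tibble(time_s = press_times, event_type = "press_right",
                   arg = ""))
  if (spec$feedback_mode == "food_and_cues" && any(fed)) {
    rows <- c(rows, list(
      tibble::tibble(time_s = press_times[fed], event_type = "pellet_delivery",
                     arg = ""),
      tibble::tibble(time_s = press_times[fed], event_type = "dispenser_cue",
                     arg = "")))
  } else if (spec$feedback_mode == "cues_only" && any(fed)) {
    rows <- c(rows, list(
      tibble::tibble(time_s = press_times[fed], event_type = "dispenser_cue",
                     arg = "")))
  }
  rows <- c(rows, list(
    entry_exit_events(entries, end_t, cfg$occupancy_mean_s),
    tibble::tibble(time_s = end_t, event_type = "session_end", arg = "")))
  tags <- condition_tags
  if (is.null(tags$feedback_mode)) tags$feedback_mode <- spec$feedback_mode
  session_log(subject_id, session_id, session_type,
              dplyr::bind_rows(rows), duration_s = end_t,
              condition_tags = tags)
}

#' Simulate a Pavlovian conditioning session
#'
#' `n_trials` presentations of a 2-min auditory CS with onset-to-onset
#' spacing drawn uniformly on 4-6 min. During reinforced (CS+) trials
#' pellets are delivered by a random-time 30 s process (a Poisson process at
#' rate 1/30 per s, giving 4 pellets per trial in expectation); each pellet
#' is retrieved with probability `p_approach_feedback`. Background entries
#' run at `background_approach_rate_per_min`, multiplied by
#' `cs_entry_multiplier` during the CS (conditioned approach).
#'
#' @param cfg A [sim_config()].
#' @param n_trials Number of CS presentations (>= 1).
#' @param reinforced If `TRUE` the cue is a CS+ with pellet deliveries; if
#'   `FALSE` a CS- with none.
#' @param rt_interval_s Mean of the random-time delivery schedule (s).
#' @param subject_id,session_id,condition_tags Metadata.
#' @return A validated [session_log()].
#' @export
simulate_pavlovian_session <- function(cfg, n_trials = 6, reinforced = TRUE,
                                       rt_interval_s = 30,
                                       subject_id = "rat01",
                                       session_id = "s01",
                                       condition_tags = list()) {
  stopifnot(n_trials >= 1)
  set_cfg_seed(cfg)
  cs_dur <- 120
  onsets <- cumsum(runif(n_trials, 240, 360))
  offsets <- onsets + cs_dur
  duration_s <- offsets[n_trials] + 120
  cue <- if (reinforced) "CS+" else "CS-"

  pellets <- numeric()
  if (reinforced) {
    pellets <- unlist(lapply(onsets, function(on) {
      k <- rpois(1, cs_dur / rt_interval_s)
      sort(on + runif(k, 0, cs_dur))
    }))
  }
  in_cs <- function(t) {
    idx <- findInterval(t, onsets)
    idx >= 1 & t <= offsets[pmax(idx, 1)] & t > onsets[pmax(idx, 1)]
  }
  # background entries by thinning of a dominating Poisson process
  rate_max <- cfg$background_approach_rate_per_min / 60 *
    max(1, cfg$cs_entry_multiplier)
  n_cand <- rpois(1, rate_max * duration_s)
  cand <- runif(n_cand, 0, duration_s)
  rate_rel <- ifelse(in_cs(cand), cfg$cs_entry_multiplier, 1) /
    max(1, cfg$cs_entry_multiplier)
  bg_entries <- cand[runif(n_cand) < rate_rel]
  got <- runif(length(pellets)) < cfg$p_approach_feedback
  pellet_entries <- pellets[got] +
    rtruncexp(sum(got), cfg$approach_latency_mean_s,
              cfg$approach_latency_max_s)

  rows <- list(
    tibble::tibble(time_s = onsets, event_type = "cs_onset", arg = cue),
    tibble::tibble(time_s = offsets, event_type = "cs_offset", arg = cue),
    if (length(pellets)) {
      tibble::tibble(time_s = pellets, event_type = "pellet_delivery",
                     arg = "")
    },
    entry_exit_events(c(bg_entries, pellet_entries), duration_s,
                      cfg$occupancy_mean_s),
    tibble::tibble(time_s = duration_s, event_type = "session_end", arg = ""))
  session_log(subject_id, session_id, "pavlovian",
              dplyr::bind_rows(purrr::compact(rows)), duration_s = duration_s,
              condition_tags = condition_tags)
}

# Pseudorandom CS order: seeded permutation with at most two consecutive
# same-type trials (conventional counterbalancing).
pit_trial_order <- function(n_each = 4) {
  repeat {
    ord <- sample(rep(c("CS+", "CS-"), each = n_each))
    runs <- rle(ord)$lengths
    if (max(runs) <= 2) return(ord)
  }
}

#' Simulate a Pavlovian-to-instrumental transfer (PIT) test session
#'
#' 8 min of lead-in extinction with the lever available and no CS, then 8
#' noncontingent cue trials (4 CS+, 4 CS-; 2 min each; 3 min fixed ITI
#' between offset and next onset) in a seeded pseudorandom order with no
#' more than two consecutive same-type trials. The whole session is under
#' extinction: no pellets or dispenser cues. During the CS+ the press hazard
#' is multiplied by `cs_press_multiplier`, the chunk probability by
#' `cs_chunk_multiplier` (capped at 1), and the background entry rate by
#' `cs_entry_multiplier`; CS- multipliers are 1.
#'
#' @param cfg A [sim_config()].
#' @param subject_id,session_id,condition_tags Metadata.
#' @return A validated [session_log()].
#' @export
simulate_pit_session <- function(cfg, subject_id = "rat01",
                                 session_id = "s01",
                                 condition_tags = list()) {
  set_cfg_seed(cfg)
  dt <- cfg$time_step_s
  lead_in <- 480
  cs_dur <- 120
  iti <- 180
  order <- pit_trial_order(4)
  onsets <- lead_in + (cs_dur + iti) * (seq_along(order) - 1)
  offsets <- onsets + cs_dur
  duration_s <- offsets[length(offsets)]

  n_step <- floor(duration_s / dt)
  t_step <- (1:n_step) * dt
  plus_on <- onsets[order == "CS+"]
  in_plus <- function(t) {
    idx <- findInterval(t, plus_on)
    idx >= 1 & t > plus_on[pmax(idx, 1)] & t <= plus_on[pmax(idx, 1)] + cs_dur
  }
  press_mult <- ifelse(in_plus(t_step), cfg$cs_press_multiplier, 1)
  p_press <- cfg$press_rate_per_min / 60 * dt * press_mult
  press_times <- round(t_step[runif(n_step) < p_press], 3)

  p_chunk <- ifelse(in_plus(press_times),
                    pmin(1, cfg$p_chunk_nonreinforced *
                           cfg$cs_chunk_multiplier),
                    cfg$p_chunk_nonreinforced)
  approach <- runif(length(press_times)) < p_chunk
  lat <- rtruncexp(length(press_times), cfg$approach_latency_mean_s,
                   cfg$approach_latency_max_s)
  rate_max <- cfg$background_approach_rate_per_min / 60 *
    max(1, cfg$cs_entry_multiplier)
  n_cand <- rpois(1, rate_max * duration_s)
  cand <- runif(n_cand, 0, duration_s)
  rate_rel <- ifelse(in_plus(cand), cfg$cs_entry_multiplier, 1) /
    max(1, cfg$cs_entry_multiplier)
  entries <- c(press_times[approach] + lat[approach],
               cand[runif(n_cand) < rate_rel])

  rows <- list(
    tibble::tibble(time_s = onsets, event_type = "cs_onset", arg = order),
    tibble::tibble(time_s = offsets, event_type = "cs_offset", arg = order),
    tibble::tibble(time_s = press_times, event_type = "press_right",
                   arg = ""),
    entry_exit_events(entries, duration_s, cfg$occupancy_mean_s),
    tibble::tibble(time_s = duration_s, event_type = "session_end", arg = ""))
  session_log(subject_id, session_id, "pit_test",
              dplyr::bind_rows(rows), duration_s = duration_s,
              condition_tags = condition_tags)
}

#' Simulate an outcome-devaluation test session
#'
#' Two levers are concurrently available, one paired with the devalued
#' outcome. The test begins with a 5-min nonreinforced (extinction) phase,
#' during which the devalued lever's press hazard is suppressed separately
#' by intended press type: the chunked component (`p_chunk_nonreinforced` of
#' the hazard, always followed by an approach) is scaled by
#' `deval_press_multiplier_chunk` and the discrete component by
#' `deval_press_multiplier_discrete`. A 15-min reinforced phase follows, in
#' which each lever is reinforced with its own outcome on CRF for its first
#' five rewards and RR-20 thereafter.
#'
#' @param cfg A [sim_config()].
#' @param devalued_side `"left"` or `"right"`.
#' @param subject_id,session_id,condition_tags Metadata. The devalued side
#'   is recorded in the tags; press and pellet events carry the lever's
#'   value tag (`"valued"`/`"devalued"`) in `arg`.
#' @return A validated [session_log()].
#' @export
simulate_devaluation_session <- function(cfg,
                                         devalued_side = c("left", "right"),
                                         subject_id = "rat01",
                                         session_id = "s01",
                                         condition_tags = list()) {
  devalued_side <- match.arg(devalued_side)
  set_cfg_seed(cfg)
  dt <- cfg$time_step_s
  ext_end <- 300
  duration_s <- 1200
  n_step <- floor(duration_s / dt)
  t_step <- (1:n_step) * dt
  base <- cfg$press_rate_per_min / 60 * dt
  p <- cfg$p_chunk_nonreinforced

  rows <- list()
  entries <- numeric()
  for (side in c("left", "right")) {
    devalued <- side == devalued_side
    tag <- if (devalued) "devalued" else "valued"
    m_chunk <- if (devalued) cfg$deval_press_multiplier_chunk else 1
    m_disc <- if (devalued) cfg$deval_press_multiplier_discrete else 1
    in_ext <- t_step <= ext_end
    # chunked and discrete press components; devaluation scales each only
    # during the extinction phase
    p_chunk_press <- base * p * ifelse(in_ext, m_chunk, 1)
    p_disc_press <- base * (1 - p) * ifelse(in_ext, m_disc, 1)
    u <- runif(n_step)
    is_chunk <- u < p_chunk_press
    is_disc <- !is_chunk & u < p_chunk_press + p_disc_press
    press_t <- round(t_step[is_chunk | is_disc], 3)
    chunked <- is_chunk[is_chunk | is_disc]

    state <- list(n_rewards = 0L)
    reinforced <- logical(length(press_t))
    for (i in seq_along(press_t)) {
      if (press_t[i] <= ext_end) next
      pr <- if (state$n_rewards < 5) 1 else 1 / 20
      if (runif(1) < pr) {
        reinforced[i] <- TRUE
        state$n_rewards <- state$n_rewards + 1L
      }
    }
    p_app <- ifelse(reinforced, cfg$p_approach_feedback,
                    ifelse(chunked, 1, 0))
    approach <- runif(length(press_t)) < p_app
    lat <- rtruncexp(length(press_t), cfg$approach_latency_mean_s,
                     cfg$approach_latency_max_s)
    entries <- c(entries, press_t[approach] + lat[approach])
    rows <- c(rows, list(
      tibble::tibble(time_s = press_t,
                     event_type = paste0("press_", side), arg = tag)))
    if (any(reinforced)) {
      rows <- c(rows, list(
        tibble::tibble(time_s = press_t[reinforced],
                       event_type = "pellet_delivery", arg = tag),
        tibble::tibble(time_s = press_t[reinforced],
                       event_type = "dispenser_cue", arg = tag)))
    }
  }
  n_bg <- rpois(1, cfg$background_approach_rate_per_min / 60 * duration_s)
  entries <- c(entries, runif(n_bg, 0, duration_s))
  rows <- c(rows, list(
    entry_exit_events(entries, duration_s, cfg$occupancy_mean_s),
    tibble::tibble(time_s = duration_s, event_type = "session_end", arg = "")))
  tags <- condition_tags
  tags$devalued_outcome <- devalued_side
  session_log(subject_id, session_id, "devaluation_test",
              dplyr::bind_rows(rows), duration_s = duration_s,
              condition_tags = tags)
}

#' Simulate a cohort under a canonical experiment script
#'
#' Deterministic given `seed`: each session gets an independent substream
#' derived from `(seed, subject index, session index)`. Scripts:
#' \describe{
#'   \item{`exp1_feedback`}{Three 30-min RI-60s test sessions per subject,
#'     one per feedback mode (`food_and_cues`, `cues_only`,
#'     `no_food_or_cues`), in seeded pseudorandom order.}
#'   \item{`exp2_pit`}{One PIT test session per subject and per
#'     configuration (e.g. drug condition).}
#'   \item{`exp3_pit`}{Two PIT test sessions per subject and per
#'     configuration (duplicate tests per drug condition).}
#'   \item{`exp4_devaluation`}{Two devaluation test sessions per subject and
#'     per configuration, alternating the devalued lever.}
#' }
#'
#' @param cfg A [sim_config()], or a named list of them (one per condition,
#'   e.g. `list(vehicle = ..., cno = ...)`); the name is recorded as the
#'   `drug` tag.
#' @param n_subjects Number of subjects.
#' @param script One of `"exp1_feedback"`, `"exp2_pit"`, `"exp3_pit"`,
#'   `"exp4_devaluation"`.
#' @param seed Integer root seed.
#' @return A list of [session_log()] objects.
#' @export
simulate_cohort <- function(cfg, n_subjects, script, seed) {
  scripts <- c("exp1_feedback", "exp2_pit", "exp3_pit", "exp4_devaluation")
  if (!script %in% scripts) {
    abort(sprintf("unknown experiment script '%s'", script),
          class = "operantmicro_parameter_error")
  }
  cfgs <- if (inherits(cfg, "sim_config")) list(none = cfg) else cfg
  stopifnot(length(cfgs) >= 1)
  logs <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("rat%02d", i)
    j <- 0L
    for (cond in names(cfgs)) {
      ccfg <- cfgs[[cond]]
      tags <- if (cond == "none") list() else list(drug = cond)
      if (script == "exp1_feedback") {
        set.seed(derive_seed(seed, i, 1000L))
        modes <- sample(c("food_and_cues", "cues_only", "no_food_or_cues"))
        for (mode in modes) {
          j <- j + 1L
          ccfg$seed <- derive_seed(seed, i, j)
          logs[[length(logs) + 1L]] <- simulate_instrumental_session(
            ccfg, schedule_spec("RI", 60, feedback_mode = mode),
            duration_s = 1800, subject_id = sid,
            session_id = sprintf("s%02d", j),
            session_type = "feedback_test", condition_tags = tags)
        }
      } else if (script %in% c("exp2_pit", "exp3_pit")) {
        n_tests <- if (script == "exp2_pit") 1L else 2L
        for (k in seq_len(n_tests)) {
          j <- j + 1L
          ccfg$seed <- derive_seed(seed, i, j)
          logs[[length(logs) + 1L]] <- simulate_pit_session(
            ccfg, subject_id = sid, session_id = sprintf("s%02d", j),
            condition_tags = c(tags, list(test = k)))
        }
      } else {
        for (side in c("left", "right")) {
          j <- j + 1L
          ccfg$seed <- derive_seed(seed, i, j)
          logs[[length(logs) + 1L]] <- simulate_devaluation_session(
            ccfg, devalued_side = side, subject_id = sid,
            session_id = sprintf("s%02d", j), condition_tags = tags)
        }
      }
    }
  }
  logs
}
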