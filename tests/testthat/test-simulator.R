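test_that("RR-1 (CRF) reinforces every press up to the cap", {
  spec <- schedule_spec("CRF", reward_cap = 3)
  state <- schedule_init(spec)
  out <- logical(5)
  for (i in 1:5) {
    step <- schedule_step(spec, state, i)
    state <- step$state
    out[i] <- step$reinforced
  }
  expect_equal(out, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("RI with constant arming delays is a deterministic state machine", {
  # 60 s arming, presses every 30 s from t=0: reinforced at 60, 120, 180...
  spec <- schedule_spec("RI", 60, reward_cap = Inf,
                        interval_dist = "constant")
  state <- schedule_init(spec)
  press_times <- seq(0, 300, by = 30)
  hits <- numeric(0)
  for (t in press_times) {
    step <- schedule_step(spec, state, t)
    state <- step$state
    if (step$reinforced) hits <- c(hits, t)
  }
  expect_equal(hits, c(60, 120, 180, 240, 300))
})

test_that("RI-60 reinforcer count respects the cap and renewal expectation", {
  # 30-min session, cap 20: count <= 20 always; with presses far denser
  # than the interval, the mean count approaches min(cap, renewal events)
  spec <- schedule_spec("RI", 60, reward_cap = 20)
  counts <- vapply(1:200, function(s) {
    set.seed(s)
    state <- schedule_init(spec)
    n <- 0
    for (t in seq(0.5, 1800, by = 6)) {  # 10 presses/min
      step <- schedule_step(spec, state, t)
      state <- step$state
      n <- n + step$reinforced
    }
    n
  }, numeric(1))
  expect_true(all(counts <= 20))
  # renewal process with ~6 s press spacing: inter-reinforcer gap approx
  # Exp(60) + Unif residual; expectation of min(20, N(1800)) is close to 20
  expect_gt(mean(counts), 17)
  expect_lt(mean(counts), 20.01)
})

test_that("a silent subject produces only the session_end event", {
  cfg <- sim_config(press_rate_per_min = 0,
                    background_approach_rate_per_min = 0, seed = 1)
  log <- simulate_instrumental_session(cfg, schedule_spec("RI", 60))
  expect_equal(nrow(log$events), 1)
  expect_equal(log$events$event_type, "session_end")
})

test_that("forced chunk structure yields proportions 1 and 0 downstream", {
  # sparse pressing with short latencies, so every approach completes
  # before the next press and attribution is unambiguous
  cfg <- sim_config(p_approach_feedback = 1, p_chunk_nonreinforced = 0,
                    background_approach_rate_per_min = 0,
                    approach_latency_mean_s = 0.1,
                    approach_latency_max_s = 0.3, press_rate_per_min = 2,
                    seed = 21)
  log <- simulate_instrumental_session(cfg, schedule_spec("RI", 60))
  cp <- classify_presses(log)
  expect_gt(sum(cp$reinforced), 0)
  expect_equal(as.numeric(proportion_with_approach(
    cp, function(d) d$reinforced)), 1)
  expect_equal(as.numeric(proportion_with_approach(
    cp, function(d) !d$reinforced)), 0)
})

test_that("reward cap truncates the session", {
  cfg <- sim_config(press_rate_per_min = 60, seed = 31)
  log <- simulate_instrumental_session(cfg, schedule_spec("RR", 2,
                                                          reward_cap = 5))
  expect_equal(sum(log$events$event_type == "pellet_delivery"), 5)
  expect_lt(log$duration_s, 1800)
  last_pellet <- max(log$events$time_s[log$events$event_type ==
                                         "pellet_delivery"])
  expect_equal(log$duration_s, min(1800, last_pellet + 5))
})

test_that("cues_only sessions emit dispenser cues but no pellets", {
  cfg <- sim_config(press_rate_per_min = 20, seed = 41)
  log <- simulate_instrumental_session(
    cfg, schedule_spec("RI", 30, feedback_mode = "cues_only"))
  expect_equal(sum(log$events$event_type == "pellet_delivery"), 0)
  expect_gt(sum(log$events$event_type == "dispenser_cue"), 0)
  log2 <- simulate_instrumental_session(
    cfg, schedule_spec("RI", 30, feedback_mode = "no_food_or_cues"))
  expect_equal(sum(log2$events$event_type %in%
                     c("pellet_delivery", "dispenser_cue")), 0)
})

test_that("pavlovian sessions have the scripted CS structure", {
  cfg <- sim_config(seed = 51)
  log <- simulate_pavlovian_session(cfg, n_trials = 6, reinforced = TRUE)
  expect_equal(sum(log$events$event_type == "cs_onset"), 6)
  expect_equal(sum(log$events$event_type == "cs_offset"), 6)
  win <- extract_cs_windows(log)
  expect_true(all(abs(win$offset_s - win$onset_s - 120) < 1e-9))
  spacing <- diff(win$onset_s)
  expect_true(all(spacing >= 240 & spacing <= 360))
  log2 <- simulate_pavlovian_session(cfg, n_trials = 4, reinforced = FALSE)
  expect_equal(sum(log2$events$event_type == "pellet_delivery"), 0)
})

test_that("random-time pellet deliveries average 4 per 2-min CS+ trial", {
  counts <- vapply(1:150, function(s) {
    log <- simulate_pavlovian_session(sim_config(seed = 6000 + s),
                                      n_trials = 2)
    sum(log$events$event_type == "pellet_delivery") / 2
  }, numeric(1))
  # mean of Poisson(4) per trial; 300 trials -> 3 SE ~ 0.35
  expect_lt(abs(mean(counts) - 4), 0.35)
})

test_that("PIT sessions follow the trial script", {
  cfg <- sim_config(press_rate_per_min = 0,
                    background_approach_rate_per_min = 0, seed = 61)
  log <- simulate_pit_session(cfg)
  ev <- log$events
  expect_equal(sum(ev$event_type == "cs_onset"), 8)
  expect_equal(sum(!ev$event_type %in%
                     c("cs_onset", "cs_offset", "session_end")), 0)
  win <- extract_cs_windows(log)
  expect_equal(sum(win$cs_type == "CS+"), 4)
  expect_equal(win$onset_s[1], 480)
  expect_equal(diff(win$onset_s), rep(300, 7))
  # no more than two consecutive same-type trials
  expect_lte(max(rle(win$cs_type)$lengths), 2)
  # extinction: no reinforcement events
  expect_equal(sum(ev$event_type %in% c("pellet_delivery", "dispenser_cue")),
               0)
})

test_that("devaluation sessions script the two phases", {
  cfg <- sim_config(seed = 71)
  log <- simulate_devaluation_session(cfg, "left")
  ev <- log$events
  expect_equal(log$duration_s, 1200)
  # extinction phase is nonreinforced
  pel <- ev$time_s[ev$event_type == "pellet_delivery"]
  expect_true(all(pel > 300))
  expect_setequal(unique(ev$arg[ev$event_type == "press_left"]), "devalued")
  expect_setequal(unique(ev$arg[ev$event_type == "press_right"]), "valued")
  # zero multipliers silence the devalued lever during extinction
  cfg0 <- sim_config(deval_press_multiplier_discrete = 0,
                     deval_press_multiplier_chunk = 0, seed = 72)
  log0 <- simulate_devaluation_session(cfg0, "left")
  dev_press <- log0$events$time_s[log0$events$event_type == "press_left"]
  expect_true(all(dev_press > 300))
})

test_that("null devaluation multipliers leave the levers exchangeable", {
  counts <- purrr::map_dfr(1:60, function(s) {
    cfg <- sim_config(deval_press_multiplier_discrete = 1,
                      deval_press_multiplier_chunk = 1, seed = 8000 + s)
    log <- simulate_devaluation_session(cfg, "left")
    cp <- classify_presses(log)
    cp <- cp[cp$press_time_s <= 300, ]
    tibble::tibble(valued = sum(cp$arg == "valued"),
                   devalued = sum(cp$arg == "devalued"))
  })
  tt <- paired_t(counts$valued, counts$devalued)
  expect_gt(tt$p, 0.01)
})

test_that("cohorts are deterministic and subject streams independent", {
  cfg <- sim_config()
  a <- simulate_cohort(cfg, 2, "exp2_pit", seed = 5)
  b <- simulate_cohort(cfg, 2, "exp2_pit", seed = 5)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$events, a[[2]]$events))
  c2 <- simulate_cohort(cfg, 2, "exp2_pit", seed = 6)
  expect_false(identical(a[[1]]$events, c2[[1]]$events))
})

test_that("exp1 cohorts give each subject one session per feedback mode", {
  logs <- simulate_cohort(sim_config(), 3, "exp1_feedback", seed = 9)
  expect_length(logs, 9)
  modes <- vapply(logs, function(l) l$condition_tags$feedback_mode, "")
  subj <- vapply(logs, `[[`, "", "subject_id")
  for (s in unique(subj)) {
    expect_setequal(modes[subj == s],
                    c("food_and_cues", "cues_only", "no_food_or_cues"))
  }
  expect_error(simulate_cohort(sim_config(), 2, "exp9", seed = 1),
               "unknown experiment script",
               class = "operantmicro_parameter_error")
})

test_that("all simulator outputs pass validation", {
  # validate_log runs inside session_log(); touching each generator here
  cfg <- sim_config(seed = 91)
  expect_s3_class(simulate_instrumental_session(cfg, schedule_spec("RR", 10)),
                  "session_log")
  expect_s3_class(simulate_pavlovian_session(cfg, 3), "session_log")
  expect_s3_class(simulate_pit_session(cfg), "session_log")
  expect_s3_class(simulate_devaluation_session(cfg, "right"), "session_log")
})

test_that("sim_config rejects out-of-range parameters", {
  expect_error(sim_config(p_approach_feedback = 1.2),
               class = "operantmicro_parameter_error")
  expect_error(sim_config(time_step_s = 0),
               class = "operantmicro_parameter_error")
  expect_error(schedule_spec("RI", -5),
               class = "operantmicro_parameter_error")
})

test_that("sim_config YAML round-trips with every field explicit", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- sim_config(press_rate_per_min = 7, seed = 3)
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
  expect_true(all(names(formals(sim_config)) %in%
                    names(yaml::read_yaml(path))))
})
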