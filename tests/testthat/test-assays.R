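# A hand-built PIT-style log used across several assay tests: first CS onset
# at 480 s, alternating cue types, 300 s onset spacing.
pit_fixture <- function() {
  order <- c("CS+", "CS-", "CS+", "CS-", "CS-", "CS+", "CS-", "CS+")
  onsets <- 480 + 300 * (0:7)
  rows <- rbind(
    data.frame(time_s = onsets, event_type = "cs_onset", arg = order),
    data.frame(time_s = onsets + 120, event_type = "cs_offset", arg = order),
    # 3 presses inside CS+ windows (two with an approach), 1 press in
    # pre-CS+ window, 2 presses in CS- windows, 1 press outside everything
    data.frame(time_s = c(490, 490.5, 490.8, 1090, 1091, 1091.3, 1990, 460,
                          790, 1390, 250),
               event_type = c("press_right", "foodcup_entry", "foodcup_exit",
                              "press_right", "foodcup_entry", "foodcup_exit",
                              "press_right", "press_right", "press_right",
                              "press_right", "press_right"),
               arg = ""),
    data.frame(time_s = 2820, event_type = "session_end", arg = ""))
  session_log("r1", "s1", "pit_test", rows, duration_s = 2820)
}

test_that("extract_cs_windows recovers the PIT trial structure", {
  log <- pit_fixture()
  win <- extract_cs_windows(log)
  expect_equal(nrow(win), 8)
  expect_equal(sum(win$cs_type == "CS+"), 4)
  expect_equal(win$pre_onset_s[1], 360)
  expect_equal(win$offset_s - win$onset_s, rep(120, 8))
})

test_that("a malformed PIT log with 7 CS presentations errors", {
  log <- pit_fixture()
  keep <- !(log$events$event_type %in% c("cs_onset", "cs_offset") &
              log$events$time_s >= 2580)
  bad <- session_log("r1", "s1", "pit_test", log$events[keep, ],
                     duration_s = 2820)
  expect_error(extract_cs_windows(bad), "4 CS\\+ and 4 CS-",
               class = "operantmicro_validation_error")
})

test_that("period table counts presses, chunks and bouts by period", {
  log <- pit_fixture()
  win <- extract_cs_windows(log)
  cp <- classify_presses(log)
  tab <- period_response_table(log, win, cp)
  row <- function(type, per) tab[tab$cs_type == type & tab$period == per, ]
  expect_equal(row("CS+", "CS")$press_count, 3)
  expect_equal(row("CS+", "CS")$presses_with_approach, 2)
  expect_equal(row("CS+", "CS")$proportion_with_approach, 2 / 3)
  expect_equal(row("CS+", "preCS")$press_count, 1)
  expect_equal(row("CS-", "CS")$press_count, 2)
  # conservation: in-window + out-of-window presses = total presses
  expect_equal(sum(tab$press_count) + 1, nrow(cp))
  # partition within each row
  expect_equal(tab$presses_with_approach + tab$presses_without_approach,
               tab$press_count)
})

test_that("zero-press logs give zero counts and undefined proportions", {
  log <- pit_fixture()
  keep <- !log$events$event_type %in% c("press_right", "foodcup_entry",
                                        "foodcup_exit")
  empty <- session_log("r1", "s1", "pit_test", log$events[keep, ],
                       duration_s = 2820)
  tab <- period_response_table(empty, extract_cs_windows(empty),
                               classify_presses(empty))
  expect_true(all(tab$press_count == 0))
  expect_true(all(is.na(tab$proportion_with_approach)))
})

test_that("pit_score is the CS+ minus pre-CS+ total and is additive", {
  log <- pit_fixture()
  tab <- period_response_table(log, extract_cs_windows(log),
                               classify_presses(log))
  expect_equal(pit_score(tab, "all"), 3 - 1)
  expect_equal(pit_score(tab, "with_approach") +
                 pit_score(tab, "without_approach"),
               pit_score(tab, "all"))
  # arithmetic on a synthetic table
  tab2 <- tibble::tibble(subject_id = "r", session_id = "s",
                         cs_type = c("CS+", "CS+"),
                         period = c("CS", "preCS"),
                         press_count = c(30, 12),
                         presses_with_approach = c(10, 2),
                         presses_without_approach = c(20, 10))
  expect_equal(pit_score(tab2, "all"), 18)
})

test_that("cno_suppression is an antisymmetric difference", {
  expect_equal(cno_suppression(10, 10), 0)
  expect_equal(cno_suppression(5, 18), -13)
  expect_equal(cno_suppression(3, 7), -cno_suppression(7, 3))
})

test_that("devaluation table uses only the nonreinforced phase", {
  rows <- rbind(
    data.frame(time_s = c(10, 50, 100, 200),
               event_type = c("press_left", "press_left", "press_right",
                              "press_right"),
               arg = c("devalued", "devalued", "valued", "valued")),
    data.frame(time_s = c(10.5, 50.5, 100.5),
               event_type = "foodcup_entry", arg = ""),
    data.frame(time_s = c(10.9, 50.9, 100.9),
               event_type = "foodcup_exit", arg = ""),
    # reinforced-phase presses must not count
    data.frame(time_s = c(400, 500), event_type = "press_right",
               arg = "valued"),
    data.frame(time_s = 1200, event_type = "session_end", arg = ""))
  log <- session_log("r1", "s1", "devaluation_test", rows,
                     duration_s = 1200,
                     condition_tags = list(drug = "vehicle",
                                           devalued_outcome = "left"))
  cp <- classify_presses(log)
  tab <- devaluation_table(log, cp)
  all_rows <- tab[tab$press_type == "all", ]
  expect_equal(all_rows$press_count[all_rows$lever_value == "devalued"], 2)
  expect_equal(all_rows$press_count[all_rows$lever_value == "valued"], 2)
  expect_equal(
    all_rows$proportion_with_approach[all_rows$lever_value == "devalued"], 1)
  expect_equal(
    all_rows$proportion_with_approach[all_rows$lever_value == "valued"], 0.5)
  expect_equal(unique(tab$drug), "vehicle")
})

test_that("asymmetric devaluation raises devalued proportion, lowers counts", {
  # discrete presses suppressed more than chunks: mixture algebra predicts
  # devalued proportion p*mc / (p*mc + (1-p)*md) > p while total falls
  tabs <- purrr::map_dfr(1:40, function(s) {
    cfg <- sim_config(seed = 9000 + s)
    log <- simulate_devaluation_session(cfg, "left")
    devaluation_table(log, classify_presses(log))
  })
  all_rows <- tabs[tabs$press_type == "all", ]
  agg <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$lever_value),
    presses = mean(.data$press_count),
    prop = mean(.data$proportion_with_approach, na.rm = TRUE))
  expect_gt(agg$presses[agg$lever_value == "valued"],
            agg$presses[agg$lever_value == "devalued"])
  expect_gt(agg$prop[agg$lever_value == "devalued"],
            agg$prop[agg$lever_value == "valued"])
})

test_that("pavlovian conditioning score uses onset-to-first-pellet windows", {
  rows <- rbind(
    data.frame(time_s = c(100, 220), event_type = c("cs_onset", "cs_offset"),
               arg = "CS+"),
    data.frame(time_s = 130, event_type = "pellet_delivery", arg = ""),
    data.frame(time_s = c(105, 110, 120, 140),
               event_type = "foodcup_entry", arg = ""),
    data.frame(time_s = 400, event_type = "session_end", arg = ""))
  rows$event_type <- as.character(rows$event_type)
  # interleave exits to satisfy alternation
  exits <- data.frame(time_s = c(106, 111, 121, 141),
                      event_type = "foodcup_exit", arg = "")
  log <- session_log("r1", "s1", "pavlovian", rbind(rows, exits),
                     duration_s = 400)
  sc <- pavlovian_conditioning_score(log)
  # 3 entries between onset (100) and first pellet (130): 3 / 0.5 min
  expect_equal(sc$cs_rate_per_min, 6)
  expect_equal(sc$pre_rate_per_min, 0)

  # entries only after the first pellet: CS rate 0
  rows2 <- rbind(
    data.frame(time_s = c(100, 220), event_type = c("cs_onset", "cs_offset"),
               arg = "CS+"),
    data.frame(time_s = 110, event_type = "pellet_delivery", arg = ""),
    data.frame(time_s = 150, event_type = "foodcup_entry", arg = ""),
    data.frame(time_s = 400, event_type = "session_end", arg = ""))
  expect_equal(pavlovian_conditioning_score(
    session_log("r1", "s1", "pavlovian", rows2,
                duration_s = 400))$cs_rate_per_min, 0)

  # no entries anywhere: both rates 0
  rows3 <- rows2[rows2$event_type != "foodcup_entry", ]
  sc3 <- pavlovian_conditioning_score(
    session_log("r1", "s1", "pavlovian", rows3, duration_s = 400))
  expect_equal(sc3$cs_rate_per_min, 0)
  expect_equal(sc3$pre_rate_per_min, 0)
})

test_that("feedback summary has the three-test structure", {
  logs <- simulate_cohort(sim_config(), 2, "exp1_feedback", seed = 13)
  fb <- feedback_summary(logs)
  expect_equal(nrow(fb), 12)  # 2 subjects x 3 modes x reinforced status
  nf <- fb[fb$feedback_mode == "no_food_or_cues", ]
  expect_true(all(nf$press_count[nf$reinforced] == 0))
  # hand-built session totals reproduce by direct count
  one <- logs[[1]]
  cp <- classify_presses(one)
  row <- fb[fb$subject_id == one$subject_id &
              fb$feedback_mode == one$condition_tags$feedback_mode &
              fb$reinforced, ]
  expect_equal(row$press_count, sum(cp$reinforced))
  expect_equal(row$presses_with_approach,
               sum(cp$reinforced & cp$with_approach))
})

test_that("dispenser cue alone drives classification like pellet feedback", {
  base <- data.frame(
    time_s = c(10, 10.3, 30), event_type = c("press_right", "foodcup_entry",
                                             "press_right"), arg = "")
  with_pellet <- rbind(base, data.frame(time_s = 10,
                                        event_type = "pellet_delivery",
                                        arg = ""))
  with_cue <- rbind(base, data.frame(time_s = 10,
                                     event_type = "dispenser_cue", arg = ""))
  cp1 <- classify_presses(session_log("r", "s", "feedback_test", with_pellet,
                                      duration_s = 40))
  cp2 <- classify_presses(session_log("r", "s", "feedback_test", with_cue,
                                      duration_s = 40))
  expect_equal(cp1$reinforced, cp2$reinforced)
  expect_equal(cp1$with_approach, cp2$with_approach)
})
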