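# End-to-end orchestration: simulate (or load) -> classify -> assay ->
# stats, with a reproducible report bundle written to disk.

#' Configure a pipeline run
#'
#' Either a simulator configuration (events are generated under the named
#' experiment script) or a path to an existing event-log CSV must be given,
#' not both.
#'
#' @param script Experiment script label (see [simulate_cohort()]); required
#'   when simulating, and used to choose the assay set.
#' @param sim A [sim_config()] or named list of them; `NULL` when reading
#'   events from disk.
#' @param events_path Path to an event-log CSV; `NULL` when simulating.
#' @param meta_path Optional metadata sidecar for `events_path`.
#' @param n_subjects Cohort size when simulating.
#' @param cutoff_s Contingency cutoff (seconds).
#' @param peth_window,peth_bin Peri-event histogram settings.
#' @param fit_models Fit the Poisson mixed count model on PIT period tables
#'   (skipped for tiny cohorts regardless).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer root seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(script, sim = NULL, events_path = NULL,
                       meta_path = NULL, n_subjects = 8, cutoff_s = 2.5,
                       peth_window = c(-5, 10), peth_bin = 0.5,
                       fit_models = TRUE, out_dir = tempfile("opmicro_run"),
                       seed = 1L) {
  if (is.null(sim) == is.null(events_path)) {
    abort("exactly one of `sim` and `events_path` must be given",
          class = "operantmicro_parameter_error")
  }
  structure(list(script = script, sim = sim, events_path = events_path,
                 meta_path = meta_path, n_subjects = n_subjects,
                 cutoff_s = cutoff_s, peth_window = peth_window,
                 peth_bin = peth_bin, fit_models = fit_models,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "operantmicro_pipeline_error")
  })
}

cfg_echo <- function(cfg) {
  sim <- cfg$sim
  sim_list <- if (is.null(sim)) NULL
  else if (inherits(sim, "sim_config")) list(default = unclass(sim))
  else lapply(sim, unclass)
  list(script = cfg$script, events_path = cfg$events_path,
       n_subjects = cfg$n_subjects, cutoff_s = cfg$cutoff_s,
       peth_window = cfg$peth_window, peth_bin = cfg$peth_bin,
       seed = cfg$seed, sim = sim_list)
}

#' Run the analysis pipeline end to end
#'
#' Simulates (or loads) a cohort of session logs, classifies every press,
#' computes the script-appropriate assay tables (feedback summaries, PIT
#' period tables and scores, devaluation tables), optionally fits the
#' Poisson count model, and writes a report bundle: `events.csv`,
#' `classified.csv`, per-assay CSV tables and a machine-readable
#' `summary.json` that echoes the configuration. Deterministic given the
#' seed: the same configuration produces byte-identical summaries. Warnings
#' are emitted for undefined proportions, small cohorts and non-converged
#' fits; any stage failure aborts with a stage-named error.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `logs`, `classified`, assay `tables`, any
#'   `fits`, the `summary` list and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  note <- function(...) message(sprintf("[%s] %s", cfg$script, sprintf(...)))

  logs <- stage("events", {
    if (!is.null(cfg$events_path)) {
      read_events(cfg$events_path, cfg$meta_path)
    } else {
      simulate_cohort(cfg$sim, cfg$n_subjects, cfg$script, cfg$seed)
    }
  })
  note("%d sessions", length(logs))
  if (cfg$n_subjects < 4) {
    warning("small cohort (n_subjects < 4): group statistics unstable",
            call. = FALSE)
  }
  stage("write_events", write_events(
    logs, file.path(cfg$out_dir, "events.csv"),
    file.path(cfg$out_dir, "sessions.yaml")))

  classified <- stage("classify", purrr::map(logs, classify_presses,
                                             cutoff_s = cfg$cutoff_s))
  all_cp <- dplyr::bind_rows(classified)
  readr::write_csv(all_cp, file.path(cfg$out_dir, "classified.csv"),
                   progress = FALSE)
  note("%d presses classified (%d with approach)", nrow(all_cp),
       sum(all_cp$with_approach))

  tables <- list()
  fits <- list()
  summary <- list(config = cfg_echo(cfg),
                  n_sessions = length(logs), n_presses = nrow(all_cp))

  if (cfg$script == "exp1_feedback") {
    tables$feedback <- stage("assay", feedback_summary(logs, cfg$cutoff_s))
    fb <- tables$feedback
    fc <- fb[fb$feedback_mode %in% c("food_and_cues", "cues_only"), ]
    wide <- tidyr::pivot_wider(
      fc[, c("subject_id", "feedback_mode", "reinforced",
             "proportion_with_approach")],
      names_from = "reinforced", values_from = "proportion_with_approach")
    ok <- stats::complete.cases(wide)
    if (sum(ok) >= 2) {
      tt <- paired_t(sqrt_prop(wide$`TRUE`[ok]), sqrt_prop(wide$`FALSE`[ok]))
      summary$reinforced_vs_nonreinforced_t <- tt
    }
    summary$mean_prop_reinforced <- mean(
      fb$proportion_with_approach[fb$reinforced &
                                    fb$feedback_mode != "no_food_or_cues"],
      na.rm = TRUE)
    summary$mean_prop_nonreinforced <- mean(
      fb$proportion_with_approach[!fb$reinforced], na.rm = TRUE)
    # peri-press approach probability, pooled over food_and_cues sessions
    fa_logs <- logs[purrr::map_chr(logs, ~ .x$condition_tags$feedback_mode) ==
                      "food_and_cues"]
    peth_tab <- purrr::map_dfr(seq_along(fa_logs), function(i) {
      cp <- classify_presses(fa_logs[[i]], cfg$cutoff_s)
      purrr::map_dfr(c(TRUE, FALSE), function(r) {
        times <- cp$press_time_s[cp$reinforced == r]
        if (!length(times)) return(NULL)
        pe <- peri_event_probability(fa_logs[[i]], times,
                                     cfg$peth_window, cfg$peth_bin)
        dplyr::mutate(as.data.frame(pe),
                      subject_id = fa_logs[[i]]$subject_id,
                      reinforced = r, n_events = pe$n_events)
      })
    })
    tables$peth <- tibble::as_tibble(peth_tab)
  } else if (cfg$script %in% c("exp2_pit", "exp3_pit")) {
    tables$periods <- stage("assay", purrr::map_dfr(
      seq_along(logs), function(i) {
        win <- extract_cs_windows(logs[[i]])
        tab <- period_response_table(logs[[i]], win, classified[[i]],
                                     cfg$cutoff_s)
        for (tag in c("drug", "test")) {
          if (!is.null(logs[[i]]$condition_tags[[tag]])) {
            tab[[tag]] <- logs[[i]]$condition_tags[[tag]]
          }
        }
        tab
      }))
    scores <- purrr::map_dfr(seq_along(logs), function(i) {
      tab <- tables$periods[
        tables$periods$session_id == logs[[i]]$session_id &
          tables$periods$subject_id == logs[[i]]$subject_id, ]
      tibble::tibble(
        subject_id = logs[[i]]$subject_id,
        session_id = logs[[i]]$session_id,
        drug = logs[[i]]$condition_tags$drug %||% "none",
        pit_score = pit_score(tab, "all"),
        pit_score_with = pit_score(tab, "with_approach"),
        pit_score_without = pit_score(tab, "without_approach"))
    })
    # average duplicate same-drug tests before group statistics
    tables$pit_scores <- dplyr::summarise(
      dplyr::group_by(scores, .data$subject_id, .data$drug),
      dplyr::across(dplyr::starts_with("pit_score"), mean), .groups = "drop")
    summary$mean_pit_score <- mean(tables$pit_scores$pit_score)
    if (nrow(tables$pit_scores) >= 2 &&
        length(unique(tables$pit_scores$drug)) == 1) {
      summary$pit_one_sample_t <- one_sample_t(tables$pit_scores$pit_score)
    }
    if (any(is.na(tables$periods$proportion_with_approach))) {
      warning("undefined proportion_with_approach in some periods (no presses)",
              call. = FALSE)
    }
    if (cfg$fit_models && cfg$n_subjects >= 4) {
      spec <- model_spec("press_count", "poisson_log",
                         fixed = c("cs_type", "period"),
                         random = c("cs_type", "period"))
      fits$press_count <- stage("stats",
                                fit_count_model(spec, tables$periods))
      if (!fits$press_count$converged) {
        warning("count model did not converge", call. = FALSE)
      }
      summary$press_count_tests <- as.data.frame(fits$press_count$f_tests)
    }
  } else if (cfg$script == "exp4_devaluation") {
    tables$devaluation <- stage("assay", purrr::map_dfr(
      seq_along(logs),
      function(i) devaluation_table(logs[[i]], classified[[i]])))
    dv <- tables$devaluation[tables$devaluation$press_type == "all", ]
    summary$mean_presses_valued <- mean(dv$press_count[dv$lever_value ==
                                                         "valued"])
    summary$mean_presses_devalued <- mean(dv$press_count[dv$lever_value ==
                                                           "devalued"])
    summary$mean_prop_valued <- mean(
      dv$proportion_with_approach[dv$lever_value == "valued"], na.rm = TRUE)
    summary$mean_prop_devalued <- mean(
      dv$proportion_with_approach[dv$lever_value == "devalued"],
      na.rm = TRUE)
  }

  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]],
                     file.path(cfg$out_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  summary$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")), 2)
  json <- jsonlite::toJSON(summary[setdiff(names(summary), "elapsed_s")],
                           auto_unbox = TRUE, digits = 10, pretty = TRUE,
                           dataframe = "columns")
  writeLines(json, file.path(cfg$out_dir, "summary.json"))
  note("report written to %s (%.1f s)", cfg$out_dir, summary$elapsed_s)
  invisible(list(logs = logs, classified = classified, tables = tables,
                 fits = fits, summary = summary, out_dir = cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
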