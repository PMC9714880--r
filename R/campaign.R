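## ---------------------------------------------------------------------------
## Simulation campaign: run every task x group battery, export session
## tables, representative field traces, summaries and the qualitative
## verdict table.
## ---------------------------------------------------------------------------

campaign_runs <- function(tasks, groups) {
  expand.grid(task = tasks, group = groups, stringsAsFactors = FALSE)
}

#' Run the full simulation campaign
#'
#' Executes the decision (200 trials), flanker (200) and stop-signal
#' (100 go + 250 stop) sessions for both group parameterizations, writes one
#' CSV per session plus run metadata (configuration hash, seeds), exports
#' reach/pause field traces for one representative trial per condition, and
#' writes the behavioral summaries and group statistics.
#'
#' @param config Configuration.
#' @param out Output directory (created if needed); NULL keeps everything in
#'   memory.
#' @param seed Master seed; each session derives its own seed from it.
#' @param tasks,groups Subsets to run (defaults: everything).
#' @param preset Trial-count preset (see [make_session()]).
#' @param progress Print progress messages.
#' @return Invisible list with `sessions` (named list of session tables),
#'   `summaries`, `stats`, `meta`.
#' @export
run_campaign <- function(config = default_config(), out = NULL, seed = 1,
                         tasks = c("decision", "flanker", "stop_signal"),
                         groups = c("neurotypical", "pd"),
                         preset = "simulation", progress = FALSE) {
  runs <- campaign_runs(tasks, groups)
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sessions <- list()
  for (i in seq_len(nrow(runs))) {
    task <- runs$task[i]; group <- runs$group[i]
    ## session seed depends on the task only, so the two groups see
    ## identical trial sequences and trial seeds (paired comparison)
    s_seed <- (seed * 1000L + match(task, c("decision", "flanker",
                                            "stop_signal"))) %%
      .Machine$integer.max
    if (progress) message("running ", task, " / ", group)
    task_preset <- if (is.list(preset)) preset[[task]] else preset
    ses <- make_session(task, group, config, seed = s_seed,
                        preset = task_preset)
    model <- build_architecture(config)
    tab <- run_session(ses, model, progress = progress)
    key <- paste(task, group, sep = ".")
    sessions[[key]] <- tab
    if (!is.null(out)) {
      utils::write.csv(tab, file.path(out, paste0("session_", key, ".csv")),
                       row.names = FALSE)
      export_field_traces(model, task, group, config,
                          file.path(out, paste0("traces_", key, ".csv")))
    }
  }
  summaries <- lapply(sessions, behavior_summary, config = config)
  stats <- list()
  for (task in tasks) {
    both <- do.call(rbind, sessions[paste(task, groups, sep = ".")])
    flt <- filter_trials(both, config)
    stats[[task]] <- group_stats(flt$analyzed)
  }
  meta <- list(config_hash = config_hash(config), seed = seed,
               preset = preset,
               r_version = as.character(getRversion()),
               timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out)) {
    jsonlite::write_json(meta, file.path(out, "meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summ_rows <- do.call(rbind, lapply(names(summaries), function(k) {
      pc <- summaries[[k]]$per_condition
      if (is.null(pc)) NULL else pc
    }))
    utils::write.csv(summ_rows, file.path(out, "summary.csv"),
                     row.names = FALSE)
  }
  invisible(list(sessions = sessions, summaries = summaries, stats = stats,
                 meta = meta))
}

## Field-trace export for one representative (first, fixed-seed) trial per
## trial type, same trial seed across groups so traces are comparable.
export_field_traces <- function(model, task, group, config, path) {
  types <- switch(task, decision = c("instructed", "choice"),
                  flanker = c("congruent", "incongruent"),
                  stop_signal = c("go", "stop"))
  gt <- group_task_params(group, task, config)
  rows <- list()
  for (ty in types) {
    spec <- trial_spec(task, ty, "right", config = config)
    if (ty == "stop") spec$ssd <- config$tasks$ssd_init
    rec <- run_trial(spec, model, gt, seed = 7L, record_fields = TRUE)
    fl <- rec$fields
    peak <- which.max(apply(fl$reach, 2, max))
    rows[[ty]] <- data.frame(
      task = task, group = group, trial_type = ty, t = fl$t,
      reach_peak_u = fl$reach[, peak],
      pause_selection_u = fl$pause[, 1],
      pause_conflict_u = fl$pause[, 2],
      pause_stop_u = fl$pause[, 3])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Evaluate the qualitative behavioral battery of a campaign
#'
#' Checks, on a completed campaign, the directional orderings the theory
#' predicts (choice > instructed RT; incongruent > congruent; go >
#' instructed within group; the PD/neurotypical group orderings; PD
#' stop-probability at or below neurotypical per matched SSD bin), the stop
#' psychometrics (near-monotone decline of P(stop) with SSD; staircase
#' convergence of the realized stop-success rate to ~50%) and the
#' change-of-mind rate bound.
#'
#' @param campaign Result of [run_campaign()], or a directory containing its
#'   `session_*.csv` exports.
#' @param config Configuration (for the exclusion rules).
#' @param iso_tol Tolerated increase between SSD bins in the monotonicity
#'   check.
#' @param min_bin_n Minimum stop trials per SSD bin entering the bin-wise
#'   checks.
#' @return Data frame with one row per check: `check`, `value`, `pass`.
#' @export
acceptance_report <- function(campaign, config = default_config(),
                              iso_tol = 0.05, min_bin_n = 5) {
  if (is.character(campaign)) {
    files <- list.files(campaign, pattern = "^session_.*\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0) {
      stop("incomplete-report error: no session tables found in ", campaign)
    }
    sessions <- lapply(files, utils::read.csv)
    names(sessions) <- sub("^session_(.*)\\.csv$", "\\1", basename(files))
  } else {
    sessions <- campaign$sessions
  }
  need <- c("decision.neurotypical", "decision.pd", "flanker.neurotypical",
            "flanker.pd", "stop_signal.neurotypical", "stop_signal.pd")
  missing <- setdiff(need, names(sessions))
  if (length(missing)) {
    stop("incomplete-report error: missing runs: ",
         paste(missing, collapse = ", "))
  }
  mean_rt <- function(key, type) {
    tab <- filter_trials(sessions[[key]], config)$analyzed
    mean(tab$rt_ms[tab$trial_type == type], na.rm = TRUE)
  }
  rows <- list()
  add <- function(check, value, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(check = check, value = value,
                                             pass = pass)
  }
  for (grp in c("neurotypical", "pd")) {
    add(paste0(grp, ": RT choice > instructed"),
        mean_rt(paste0("decision.", grp), "choice") -
          mean_rt(paste0("decision.", grp), "instructed"), NA)
    add(paste0(grp, ": RT incongruent > congruent"),
        mean_rt(paste0("flanker.", grp), "incongruent") -
          mean_rt(paste0("flanker.", grp), "congruent"), NA)
    add(paste0(grp, ": RT go > instructed"),
        mean_rt(paste0("stop_signal.", grp), "go") -
          mean_rt(paste0("decision.", grp), "instructed"), NA)
  }
  add("PD - NT instructed RT",
      mean_rt("decision.pd", "instructed") -
        mean_rt("decision.neurotypical", "instructed"), NA)
  add("PD - NT congruent RT",
      mean_rt("flanker.pd", "congruent") -
        mean_rt("flanker.neurotypical", "congruent"), NA)
  add("PD - NT incongruent RT",
      mean_rt("flanker.pd", "incongruent") -
        mean_rt("flanker.neurotypical", "incongruent"), NA)
  add("NT - PD go RT",
      mean_rt("stop_signal.neurotypical", "go") -
        mean_rt("stop_signal.pd", "go"), NA)
  for (i in seq_along(rows)) rows[[i]]$pass <- rows[[i]]$value > 0

  curves <- lapply(c(neurotypical = "stop_signal.neurotypical",
                     pd = "stop_signal.pd"), function(k)
                       stop_probability_curve(sessions[[k]],
                                              min_n = min_bin_n))
  for (grp in names(curves)) {
    cv <- curves[[grp]]
    viol <- if (nrow(cv) > 1) max(c(0, diff(cv$p_stop))) else 0
    add(paste0(grp, ": P(stop) non-increasing (max rise)"), viol,
        viol <= iso_tol)
    st <- sessions[[paste0("stop_signal.", grp)]]
    rate <- mean(st$stop_outcome[!is.na(st$stop_outcome)] == "success")
    add(paste0(grp, ": staircase success rate ~ 0.5"), rate,
        abs(rate - 0.5) <= 0.10)
  }
  shared <- intersect(curves$neurotypical$bin, curves$pd$bin)
  if (length(shared)) {
    dmax <- max(curves$pd$p_stop[match(shared, curves$pd$bin)] -
                  curves$neurotypical$p_stop[match(shared,
                                                   curves$neurotypical$bin)])
    add("PD P(stop) <= NT P(stop) per shared bin (max excess)", dmax,
        dmax <= 0)
  }
  ch <- sessions$decision.neurotypical
  ch <- ch[ch$trial_type == "choice" & ch$responded, ]
  com <- mean(ch$change_of_mind)
  add("choice change-of-mind rate in (0, 0.10)", com, com > 0 && com < 0.10)
  do.call(rbind, rows)
}
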