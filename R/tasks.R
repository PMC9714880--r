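## ---------------------------------------------------------------------------
## Task protocols: free-choice decision, arrow flanker, stop-signal with a
## 1-up/1-down SSD staircase; session orchestration.
##
## Direction convention: right = 0 degrees, left = 180 degrees (the two
## response directions of the joystick task).
## ---------------------------------------------------------------------------

DIR_DEG <- c(right = 0, left = 180)

#' Construct one trial specification
#'
#' @param task `"decision"`, `"flanker"` or `"stop_signal"`.
#' @param trial_type One of `instructed`, `choice`, `congruent`,
#'   `incongruent`, `go`, `stop` (must match the task).
#' @param direction `"left"` or `"right"`; for choice trials the direction is
#'   free and ignored.
#' @param ssd Stop-signal delay (ms), stop trials only.
#' @param config Configuration (for timing defaults).
#' @return List of class `trial_spec`.
#' @export
trial_spec <- function(task, trial_type, direction = "right", ssd = NA_real_,
                       config = default_config()) {
  valid <- list(decision = c("instructed", "choice"),
                flanker = c("congruent", "incongruent"),
                stop_signal = c("go", "stop"))
  if (!task %in% names(valid)) stop("unknown task: ", task)
  if (!trial_type %in% valid[[task]]) {
    stop("trial type '", trial_type, "' invalid for task '", task, "'")
  }
  if (!direction %in% names(DIR_DEG)) stop("direction must be left or right")
  structure(list(task = task, trial_type = trial_type, direction = direction,
                 flanker_lead = config$tasks$flanker_lead,
                 ssd = ssd, timeout = config$display),
            class = "trial_spec")
}

#' Generate a randomized session of trial specifications
#'
#' Presets carry the default simulation trial counts (`"simulation"`: 200 decision trials
#' half choice, 200 flanker trials half incongruent, 100 go + 250 stop) and
#' the human-protocol counts (`"human"`: 2 x 52, 2 x 52, 3 x 60 with 40/20
#' go/stop per block).
#'
#' @param task Task name.
#' @param group `"neurotypical"` or `"pd"` (recorded on the session).
#' @param config Configuration.
#' @param seed Integer seed fixing the trial order and directions.
#' @param preset `"simulation"` (default) or `"human"` (the human-protocol
#'   counts), or a named count vector
#'   such as `c(go = 10, stop = 25)`.
#' @return List with `specs` (list of `trial_spec`), `task`, `group`,
#'   `seed`.
#' @export
make_session <- function(task, group = "neurotypical",
                         config = default_config(), seed = 1,
                         preset = "simulation") {
  counts <- if (is.character(preset)) {
    p <- config$tasks$presets[[preset]]
    if (is.null(p)) stop("unknown preset: ", preset)
    p[[task]]
  } else preset
  if (is.null(counts) || any(counts < 0) || sum(counts) == 0) {
    stop("configuration error: impossible trial mix for task ", task)
  }
  set.seed(seed)
  types <- sample(rep(names(counts), counts))
  dirs <- sample(names(DIR_DEG), length(types), replace = TRUE)
  specs <- lapply(seq_along(types), function(i) {
    trial_spec(task, types[i], dirs[i], config = config)
  })
  list(task = task, group = group, specs = specs, seed = seed)
}

#' Staircase state
#'
#' @param ssd Current stop-signal delay (ms).
#' @param step Step size (ms), default 50.
#' @param floor,ceiling Bounds (ms).
#' @return List of class `staircase_state`.
#' @export
staircase_state <- function(ssd = 200, step = 50, floor = 0, ceiling = 1500) {
  structure(list(ssd = ssd, step = step, floor = floor, ceiling = ceiling),
            class = "staircase_state")
}

#' Update the SSD staircase after a stop trial
#'
#' A successful stop makes the next stop trial harder (+step); a failed stop
#' makes it easier (-step); the SSD is clamped to its bounds.
#'
#' @param state A [staircase_state()].
#' @param outcome `"success"` or `"fail"`.
#' @return Updated `staircase_state`.
#' @export
update_staircase <- function(state, outcome = c("success", "fail")) {
  outcome <- match.arg(outcome)
  d <- if (outcome == "success") state$step else -state$step
  state$ssd <- min(max(state$ssd + d, state$floor), state$ceiling)
  state
}

## Build the stimulus/context timeline for a trial spec.
build_timeline <- function(spec, model) {
  cfg <- model$config
  st <- cfg$stimulus
  labels <- model$specs$spatial_sensory$labels
  on <- cfg$settle
  dir_deg <- DIR_DEG[[spec$direction]]
  opp_deg <- 180 - dir_deg
  t_end <- on + cfg$display
  no_eo <- encode_stimuli(numeric(0), 0, 0, 0, st$width, labels)

  if (spec$task == "decision") {
    target_onset <- on
    off <- on + spec$timeout
    if (spec$trial_type == "choice") {
      sens <- encode_stimuli(c(0, 180), on, off, st$amplitude, st$width,
                             labels)
      dirs <- c(0, 180)
    } else {
      sens <- encode_stimuli(dir_deg, on, off, st$amplitude, st$width, labels)
      dirs <- dir_deg
    }
    trial_timeline(t_end, target_onset, sens, no_eo, dirs = dirs)
  } else if (spec$task == "flanker") {
    target_onset <- on + spec$flanker_lead
    off <- target_onset + spec$timeout
    t_end <- off
    if (spec$trial_type == "congruent") {
      sens <- encode_stimuli(c(dir_deg, dir_deg), c(on, target_onset),
                             off, st$amplitude, st$width, labels)
      conflict_on <- NULL
      dirs <- dir_deg
    } else {
      sens <- encode_stimuli(c(opp_deg, dir_deg), c(on, target_onset),
                             off, st$amplitude, st$width, labels)
      conflict_on <- c(target_onset, off)
      dirs <- c(0, 180)
    }
    eo <- encode_stimuli(dir_deg, target_onset, off, st$eo_amplitude,
                         st$width, labels)
    trial_timeline(t_end, target_onset, sens, eo,
                   conflict_on = conflict_on, dirs = dirs)
  } else {  # stop_signal
    target_onset <- on
    off <- on + spec$timeout
    sens <- encode_stimuli(dir_deg, on, off, st$amplitude, st$width, labels)
    stop_on <- if (spec$trial_type == "stop") {
      if (!is.finite(spec$ssd)) {
        stop("stop trial needs a finite ssd (set spec$ssd or run it ",
             "through run_session, which threads the staircase)")
      }
      c(on + spec$ssd, t_end)
    } else NULL
    trial_timeline(t_end, target_onset, sens, no_eo,
                   stop_on = stop_on, dirs = dir_deg)
  }
}

#' Run one trial
#'
#' Builds the trial's stimulus/context timeline, executes the closed-loop
#' simulation, computes the velocity-rule reaction time from the simulated
#' trajectory, and classifies the outcome (response direction, stop
#' success/failure, change of mind).
#'
#' @param spec A [trial_spec()].
#' @param model An `ar_model` built for the matching group/task.
#' @param group_task A [group_task_params()].
#' @param seed Integer trial seed.
#' @param noise Logical; FALSE for deterministic trials.
#' @param keep_trajectory Attach the simulated trajectory to the record.
#' @param record_fields Attach decimated field traces.
#' @return List of class `trial_record`.
#' @export
run_trial <- function(spec, model, group_task, seed = NULL, noise = TRUE,
                      keep_trajectory = FALSE, record_fields = FALSE) {
  stopifnot(inherits(spec, "trial_spec"))
  tl <- build_timeline(spec, model)
  sim <- tryCatch(
    rhc_execute(model, tl, group_task, seed = seed, noise = noise,
                record_fields = record_fields),
    error = function(e) {
      stop("trial failed (seed ", seed, "): ", conditionMessage(e))
    })
  ev <- sim$events
  cfg <- model$config
  rt <- compute_rt(sim$trajectory, onset = 0,
                   vel_frac = cfg$metrics$vel_frac)
  com <- detect_change_of_mind(sim$trajectory,
                               range = cfg$control$target_distance,
                               frac = cfg$metrics$com_frac)
  is_stop <- spec$task == "stop_signal" && spec$trial_type == "stop"
  stop_outcome <- if (!is_stop) NA_character_
                  else if (ev$responded) "fail" else "success"
  choice <- if (ev$responded) {
    if (ev$chosen_side > 0) "right" else "left"
  } else NA_character_
  correct <- if (spec$trial_type == "choice") NA
             else if (is_stop) !ev$responded
             else identical(choice, spec$direction)
  rec <- list(
    spec = spec,
    rt = if (ev$responded) rt else NA_real_,
    rt_thresh = if (!is.na(ev$t_cross)) ev$t_cross + cfg$control$latency
                else NA_real_,
    responded = ev$responded,
    response_time = ev$response_time,
    choice = choice,
    correct = correct,
    stop_outcome = stop_outcome,
    change_of_mind = isTRUE(com) && ev$responded,
    n_replan = ev$n_replan,
    seed = seed
  )
  if (keep_trajectory) rec$trajectory <- sim$trajectory
  if (record_fields) rec$fields <- sim$fields
  class(rec) <- "trial_record"
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>", x$spec$task, "/", x$spec$trial_type,
      "dir", x$spec$direction,
      if (!is.na(x$spec$ssd)) paste0("ssd ", x$spec$ssd) else "",
      "| rt", round(x$rt, 1), "ms",
      if (!is.na(x$stop_outcome)) paste0("| stop ", x$stop_outcome) else "",
      if (x$change_of_mind) "| change-of-mind" else "", "\n")
  invisible(x)
}

#' Run a full session
#'
#' Runs every trial of a session sequentially (threading the SSD staircase
#' through stop-signal sessions) and returns a tidy per-trial table.  Each
#' trial draws its own seed from the session seed, so any single trial is
#' reproducible in isolation from the `seed` column.
#'
#' @param session From [make_session()].
#' @param model An `ar_model`; built from `config` when NULL.
#' @param config Configuration used when `model` is NULL.
#' @param noise Logical.
#' @param keep_trajectories Attach a list of trajectories as an attribute.
#' @param progress Print per-trial progress.
#' @return A `data.frame` of class `ar_session` with one row per trial:
#'   task, group, trial, trial_type, direction, ssd, rt_ms, rt_thresh_ms,
#'   responded, choice, correct, stop_outcome, change_of_mind, seed.
#' @export
run_session <- function(session, model = NULL, config = default_config(),
                        noise = TRUE, keep_trajectories = FALSE,
                        progress = FALSE) {
  if (is.null(model)) model <- build_architecture(config)
  gt <- group_task_params(session$group, session$task, model$config)
  n <- length(session$specs)
  set.seed(session$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  stair <- staircase_state(model$config$tasks$ssd_init,
                           model$config$tasks$ssd_step,
                           model$config$tasks$ssd_floor,
                           model$config$tasks$ssd_ceiling)
  rows <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    spec <- session$specs[[i]]
    if (spec$task == "stop_signal" && spec$trial_type == "stop") {
      spec$ssd <- stair$ssd
    }
    rec <- run_trial(spec, model, gt, seed = trial_seeds[i], noise = noise,
                     keep_trajectory = keep_trajectories)
    if (!is.na(rec$stop_outcome)) {
      stair <- update_staircase(stair, rec$stop_outcome)
    }
    rows[[i]] <- data.frame(
      task = spec$task, group = session$group, trial = i,
      trial_type = spec$trial_type, direction = spec$direction,
      ssd = if (is.null(spec$ssd)) NA_real_ else spec$ssd,
      rt_ms = rec$rt, rt_thresh_ms = rec$rt_thresh,
      responded = rec$responded,
      choice = if (is.null(rec$choice) || is.na(rec$choice)) NA_character_
               else rec$choice,
      correct = rec$correct,
      stop_outcome = rec$stop_outcome,
      change_of_mind = rec$change_of_mind,
      seed = rec$seed,
      stringsAsFactors = FALSE
    )
    if (keep_trajectories) trajs[[i]] <- rec$trajectory
    if (progress && i %% 25 == 0) {
      message(session$task, "/", session$group, ": trial ", i, "/", n)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ar_session", class(out))
  attr(out, "session_seed") <- session$seed
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' @export
summary.ar_session <- function(object, ...) {
  agg <- stats::aggregate(rt_ms ~ trial_type,
                          data = object[object$responded, ],
                          FUN = function(r) c(mean = mean(r), sd = sd(r),
                                              n = length(r)))
  cat("Session:", object$task[1], "/", object$group[1], "-",
      nrow(object), "trials\n")
  print(do.call(data.frame, agg))
  if (any(!is.na(object$stop_outcome))) {
    st <- object[!is.na(object$stop_outcome), ]
    cat("stop success rate:",
        round(mean(st$stop_outcome == "success"), 3),
        "over", nrow(st), "stop trials\n")
  }
  invisible(object)
}
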