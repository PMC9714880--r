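## ---------------------------------------------------------------------------
## Trajectory-to-behavior reduction: spline-smoothed velocity reaction
## times, exclusion rules, change-of-mind detection, stop psychometrics and
## group statistics.  Everything here runs on plain trajectory tables, so it
## is testable on synthetic trajectories independently of the simulator.
## ---------------------------------------------------------------------------

check_trajectory <- function(traj) {
  if (!all(c("t", "x", "y") %in% names(traj))) {
    stop("trajectory needs columns t, x, y")
  }
  if (nrow(traj) < 4) stop("metric error: need >= 4 samples for spline smoothing")
  if (any(diff(traj$t) <= 0)) stop("trajectory time must be strictly increasing")
  traj
}

#' Velocity-rule reaction time
#'
#' Smooths the trajectory with natural cubic interpolating splines,
#' differentiates the splines analytically to obtain the speed profile, and
#' returns the first time after stimulus onset at which the speed exceeds
#' `vel_frac` (default 10%) of the maximum speed.  `NA` when the hand never
#' moves.
#'
#' @param traj Data frame with columns `t` (ms, strictly increasing), `x`,
#'   `y`.
#' @param onset Stimulus onset on the trajectory's time axis (default 0).
#' @param vel_frac Fraction of the maximum speed defining movement onset.
#' @return Reaction time in ms relative to `onset`, or `NA_real_`.
#' @export
compute_rt <- function(traj, onset = 0, vel_frac = 0.10) {
  check_trajectory(traj)
  fx <- stats::splinefun(traj$t, traj$x, method = "natural")
  fy <- stats::splinefun(traj$t, traj$y, method = "natural")
  grid <- seq(min(traj$t), max(traj$t), by = 1)
  speed <- sqrt(fx(grid, deriv = 1)^2 + fy(grid, deriv = 1)^2)
  vmax <- max(speed)
  disp <- max(abs(traj$x - traj$x[1]), abs(traj$y - traj$y[1]))
  if (vmax <= 0 || disp < 1e-9) return(NA_real_)
  ok <- grid > onset & speed > vel_frac * vmax
  if (!any(ok)) return(NA_real_)
  grid[which(ok)[1]] - onset
}

#' Change-of-mind detection
#'
#' A trajectory is a change of mind when the hand moves past `frac`
#' (default 5%) of the maximum range toward one direction along the choice
#' axis and the final response is the opposite direction.
#'
#' @param traj Trajectory data frame (choice axis = `x`).
#' @param range Maximum range of the choice axis (full target distance).
#' @param frac Excursion fraction defining commitment to a direction.
#' @return Logical flag.
#' @export
detect_change_of_mind <- function(traj, range = 1, frac = 0.05) {
  check_trajectory(traj)
  x_final <- traj$x[nrow(traj)]
  side <- sign(x_final)
  if (side == 0) return(FALSE)
  any(-side * traj$x > frac * range)
}

#' Apply the reaction-time exclusion rules
#'
#' Removes, per condition cell (task x group x trial_type): RTs faster than
#' `rt_min` (anticipation), RTs slower than `rt_max`, RTs more than `rt_sd`
#' standard deviations from the cell mean (mean and SD computed after the
#' absolute cuts, one pass), and change-of-mind trials.  Trials without an
#' RT (successful stops, misses) are left untouched but not counted as
#' analyzed RT trials.
#'
#' @param records An `ar_session` table (or any data frame with `rt_ms` and
#'   `change_of_mind`).
#' @param config Configuration supplying the cut values.
#' @return List with `analyzed` (surviving rows) and `exclusions` (named
#'   counts: `too_fast`, `too_slow`, `outlier_sd`, `change_of_mind`).
#' @export
filter_trials <- function(records, config = default_config()) {
  m <- config$metrics
  if (nrow(records) == 0) {
    return(list(analyzed = records,
                exclusions = c(too_fast = 0L, too_slow = 0L,
                               outlier_sd = 0L, change_of_mind = 0L)))
  }
  if (is.null(records$change_of_mind)) records$change_of_mind <- FALSE
  has_rt <- !is.na(records$rt_ms)
  com <- records$change_of_mind & has_rt
  fast <- has_rt & !com & records$rt_ms < m$rt_min
  slow <- has_rt & !com & records$rt_ms > m$rt_max
  keep <- !(com | fast | slow)
  cell_cols <- intersect(c("task", "group", "trial_type"), names(records))
  cell <- if (length(cell_cols)) {
    interaction(records[cell_cols], drop = TRUE)
  } else factor(rep(1, nrow(records)))
  out_sd <- rep(FALSE, nrow(records))
  for (lv in levels(cell)) {
    i <- which(cell == lv & keep & has_rt)
    if (length(i) < 2) next
    mu <- mean(records$rt_ms[i]); s <- stats::sd(records$rt_ms[i])
    if (s > 0) out_sd[i] <- abs(records$rt_ms[i] - mu) > m$rt_sd * s
  }
  keep <- keep & !out_sd
  list(analyzed = records[keep, , drop = FALSE],
       exclusions = c(too_fast = sum(fast), too_slow = sum(slow),
                      outlier_sd = sum(out_sd),
                      change_of_mind = sum(com)))
}

#' Stop-success probability as a function of SSD
#'
#' @param records Session table containing stop trials (`stop_outcome`
#'   `success`/`fail`, `ssd`).
#' @param bin_width Bin width in ms, aligned to the staircase grid.
#' @param min_n Minimum stop trials for a bin to be reported.
#' @return Data frame with `bin` (lower edge, ms), `n`, `p_stop`.
#' @export
stop_probability_curve <- function(records, bin_width = 50, min_n = 1) {
  st <- records[!is.na(records$stop_outcome), , drop = FALSE]
  if (nrow(st) == 0) stop("no stop trials in records")
  bin <- floor(st$ssd / bin_width) * bin_width
  tab <- stats::aggregate(list(n = bin), by = list(bin = bin), FUN = length)
  succ <- tapply(st$stop_outcome == "success", bin, sum)
  tab$p_stop <- as.numeric(succ[as.character(tab$bin)]) / tab$n
  tab <- tab[tab$n >= min_n, , drop = FALSE]
  tab[order(tab$bin), , drop = FALSE]
}

#' Group-level statistics
#'
#' Two-way ANOVA (group x trial type, type-II sums of squares) on per-trial
#' RT for the decision and flanker tasks, and a two-tailed Welch t-test on
#' go-trial RT for the stop-signal task.
#'
#' @param records Combined session table for one task, both groups, RTs
#'   filtered.
#' @return List: for decision/flanker, `anova` (data frame with F and p per
#'   term); for stop, `t_test` (`htest`).  Both carry per-cell means.
#' @export
group_stats <- function(records) {
  task <- records$task[1]
  rec <- records[!is.na(records$rt_ms), , drop = FALSE]
  if (nrow(rec) < 4) stop("need >= 2 analyzed trials per cell")
  cellmeans <- stats::aggregate(rt_ms ~ group + trial_type, data = rec, mean)
  if (task %in% c("decision", "flanker")) {
    fit <- stats::lm(rt_ms ~ group * trial_type, data = rec)
    aov2 <- car::Anova(fit, type = 2)
    res <- data.frame(term = rownames(aov2),
                      F = aov2[["F value"]],
                      p = aov2[["Pr(>F)"]])
    list(task = task, anova = res, cell_means = cellmeans)
  } else {
    go <- rec[rec$trial_type == "go", ]
    tt <- stats::t.test(rt_ms ~ group, data = go)
    list(task = task, t_test = tt, cell_means = cellmeans)
  }
}

#' Synthetic trajectory generator
#'
#' Closed-form fixture trajectories with known ground truth, used to test
#' the metric functions independently of the simulator:
#' * `minimum_jerk`: straight reach with the minimum-jerk speed profile
#'   `v(s) / v_peak = (30 s^2 - 60 s^3 + 30 s^4) / 1.875`, onset and
#'   duration known analytically;
#' * `change_of_mind`: an excursion past the commitment fraction toward one
#'   side followed by a reach to the other;
#' * `stationary`: no movement.
#'
#' @param kind One of `"minimum_jerk"`, `"change_of_mind"`, `"stationary"`.
#' @param onset Movement onset (ms).
#' @param duration Movement duration (ms).
#' @param amplitude Reach amplitude (workspace units; sign = direction).
#' @param excursion For `change_of_mind`: peak fractional excursion toward
#'   the abandoned side (of `abs(amplitude)`).
#' @param noise SD of additive positional noise.
#' @param t_end Total duration (ms).
#' @param dt Sample interval (ms).
#' @param seed Optional seed for the noise.
#' @return Trajectory data frame (`t`, `x`, `y`).
#' @export
generate_synthetic_trajectory <- function(kind = c("minimum_jerk",
                                                   "change_of_mind",
                                                   "stationary"),
                                          onset = 300, duration = 600,
                                          amplitude = 1, excursion = 0.08,
                                          noise = 0, t_end = onset + duration + 100,
                                          dt = 5, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_end, by = dt)
  mj <- function(s) ifelse(s <= 0, 0, ifelse(s >= 1, 1,
                                             10 * s^3 - 15 * s^4 + 6 * s^5))
  x <- switch(kind,
    minimum_jerk = amplitude * mj((t - onset) / duration),
    change_of_mind = {
      ## out-and-back to the abandoned side, then a reach to the final side
      half <- duration / 2
      exc <- -amplitude * excursion *
        sin(pi * pmin(pmax((t - onset) / half, 0), 1))
      exc + amplitude * mj((t - onset - half) / duration)
    },
    stationary = rep(0, length(t))
  )
  if (noise > 0) x <- x + stats::rnorm(length(t), 0, noise)
  data.frame(t = t, x = x, y = rep(0, length(t)))
}

#' Analytic movement-onset offset of the minimum-jerk speed profile
#'
#' Time (as a fraction of movement duration) at which the minimum-jerk speed
#' first exceeds `vel_frac` of its peak; used as the ground truth for RT
#' recovery tests.
#'
#' @param vel_frac Fraction of peak speed.
#' @return Fraction of the movement duration.
#' @export
minimum_jerk_crossing <- function(vel_frac = 0.10) {
  speed <- function(s) (30 * s^2 - 60 * s^3 + 30 * s^4) / 1.875
  stats::uniroot(function(s) speed(s) - vel_frac, c(1e-9, 0.5),
                 tol = 1e-10)$root
}

#' Summarize a session's behavior
#'
#' Applies the exclusion rules and reduces a session table to per-condition
#' mean/SE RT, exclusion counts, change-of-mind rate and (for stop sessions)
#' the stop-probability curve.
#'
#' @param records Session table.
#' @param config Configuration.
#' @return List of class `behavior_summary`.
#' @export
behavior_summary <- function(records, config = default_config()) {
  flt <- filter_trials(records, config)
  an <- flt$analyzed
  rts <- an[!is.na(an$rt_ms), , drop = FALSE]
  per_cond <- if (nrow(rts)) {
    agg <- stats::aggregate(rt_ms ~ task + group + trial_type, data = rts,
                            FUN = function(r) c(mean = mean(r),
                                                se = stats::sd(r) / sqrt(length(r)),
                                                n = length(r)))
    do.call(data.frame, agg)
  } else NULL
  com_rate <- mean(records$change_of_mind[records$responded], na.rm = TRUE)
  curve <- if (any(!is.na(records$stop_outcome))) {
    stop_probability_curve(records)
  } else NULL
  structure(list(per_condition = per_cond,
                 exclusions = flt$exclusions,
                 n_raw = nrow(records), n_analyzed = nrow(an),
                 change_of_mind_rate = com_rate,
                 stop_curve = curve),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>", x$n_analyzed, "of", x$n_raw, "trials analyzed\n")
  cat("exclusions:", paste(names(x$exclusions), x$exclusions,
                           sep = "=", collapse = ", "), "\n")
  if (!is.null(x$per_condition)) print(x$per_condition)
  cat("change-of-mind rate:", round(x$change_of_mind_rate, 4), "\n")
  if (!is.null(x$stop_curve)) {
    cat("stop-probability curve:\n"); print(x$stop_curve)
  }
  invisible(x)
}
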