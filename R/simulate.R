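## ---------------------------------------------------------------------------
## Closed-loop trial simulation: field integration, desirability-weighted
## policy mixing, receding-horizon re-planning, response and stop detection.
##
## Two exactness-preserving reductions keep the loop fast without changing
## the model: (i) the context fields receive spatially uniform input and are
## integrated noise-free by default, so a single representative neuron
## carries the whole field; (ii) because every active policy shares one gain
## table (see control.R), the desirability-weighted mixture of policy
## commands equals a single feedback law toward the desirability-weighted
## goal.  Both identities are unit-tested against the explicit forms.
## ---------------------------------------------------------------------------

#' Build a trial timeline
#'
#' Low-level constructor for the stimulus/context schedule consumed by
#' [rhc_execute()].  [run_trial()] builds these from a trial spec; call this
#' directly only for custom protocols.
#'
#' @param t_end Total simulated time (ms).
#' @param target_onset Time of the RT-defining stimulus (ms).
#' @param sensory `stimulus_drive` for the spatial sensory field.
#' @param eo `stimulus_drive` for the expected outcome field.
#' @param conflict_on,stop_on Optional `c(start, end)` activation windows of
#'   the context-field box drives (ms).
#' @param dirs Active target directions (degrees), used to assign each reach
#'   neuron's goal.
#' @return List of class `ar_timeline`.
#' @export
trial_timeline <- function(t_end, target_onset, sensory, eo,
                           conflict_on = NULL, stop_on = NULL, dirs) {
  structure(list(t_end = t_end, target_onset = target_onset,
                 sensory = sensory, eo = eo,
                 conflict_on = conflict_on, stop_on = stop_on,
                 dirs = dirs),
            class = "ar_timeline")
}

## piecewise-constant drive evaluator: recompute only at window boundaries
drive_schedule <- function(stim, t_end, dt, n) {
  bounds <- sort(unique(c(0, stim$onset, stim$offset, t_end + dt)))
  vals <- lapply(bounds[-length(bounds)], function(t0) {
    v <- stimulus_input(stim, t0)
    if (length(v) == 1L) rep(v, n) else v
  })
  list(bounds = bounds, vals = vals)
}

box_active <- function(win, t) !is.null(win) && t >= win[1] && t < win[2]

#' Execute one trial under receding-horizon control
#'
#' Steps every field with forward Euler, forms the relative-desirability
#' weights of the supra-threshold reach neurons at every step, applies the
#' desirability-weighted mixture of the per-neuron finite-horizon optimal
#' policies (re-planned every `tau_rhc` steps), and integrates the plant
#' until a response registers (plus a short follow-through), the display
#' window ends, or a divergence is detected.
#'
#' @param model An `ar_model` from [build_architecture()].
#' @param timeline An `ar_timeline`.
#' @param group_task A [group_task_params()].
#' @param seed Optional integer; when non-NULL the RNG is seeded so the
#'   trial is reproducible in isolation.
#' @param noise Logical; FALSE zeroes every noise source.
#' @param record_fields Store decimated field activity traces (10 ms stride).
#' @return List with `trajectory` (data frame `t`, `x`, `y`; time relative
#'   to `target_onset`), `events` (threshold crossing, movement start,
#'   response registration, re-plan count, ...) and optionally `fields`.
#' @export
rhc_execute <- function(model, timeline, group_task, seed = NULL,
                        noise = TRUE, record_fields = FALSE) {
  stopifnot(inherits(model, "ar_model"), inherits(timeline, "ar_timeline"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- model$config
  dt <- cfg$dt
  fc <- cfg$fields
  ctrl <- cfg$control

  sp_r <- model$specs$reach_planning
  labels <- sp_r$labels
  n_r <- sp_r$n_neurons
  W <- model$W_reach
  beta_r <- sp_r$beta; u0_r <- sp_r$u0
  gamma <- model$gamma
  g <- model$gains

  tau_s <- fc$spatial_sensory$tau; h_s <- fc$spatial_sensory$h
  beta_s <- fc$spatial_sensory$beta
  tau_e <- fc$expected_outcome$tau; h_e <- fc$expected_outcome$h
  beta_e <- fc$expected_outcome$beta
  tau_c <- fc$stop_context$tau; h_c <- fc$stop_context$h
  beta_c <- fc$stop_context$beta
  tau_p <- fc$pause$tau; h_p <- fc$pause$h; beta_p <- fc$pause$beta
  n_sub <- fc$pause$n_sub; n_pause <- 3L * n_sub
  a_ctx <- cfg$stimulus$context_amplitude

  sig_r <- if (noise) fc$reach_planning$noise * sqrt(dt) else 0
  sig_p <- if (noise) fc$pause$noise * sqrt(dt) else 0
  sig_s <- if (noise) fc$spatial_sensory$noise * sqrt(dt) else 0

  tonic <- group_task$pause_tonic
  w_sel <- cfg$coupling$w_select
  w_con <- cfg$coupling$w_conflict
  w_stp <- cfg$coupling$w_stop

  ## goal geometry
  rad <- labels * pi / 180
  cosl <- cos(rad); sinl <- sin(rad)
  r0 <- ctrl$target_distance
  dirs <- timeline$dirs
  tgt_pos <- cbind(r0 * cos(dirs * pi / 180), r0 * sin(dirs * pi / 180))
  ## nearest active target direction per neuron
  nearest <- if (length(dirs)) {
    apply(abs(outer(labels, dirs, "-")), 1, which.min)
  } else rep(1L, n_r)

  K <- cached_gains(ctrl, dt)
  min_h <- ctrl$min_horizon
  resp_x <- ctrl$response_frac * r0
  b <- ctrl$damping; minv <- 1 / ctrl$mass

  n_steps <- ceiling(timeline$t_end / dt)
  can_multi <- length(unique(timeline$dirs)) >= 2L
  sens_sched <- drive_schedule(timeline$sensory, timeline$t_end, dt, n_r)
  eo_sched <- drive_schedule(timeline$eo, timeline$t_end, dt, n_r)

  ## states
  u_sens <- rep(h_s, n_r); u_eo <- rep(h_e, n_r); u_reach <- rep(sp_r$h, n_r)
  u_stopc <- h_c; u_confc <- h_c      # representative neurons (uniform input)
  u_pause <- rep(h_p, n_pause)
  sub_idx <- rep(1:3, each = n_sub)   # 1 selection, 2 conflict, 3 stop
  px <- 0; py <- 0; vx <- 0; vy <- 0

  stride <- max(1L, round(cfg$traj_stride / dt))
  n_rec <- n_steps %/% stride + 2L
  rec_t <- numeric(n_rec); rec_x <- numeric(n_rec); rec_y <- numeric(n_rec)
  rec_i <- 1L
  rec_t[1] <- 0 - timeline$target_onset

  if (record_fields) {
    fstride <- max(1L, round(10 / dt))
    nf <- n_steps %/% fstride + 2L
    rec_ft <- numeric(nf)
    rec_freach <- matrix(NA_real_, nf, n_r)
    rec_fpause <- matrix(NA_real_, nf, 3)
    fi <- 0L
  }

  t_cross <- NA_real_; move_start <- NA_real_; move_end <- NA_real_
  responded <- FALSE; response_time <- NA_real_; chosen <- NA_real_
  n_replan <- 0L
  gx <- numeric(n_r); gy <- numeric(n_r)
  si <- 1L; ei <- 1L
  S_sens <- sens_sched$vals[[1]]; S_eo <- eo_sched$vals[[1]]
  f_reach <- sigmoid_output(u_reach, beta_r, u0_r)

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    while (t_now >= sens_sched$bounds[si + 1L]) {
      si <- si + 1L; S_sens <- sens_sched$vals[[si]]
    }
    while (t_now >= eo_sched$bounds[ei + 1L]) {
      ei <- ei + 1L; S_eo <- eo_sched$vals[[ei]]
    }

    ## input-layer fields
    noise_s <- if (sig_s > 0) stats::rnorm(n_r, 0, sig_s) else 0
    u_sens <- u_sens + (dt / tau_s) * (-u_sens + h_s + S_sens) + noise_s
    u_eo <- u_eo + (dt / tau_e) * (-u_eo + h_e + S_eo)
    f_sens <- 1 / (1 + exp(-beta_s * u_sens))
    f_eo <- 1 / (1 + exp(-beta_e * u_eo))

    ## context fields (uniform -> representative neuron)
    in_stop <- if (box_active(timeline$stop_on, t_now)) a_ctx else 0
    in_conf <- if (box_active(timeline$conflict_on, t_now)) a_ctx else 0
    u_stopc <- u_stopc + (dt / tau_c) * (-u_stopc + h_c + in_stop)
    u_confc <- u_confc + (dt / tau_c) * (-u_confc + h_c + in_conf)

    ## pause routing and pause field
    ## tonic and phasic drives combine by saturation (max), not summation:
    ## a sub-population already held at a high tonic level is not driven
    ## further by its phasic input
    multi <- can_multi && detect_multi_target(f_sens)
    d_sel <- max(if (multi) w_sel * mean(f_sens) else 0, tonic[[1L]])
    d_con <- max(w_con / (1 + exp(-beta_c * u_confc)), tonic[[2L]])
    d_stp <- max(w_stp / (1 + exp(-beta_c * u_stopc)), tonic[[3L]])
    drive_p <- c(d_sel, d_con, d_stp)[sub_idx]
    noise_p <- if (sig_p > 0) stats::rnorm(n_pause, 0, sig_p) else 0
    u_pause <- u_pause + (dt / tau_p) * (-u_pause + h_p + drive_p) + noise_p
    v_pau <- sum(1 / (1 + exp(-beta_p * u_pause))) / n_sub

    ## reach planning field
    S_act <- g$eta_pos * f_sens + g$eta_reward * f_eo - g$eta_pau * v_pau
    lateral <- as.numeric(W %*% f_reach)
    noise_r <- if (sig_r > 0) stats::rnorm(n_r, 0, sig_r) else 0
    u_reach <- u_reach +
      (dt / sp_r$tau) * (-u_reach + sp_r$h + S_act + lateral) + noise_r
    f_reach <- 1 / (1 + exp(-beta_r * (u_reach - u0_r)))

    ## action initiation and control
    supra <- u_reach > gamma
    any_supra <- any(supra)
    if (is.na(t_cross) && any_supra) {
      t_cross <- t_now
      move_start <- t_cross + ctrl$latency
      move_end <- move_start + ctrl$move_time
    }
    ux <- 0; uy <- 0
    if (!is.na(move_start) && t_now >= move_start && any_supra) {
      if ((step - 1L) %% ctrl$tau_rhc == 0L || n_replan == 0L) {
        ## re-plan: each neuron's policy aims at the stimulus it encodes, at
        ## the current hand-to-stimulus distance (for the neuron tuned to
        ## the stimulus direction this is exactly the direction-coded goal;
        ## snapping its neighbours to the same point keeps the
        ## boundary-truncated population from drifting off the choice axis)
        n_replan <- n_replan + 1L
        gx <- tgt_pos[nearest, 1]
        gy <- tgt_pos[nearest, 2]
      }
      w <- f_reach[supra]
      w <- w / sum(w)
      gxm <- sum(w * gx[supra]); gym <- sum(w * gy[supra])
      s <- (move_end - t_now) / dt          # steps-to-go
      if (s < min_h) s <- min_h
      if (s > dim(K)[3]) s <- dim(K)[3]
      Ks <- K[, , as.integer(s)]
      e1 <- px - gxm; e2 <- py - gym
      ux <- -(Ks[1, 1] * e1 + Ks[1, 2] * e2 + Ks[1, 3] * vx + Ks[1, 4] * vy)
      uy <- -(Ks[2, 1] * e1 + Ks[2, 2] * e2 + Ks[2, 3] * vx + Ks[2, 4] * vy)
    }

    ## plant
    px <- px + dt * vx; py <- py + dt * vy
    vx <- vx + dt * (minv * ux - b * vx)
    vy <- vy + dt * (minv * uy - b * vy)

    if (!responded && abs(px) >= resp_x) {
      responded <- TRUE
      response_time <- t_now
      chosen <- sign(px)
    }

    if (step %% stride == 0L) {
      rec_i <- rec_i + 1L
      rec_t[rec_i] <- t_now - timeline$target_onset
      rec_x[rec_i] <- px; rec_y[rec_i] <- py
    }
    if (record_fields && step %% fstride == 0L) {
      fi <- fi + 1L
      rec_ft[fi] <- t_now - timeline$target_onset
      rec_freach[fi, ] <- u_reach
      rec_fpause[fi, ] <- tapply(u_pause, sub_idx, mean)
    }

    if (step %% 50L == 0L) {
      m <- max(abs(u_reach))
      if (!is.finite(m) || m > cfg$u_ceiling) {
        stop("divergence error in field 'reach_planning' at t = ", t_now,
             " ms (|u| = ", format(m), ")")
      }
    }
    if (responded && t_now >= response_time + cfg$follow_through) break
  }

  traj <- data.frame(t = rec_t[seq_len(rec_i)],
                     x = rec_x[seq_len(rec_i)],
                     y = rec_y[seq_len(rec_i)])
  out <- list(
    trajectory = traj,
    events = list(
      t_cross = t_cross - timeline$target_onset,
      move_start = move_start - timeline$target_onset,
      responded = responded,
      response_time = if (responded) response_time - timeline$target_onset
                      else NA_real_,
      chosen_side = chosen,            # +1 right (0 deg), -1 left (180 deg)
      n_replan = n_replan
    ),
    final_state = c(px = px, py = py, vx = vx, vy = vy)
  )
  if (record_fields) {
    out$fields <- list(t = rec_ft[seq_len(fi)],
                       reach = rec_freach[seq_len(fi), , drop = FALSE],
                       pause = rec_fpause[seq_len(fi), , drop = FALSE],
                       labels = labels)
  }
  out
}
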