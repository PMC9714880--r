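## ---------------------------------------------------------------------------
## Model architecture: the wired set of fields of the action-regulation
## circuit and the reach-planning drive.
##
## Wiring (all under the default configuration):
##   spatial_sensory(181)  --one_to_one  exc-->  reach_planning(181)
##   expected_outcome(181) --one_to_one  exc-->  reach_planning(181)
##   pause(3 x 75)         --one_to_all  inh-->  reach_planning(181)
##   stop_context(100)     --one_to_all  exc-->  pause[stop]
##   conflict_context(100) --one_to_all  exc-->  pause[conflict]
##   spatial_sensory(181)  --one_to_all  exc-->  pause[selection]
##                                         (gated on multi-target detection)
## ---------------------------------------------------------------------------

as_field_spec <- function(name, f) {
  kern <- NULL
  if (!is.null(f$kernel)) {
    kern <- kernel_spec(f$kernel$c_exc, f$kernel$c_inh,
                        f$kernel$sigma_exc, f$kernel$sigma_inh)
  }
  n <- if (!is.null(f$n)) f$n else 3L * f$n_sub
  field_spec(n, tau = f$tau, h = f$h, beta = f$beta, kernel = kern,
             directional = isTRUE(f$directional),
             u0 = if (is.null(f$u0)) 0 else f$u0)
}

#' Build the action-regulation model
#'
#' Instantiates every field at its resting level, precomputes the lateral
#' weight matrix of the reach planning field, and wires the projections of
#' the architecture (sensory and expected-outcome topological excitation of
#' the reach planning field; pause-field broadcast inhibition; context-field
#' and sensory one-to-all excitation of the matching pause sub-populations).
#'
#' @param config Configuration from [default_config()].
#' @return Object of class `ar_model`: `specs` and `states` per field, the
#'   `projections` list, `gains`, `gamma`, and the originating `config`.
#' @examples
#' m <- build_architecture(default_config())
#' print(m)
#' @export
build_architecture <- function(config = default_config()) {
  fc <- config$fields
  required <- c("spatial_sensory", "expected_outcome", "reach_planning",
                "stop_context", "conflict_context", "pause")
  missing <- setdiff(required, names(fc))
  if (length(missing)) {
    stop("configuration error: missing field definitions: ",
         paste(missing, collapse = ", "))
  }
  specs <- lapply(required, function(nm) as_field_spec(nm, fc[[nm]]))
  names(specs) <- required
  states <- lapply(specs, field_state)

  n_pause <- specs$pause$n_neurons
  g <- config$gains
  cp <- config$coupling
  projections <- list(
    projection("spatial_sensory", "reach_planning", "one_to_one",
               weight = g$eta_pos, sign = "excitatory"),
    projection("expected_outcome", "reach_planning", "one_to_one",
               weight = g$eta_reward, sign = "excitatory"),
    projection("pause", "reach_planning", "one_to_all",
               weight = g$eta_pau / fc$pause$n_sub, sign = "inhibitory"),
    projection("stop_context", "pause.stop", "one_to_all",
               weight = cp$w_stop / fc$stop_context$n, sign = "excitatory"),
    projection("conflict_context", "pause.conflict", "one_to_all",
               weight = cp$w_conflict / fc$conflict_context$n,
               sign = "excitatory"),
    projection("spatial_sensory", "pause.selection", "one_to_all",
               weight = cp$w_select / fc$spatial_sensory$n,
               sign = "excitatory")
  )
  sizes <- vapply(specs, function(s) s$n_neurons, integer(1))
  for (p in projections) {
    if (p$topology == "one_to_one") {
      src <- sizes[[p$source]]
      tgt <- sizes[[sub("\\..*$", "", p$target)]]
      if (src != tgt) {
        stop("configuration error: one_to_one projection ", p$source,
             " -> ", p$target, " has mismatched sizes (", src, " vs ",
             tgt, ")")
      }
    }
  }

  model <- structure(list(
    specs = specs,
    states = states,
    projections = projections,
    gains = g,
    gamma = config$gamma,
    W_reach = if (!is.null(specs$reach_planning$kernel)) {
      kernel_weights(specs$reach_planning$kernel,
                     specs$reach_planning$labels)
    } else NULL,
    n_sub = fc$pause$n_sub,
    config = config
  ), class = "ar_model")
  model
}

#' @export
print.ar_model <- function(x, ...) {
  cat("<ar_model> action-regulation circuit\n")
  for (nm in names(x$specs)) {
    s <- x$specs[[nm]]
    extra <- if (nm == "pause") paste0(" (3 sub-populations of ", x$n_sub, ")")
             else ""
    cat(sprintf("  %-17s %4d neurons, tau %4g ms, h %5g%s\n",
                nm, s$n_neurons, s$tau, s$h, extra))
  }
  cat("  projections:\n")
  for (p in x$projections) {
    cat(sprintf("    %-17s -> %-16s %-10s %-10s w = %.4g\n",
                p$source, p$target, p$topology, p$sign, p$weight))
  }
  cat("  gamma =", x$gamma, "\n")
  invisible(x)
}

#' Validation report of a built model
#'
#' @param model An `ar_model`.
#' @return Data frame listing every field (with size) and every projection.
#' @export
validate_architecture <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  fields <- data.frame(
    item = names(model$specs),
    kind = "field",
    detail = vapply(model$specs, function(s)
      paste0(s$n_neurons, " neurons"), character(1)),
    row.names = NULL
  )
  projs <- data.frame(
    item = vapply(model$projections, function(p)
      paste0(p$source, " -> ", p$target), character(1)),
    kind = "projection",
    detail = vapply(model$projections, function(p)
      paste(p$topology, p$sign, sep = ", "), character(1)),
    row.names = NULL
  )
  rbind(fields, projs)
}

#' Encode stimuli as time-gated Gaussian drive bumps
#'
#' Each stimulus direction contributes a nonnegative Gaussian bump over the
#' direction axis, active within `[onset, offset)`; simultaneous bumps sum.
#' Right and left responses map to 0 and 180 degrees.
#'
#' @param directions Target angles in degrees, each within \[0, 180\].
#' @param onset,offset Activation window (ms); scalars or per-direction
#'   vectors.
#' @param amplitude Drive strength (scalar or per-direction).
#' @param width Gaussian bump SD in degrees.
#' @param labels Field coordinate vector (degrees).
#' @return Object of class `stimulus_drive`; call it via [stimulus_input()]
#'   to obtain the drive vector at a time `t`.
#' @export
encode_stimuli <- function(directions, onset, offset, amplitude, width,
                           labels) {
  if (length(directions) == 0) {
    return(structure(list(bumps = matrix(0, length(labels), 0),
                          onset = numeric(0), offset = numeric(0)),
                     class = "stimulus_drive"))
  }
  if (any(directions < 0 | directions > 180)) {
    stop("stimulus direction outside [0, 180] degrees")
  }
  k <- length(directions)
  onset <- rep_len(onset, k); offset <- rep_len(offset, k)
  amplitude <- rep_len(amplitude, k)
  bumps <- vapply(seq_len(k), function(i) {
    amplitude[i] * exp(-(labels - directions[i])^2 / (2 * width^2))
  }, numeric(length(labels)))
  structure(list(bumps = bumps, onset = onset, offset = offset),
            class = "stimulus_drive")
}

#' Evaluate a stimulus drive at a time point
#'
#' @param stim A `stimulus_drive` from [encode_stimuli()].
#' @param t Time (ms).
#' @return Drive vector (sums of the bumps active at `t`).
#' @export
stimulus_input <- function(stim, t) {
  act <- stim$onset <= t & t < stim$offset
  if (!any(act)) return(0)
  if (sum(act) == 1L) stim$bumps[, which(act)]
  else rowSums(stim$bumps[, act, drop = FALSE])
}

#' Reach-planning drive
#'
#' The external drive to the reach planning field:
#' `S_action = eta_pos v_pos + eta_reward v_reward - eta_pau v_pau + xi`,
#' where `v_pos` and `v_reward` are the topological outputs of the sensory
#' and expected-outcome fields, `v_pau` is the pause field's one-to-all
#' contribution (scalar, broadcast), and `xi` is additive Gaussian noise.
#'
#' @param v_pos,v_reward Output vectors sized to the reach field.
#' @param v_pau Scalar pause contribution (normalized one-to-all sum).
#' @param gains List with `eta_pos`, `eta_reward`, `eta_pau`.
#' @param noise Optional pre-drawn noise vector (0 for none).
#' @return Drive vector.
#' @export
reach_drive <- function(v_pos, v_reward, v_pau, gains, noise = 0) {
  if (length(v_pos) != length(v_reward)) {
    stop("wiring error: v_pos and v_reward sizes differ")
  }
  if (length(v_pau) != 1L) {
    stop("wiring error: v_pau must be the scalar broadcast pause contribution")
  }
  gains$eta_pos * v_pos + gains$eta_reward * v_reward -
    gains$eta_pau * v_pau + noise
}

#' Detect multiple encoded targets in a sensory output
#'
#' A target counts as encoded when a connected run of neurons exceeds the
#' sigmoid midpoint; two or more disjoint supra-threshold runs signal a
#' multi-target situation (the trigger of the selection pause
#' sub-population).
#'
#' @param output Sigmoided sensory output vector.
#' @param threshold Detection threshold (default 0.5, the sigmoid midpoint).
#' @return TRUE when at least two disjoint supra-threshold components exist.
#' @export
detect_multi_target <- function(output, threshold = 0.5) {
  r <- rle(output > threshold)
  sum(r$values) >= 2L
}

#' Route drives to the pause sub-populations
#'
#' The selection sub-population receives the one-to-all sensory drive gated
#' on multi-target detection; the conflict and stop sub-populations receive
#' the one-to-all drives of their context fields; each sub-population's
#' phasic drive combines with its group/task tonic drive by saturation
#' (element-wise maximum): a sub-population already held at a high tonic
#' level is not driven further by its phasic input.
#'
#' @param sensory_output,conflict_output,stop_output Sigmoided outputs of the
#'   respective fields.
#' @param group_task A [group_task_params()].
#' @param coupling Coupling weights (`w_select`, `w_conflict`, `w_stop`);
#'   taken from [default_config()] when missing.
#' @return Named numeric vector of per-sub-population drives
#'   (`selection`, `conflict`, `stop`).
#' @export
pause_routing <- function(sensory_output, conflict_output, stop_output,
                          group_task, coupling = default_config()$coupling) {
  stopifnot(inherits(group_task, "group_task_params"))
  sel_gate <- detect_multi_target(sensory_output)
  drives <- c(
    selection = if (sel_gate)
      coupling$w_select * mean(sensory_output) else 0,
    conflict = coupling$w_conflict * mean(conflict_output),
    stop = coupling$w_stop * mean(stop_output)
  )
  pmax(drives, group_task$pause_tonic)
}
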