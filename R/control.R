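## ---------------------------------------------------------------------------
## Per-neuron stochastic optimal controllers.
##
## Plant: discrete-time linear point mass with viscous damping,
##   state x = (px, py, vx, vy), control = planar force,
##   p <- p + dt v ;  v <- v + dt (u/m - b v).
## Each reach neuron's controller minimizes a terminal-precision plus
## summed-control cost over a finite horizon (backward Riccati recursion).
## Because the goal state (goal position, zero velocity) is an equilibrium of
## the uncontrolled plant, the optimal feedback law is u_t = -K_s (x_t - g)
## with gains K_s depending only on the number of steps-to-go s, which lets
## one gain table serve every goal and every receding-horizon re-plan.
## ---------------------------------------------------------------------------

#' Discrete-time point-mass plant matrices
#'
#' @param control Control sub-list of [default_config()] (`mass`, `damping`).
#' @param dt Step (ms).
#' @return List with state matrix `A` (4 x 4) and input matrix `B` (4 x 2).
#' @export
plant_matrices <- function(control, dt = 1) {
  b <- control$damping; m <- control$mass
  A <- diag(4)
  A[1, 3] <- dt; A[2, 4] <- dt
  A[3, 3] <- 1 - b * dt; A[4, 4] <- 1 - b * dt
  B <- matrix(0, 4, 2)
  B[3, 1] <- dt / m; B[4, 2] <- dt / m
  list(A = A, B = B)
}

#' Finite-horizon LQ feedback gains
#'
#' Backward Riccati recursion for the cost
#' `(x_T - g)' Q_T (x_T - g) + sum_t u_t' R u_t` (state cost at the terminal
#' step only).  Returns the gain for every number of steps-to-go, so the same
#' table serves shrinking receding-horizon re-plans.
#'
#' @param A,B Plant matrices from [plant_matrices()].
#' @param Q_T Terminal weight (4 x 4, positive semidefinite).
#' @param R Control weight (2 x 2, positive definite).
#' @param horizon Maximum steps.
#' @return `ncol(B)` x `nrow(A)` x horizon array; slice `[,,s]` is the gain
#'   with `s` steps to go, i.e. `u = -K[,,s] (x - g)`.
#' @export
lqr_gains <- function(A, B, Q_T, R, horizon) {
  stopifnot(horizon >= 1)
  A <- as.matrix(A); B <- as.matrix(B)
  Q_T <- as.matrix(Q_T); R <- as.matrix(R)
  P <- Q_T
  K <- array(0, c(ncol(B), nrow(A), horizon))
  for (s in seq_len(horizon)) {
    G <- R + t(B) %*% P %*% B
    if (rcond(G) < 1e-14) {
      stop("numerical error: ill-conditioned Riccati recursion at ",
           s, " steps-to-go (rcond = ", format(rcond(G)), ")")
    }
    Ks <- solve(G, t(B) %*% P %*% A)
    K[, , s] <- Ks
    P <- t(A) %*% P %*% (A - B %*% Ks)
    P <- (P + t(P)) / 2
  }
  K
}

terminal_weight <- function(control) {
  diag(c(control$q_pos, control$q_pos, control$q_vel, control$q_vel))
}

control_weight <- function(control) diag(control$r_control, 2)

## Gain tables are cached per (plant, cost, horizon) so repeated trials reuse
## one Riccati solve.
.gain_cache <- new.env(parent = emptyenv())

cached_gains <- function(control, dt = 1) {
  key <- paste(control$mass, control$damping, control$q_pos, control$q_vel,
               control$r_control, control$move_time, dt, sep = "|")
  if (is.null(.gain_cache[[key]])) {
    pl <- plant_matrices(control, dt)
    .gain_cache[[key]] <- lqr_gains(pl$A, pl$B, terminal_weight(control),
                                    control_weight(control),
                                    ceiling(control$move_time / dt))
  }
  .gain_cache[[key]]
}

#' Solve a finite-horizon reach policy
#'
#' @param plant List with `A`, `B` from [plant_matrices()].
#' @param goal Goal position (length 2); the implied goal state appends zero
#'   velocity.  For non-standard plants a full goal state of length
#'   `nrow(A)` may be given instead.
#' @param horizon Steps, >= 1.
#' @param Q_T,R Cost matrices (see [lqr_gains()]).
#' @return Object of class `control_policy` with the goal state and the
#'   time-indexed feedback gains.
#' @export
solve_policy <- function(plant, goal, horizon, Q_T, R) {
  stopifnot(horizon >= 1)
  K <- lqr_gains(plant$A, plant$B, Q_T, R, horizon)
  n <- nrow(as.matrix(plant$A))
  goal_state <- if (length(goal) == n) goal
                else if (length(goal) == 2 && n == 4) c(goal, 0, 0)
                else stop("goal must have length 2 (position) or nrow(A)")
  structure(list(goal = goal_state, horizon = horizon, K = K),
            class = "control_policy")
}

#' Evaluate a policy's control command
#'
#' @param policy A `control_policy`.
#' @param x State (px, py, vx, vy).
#' @param step Time step within the policy, 1-based (step 1 has the full
#'   horizon to go).
#' @return Control vector (2).
#' @export
policy_command <- function(policy, x, step = 1) {
  s <- policy$horizon - step + 1L
  if (s < 1L) s <- 1L
  -as.numeric(policy$K[, , s] %*% (x - policy$goal))
}

#' @export
print.control_policy <- function(x, ...) {
  cat("<control_policy> goal (", paste(round(x$goal[1:2], 3), collapse = ", "),
      "), horizon ", x$horizon, " steps\n", sep = "")
  invisible(x)
}

#' Relative desirability weights
#'
#' Normalized activity of the reach-planning neurons whose activation exceeds
#' the action-initiation threshold `gamma`: `d_j = f(u_j) / sum_k f(u_k)`
#' over supra-threshold neurons `k` (the sigmoided output is used by default;
#' set `on_output = FALSE` to normalize raw activations).  Empty when no
#' neuron is supra-threshold, in which case no movement command exists.
#'
#' @param u_reach Reach-planning activation vector.
#' @param gamma Action-initiation threshold.
#' @param beta,u0 Sigmoid parameters of the reach field.
#' @param on_output Normalize sigmoided output (default) or raw activation.
#' @return Object of class `desirability`: integer `idx` of supra-threshold
#'   neurons and matching `weights` summing to 1 (both empty when none).
#' @export
relative_desirability <- function(u_reach, gamma, beta = 4, u0 = 0,
                                  on_output = TRUE) {
  idx <- which(u_reach > gamma)
  if (length(idx) == 0L) {
    return(structure(list(idx = integer(0), weights = numeric(0)),
                     class = "desirability"))
  }
  a <- if (on_output) sigmoid_output(u_reach[idx], beta, u0) else u_reach[idx]
  structure(list(idx = idx, weights = a / sum(a)), class = "desirability")
}

#' Mix active policies by relative desirability
#'
#' `pi_mix(x) = sum_j d_j pi_j(x)` over the active policies; an empty weight
#' set yields a no-command sentinel (`NULL`), under which the plant holds.
#'
#' @param policies List of `control_policy`, parallel to `weights$idx`.
#' @param weights A `desirability`.
#' @param x Current plant state.
#' @param step Time step within the policies.
#' @return Control vector (2), or `NULL` when no policy is active.
#' @export
mix_policies <- function(policies, weights, x, step = 1) {
  if (length(weights$idx) == 0L) return(NULL)
  if (length(policies) != length(weights$idx)) {
    stop("policies and desirability weights must be parallel")
  }
  cmd <- c(0, 0)
  for (j in seq_along(policies)) {
    cmd <- cmd + weights$weights[j] * policy_command(policies[[j]], x, step)
  }
  cmd
}
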