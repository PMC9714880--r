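## ---------------------------------------------------------------------------
## Dynamic neural field (DNF) machinery: interaction kernels, sigmoid gain,
## noisy forward-Euler integration and inter-field projections.
##
## A field is a population of rate neurons u(x, t) over a labelled coordinate
## axis (degrees for direction-tuned fields, plain indices otherwise) obeying
##
##   tau * du/dt = -u + h + S(x,t) + [w (*) f(u)](x,t) + sum_k [w_jk (*) f_k(u_k)]
##
## with local-excitation / surround-inhibition kernel w and logistic gain f.
## ---------------------------------------------------------------------------

#' Interaction-kernel specification
#'
#' Difference-of-Gaussians lateral interaction kernel with a local excitatory
#' lobe and a (typically broader) inhibitory surround.
#'
#' @param c_exc,c_inh Nonnegative amplitudes of the excitatory and inhibitory
#'   components (activation units).
#' @param sigma_exc,sigma_inh Widths (same units as the field labels, e.g.
#'   degrees).  Must be positive whenever the corresponding amplitude is
#'   positive.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec(c_exc = 1, c_inh = 0.5, sigma_exc = 5, sigma_inh = 10)
#' @export
kernel_spec <- function(c_exc, c_inh, sigma_exc, sigma_inh) {
  vals <- c(c_exc = c_exc, c_inh = c_inh,
            sigma_exc = sigma_exc, sigma_inh = sigma_inh)
  if (!all(is.finite(vals))) {
    stop("kernel parameters must be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("kernel parameters must be nonnegative")
  }
  if (c_exc > 0 && sigma_exc <= 0) stop("sigma_exc must be > 0 when c_exc > 0")
  if (c_inh > 0 && sigma_inh <= 0) stop("sigma_inh must be > 0 when c_inh > 0")
  if (c_exc > 0 && c_inh > 0 && sigma_inh <= sigma_exc) {
    warning("sigma_inh <= sigma_exc: kernel lacks the usual ",
            "local-excitation / surround-inhibition shape")
  }
  structure(list(c_exc = c_exc, c_inh = c_inh,
                 sigma_exc = sigma_exc, sigma_inh = sigma_inh),
            class = "kernel_spec")
}

#' Field specification
#'
#' @param n_neurons Positive neuron count.
#' @param tau Time constant (ms), > 0.
#' @param h Resting level (activation units).
#' @param beta Sigmoid steepness (> 0).
#' @param kernel Optional [kernel_spec()] for lateral interactions.
#' @param labels Per-neuron coordinates.  Defaults to evenly spaced degrees
#'   over \[0, 180\] for direction-tuned fields when `directional = TRUE`,
#'   otherwise plain indices `1:n_neurons`.
#' @param directional Whether the field is direction tuned.
#' @param u0 Sigmoid offset (threshold) in `f(u) = 1/(1 + exp(-beta (u - u0)))`;
#'   default 0 so the printed logistic form is recovered.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(n_neurons, tau, h, beta, kernel = NULL,
                       labels = NULL, directional = FALSE, u0 = 0) {
  stopifnot(length(n_neurons) == 1L, n_neurons >= 1, tau > 0, beta > 0)
  n_neurons <- as.integer(n_neurons)
  if (is.null(labels)) {
    labels <- if (directional) seq(0, 180, length.out = n_neurons)
              else seq_len(n_neurons)
  }
  if (length(labels) != n_neurons) stop("labels must have length n_neurons")
  if (directional) {
    d <- diff(labels)
    if (abs(labels[1]) > 1e-9 || abs(labels[n_neurons] - 180) > 1e-9 ||
        any(abs(d - d[1]) > 1e-9)) {
      stop("direction-tuned fields must carry evenly spaced labels over [0, 180]")
    }
  }
  if (!is.null(kernel) && !inherits(kernel, "kernel_spec")) {
    stop("kernel must be a kernel_spec or NULL")
  }
  structure(list(n_neurons = n_neurons, labels = as.numeric(labels),
                 tau = tau, h = h, beta = beta, kernel = kernel,
                 directional = directional, u0 = u0),
            class = "field_spec")
}

#' Field state
#'
#' Activation vector of one field plus the current simulated time.
#'
#' @param spec A [field_spec()].
#' @param u Initial activation; defaults to the resting level `h`.
#' @param t Simulated time (ms).
#' @return An object of class `field_state`.
#' @export
field_state <- function(spec, u = NULL, t = 0) {
  if (is.null(u)) u <- rep(spec$h, spec$n_neurons)
  if (length(u) != spec$n_neurons) stop("u must have length n_neurons")
  if (!all(is.finite(u))) stop("field activation must be finite")
  structure(list(u = as.numeric(u), t = t), class = "field_state")
}

#' Build a lateral interaction weight matrix
#'
#' Evaluates the difference-of-Gaussians kernel on every pair of field
#' coordinates.  Entry `(i, j)` is
#' `c_exc exp(-(x_i - x_j)^2 / (2 sigma_exc^2)) -
#'  c_inh exp(-(x_i - x_j)^2 / (2 sigma_inh^2))`.
#' Interactions are zero-padded at the field borders (the direction axis is a
#' bounded line, not a ring), which the pairwise-distance construction gives
#' directly.
#'
#' @param spec A [kernel_spec()].
#' @param labels Evenly spaced coordinate vector.
#' @return Symmetric `length(labels)` x `length(labels)` matrix.
#' @export
kernel_weights <- function(spec, labels) {
  stopifnot(inherits(spec, "kernel_spec"))
  d <- outer(labels, labels, "-")
  w <- matrix(0, length(labels), length(labels))
  if (spec$c_exc > 0) w <- w + spec$c_exc * exp(-d^2 / (2 * spec$sigma_exc^2))
  if (spec$c_inh > 0) w <- w - spec$c_inh * exp(-d^2 / (2 * spec$sigma_inh^2))
  w
}

#' Sigmoid population output
#'
#' Logistic gain `f(u) = 1 / (1 + exp(-beta (u - u0)))` mapping activation to
#' a firing rate in (0, 1).
#'
#' @param u Activation vector.
#' @param beta Steepness, > 0.
#' @param u0 Offset (threshold), default 0.
#' @return Rate vector, elementwise in (0, 1).
#' @export
sigmoid_output <- function(u, beta, u0 = 0) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (u - u0)))
}

## Low-level Euler update used by both step_field() and the trial simulator.
## `lateral` is the already-convolved lateral term W %*% f(u); `input` bundles
## stimulus drive plus projection input; `noise` is a pre-scaled N(0, sigma
## sqrt(dt)) draw (or 0).
dnf_step_u <- function(u, tau, h, input, lateral, dt, noise) {
  u + (dt / tau) * (-u + h + input + lateral) + noise
}

#' Advance one field by one Euler step
#'
#' Forward-Euler (Euler--Maruyama) update of the field equation.  Additive
#' per-neuron Gaussian noise is drawn with standard deviation
#' `sigma * sqrt(dt)` so that trial statistics are invariant under time-step
#' refinement.
#'
#' @param state A [field_state()].
#' @param spec The matching [field_spec()].
#' @param external_input Stimulus drive vector (length `n_neurons`) or scalar 0.
#' @param projection_inputs Summed drive from other fields (same shape).
#' @param dt Step (ms); must satisfy `dt <= tau / 5`.
#' @param sigma Noise standard deviation per neuron per unit time; 0 for a
#'   deterministic update.
#' @param W Optional precomputed lateral weight matrix (from
#'   [kernel_weights()]); computed from `spec$kernel` when missing.
#' @return Updated `field_state` with `t` advanced by `dt`.
#' @export
step_field <- function(state, spec, external_input = 0, projection_inputs = 0,
                       dt = 1, sigma = 0, W = NULL) {
  stopifnot(inherits(state, "field_state"), inherits(spec, "field_spec"))
  if (dt <= 0) stop("dt must be > 0")
  if (dt > spec$tau / 5) {
    stop("dt must satisfy dt <= tau/5 for a stable Euler step (dt = ",
         dt, ", tau = ", spec$tau, ")")
  }
  n <- spec$n_neurons
  chk <- function(v, what) {
    if (length(v) != 1L && length(v) != n)
      stop("wiring error: ", what, " has length ", length(v),
           " but field has ", n, " neurons")
    v
  }
  ext <- chk(external_input, "external_input")
  prj <- chk(projection_inputs, "projection_inputs")
  lateral <- 0
  if (!is.null(spec$kernel)) {
    if (is.null(W)) W <- kernel_weights(spec$kernel, spec$labels)
    lateral <- as.numeric(W %*% sigmoid_output(state$u, spec$beta, spec$u0))
  }
  noise <- if (sigma > 0) stats::rnorm(n, 0, sigma * sqrt(dt)) else 0
  u <- dnf_step_u(state$u, spec$tau, spec$h, ext + prj, lateral, dt, noise)
  if (!all(is.finite(u))) {
    stop("divergence error: field integration produced non-finite activation")
  }
  structure(list(u = u, t = state$t + dt), class = "field_state")
}

#' Inter-field projection specification
#'
#' @param source,target Field identifiers (character); `target` may name a
#'   sub-population, e.g. `"pause.stop"`.
#' @param topology `"one_to_one"` (topological, requires equal sizes) or
#'   `"one_to_all"` (every target neuron receives the summed source output).
#' @param weight Scalar gain, >= 0.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return An object of class `projection`.
#' @export
projection <- function(source, target, topology = c("one_to_one", "one_to_all"),
                       weight = 1, sign = c("excitatory", "inhibitory")) {
  topology <- match.arg(topology)
  sign <- match.arg(sign)
  stopifnot(is.character(source), is.character(target), weight >= 0)
  structure(list(source = source, target = target, topology = topology,
                 weight = weight, sign = sign),
            class = "projection")
}

#' Apply a projection to a source field's output
#'
#' @param source_output Sigmoided rate vector of the source field.
#' @param proj A [projection()].
#' @param target_size Number of target neurons.
#' @return Signed drive vector of length `target_size`.
#' @export
project <- function(source_output, proj, target_size) {
  stopifnot(inherits(proj, "projection"))
  s <- if (proj$sign == "inhibitory") -1 else 1
  if (proj$topology == "one_to_one") {
    if (length(source_output) != target_size) {
      stop("wiring error: one_to_one projection ", proj$source, " -> ",
           proj$target, " requires equal sizes (", length(source_output),
           " vs ", target_size, ")")
    }
    s * proj$weight * source_output
  } else {
    rep(s * proj$weight * sum(source_output), target_size)
  }
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> ", x$n_neurons, " neurons, tau = ", x$tau,
      " ms, h = ", x$h, ", beta = ", x$beta,
      if (!is.null(x$kernel)) ", lateral kernel" else ", no kernel",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> c_exc = ", x$c_exc, " (sigma ", x$sigma_exc,
      "), c_inh = ", x$c_inh, " (sigma ", x$sigma_inh, ")\n", sep = "")
  invisible(x)
}
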