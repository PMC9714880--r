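---
title: "A neurodynamical model of action regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neurodynamical model of action regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionreg)
```

# The model

`actionreg` simulates how reaching movements are selected, delayed and
cancelled.  Three behavioral protocols are covered — free-choice decisions
between two opposed directions, an arrow flanker task with congruent and
incongruent trials, and a stop-signal task with a staircased stop-signal
delay (SSD) — under two parameterizations, *neurotypical* and *PD*
(Parkinson's disease, modeled purely as a dysfunction of a pause mechanism).

## Dynamic neural fields

Every population is a dynamic neural field (DNF): a vector of rate neurons
`u(x, t)` over a labelled axis obeying

    tau du/dt = -u + h + S(x,t) + [w * f(u)](x,t) + sum_k [w_jk * f_k(u_k)]

with resting level `h`, external input `S`, logistic gain
`f(u) = 1 / (1 + exp(-beta (u - u0)))` and a difference-of-Gaussians lateral
kernel `w` (local excitation, broad inhibition).  Fields are integrated with
forward Euler (Euler–Maruyama) at `dt = 1` ms; additive per-neuron Gaussian
noise enters with standard deviation `sigma * sqrt(dt)` so that summary
statistics are invariant under step refinement.  The integrator refuses
`dt > tau / 5` and treats non-finite activation as an error, never silently.
Convolution is zero-padded: the 0–180° direction axis is a bounded line
(left vs right reaches), not a ring.

The architecture wires six fields: a spatial sensory field (181 direction-
tuned neurons over 0–180°), an expected-outcome field (181), a reach
planning field (181, the only field with a lateral kernel), stop and
conflict context fields (100 each), and a pause field of three 75-neuron
sub-populations (selection, conflict, stop).  Sensory and expected-outcome
outputs project one-to-one onto the reach planning field; the pause field
inhibits it one-to-all; the context fields and (gated on multi-target
detection) the sensory field excite their matching pause sub-populations
one-to-all.  The reach drive is

    S_action = eta_pos v_pos + eta_reward v_reward - eta_pau v_pau + xi

where `v_pau` is the pause output summed one-to-all and normalized by the
sub-population size, so one saturated sub-population contributes about 1.

## Optimal control and policy mixing

Each reach neuron owns a finite-horizon linear-quadratic controller over a
discrete-time planar point mass with viscous damping (state = position and
velocity, control = force).  The cost is terminal precision plus summed
control effort; gains come from the backward Riccati recursion.  Because
the goal state (goal position, zero velocity) is an equilibrium of the
uncontrolled plant, the feedback law depends only on the number of steps to
go, and one cached gain table serves every goal and every re-plan.

Whenever a reach neuron's activation exceeds the initiation threshold
`gamma`, its policy becomes active.  The executed command is the mixture of
active policies weighted by *relative desirability* — the normalized
sigmoided activity of the supra-threshold neurons — recomputed at every
step.  Re-planning follows receding-horizon control with a re-plan interval
of 9 steps.  Each neuron's policy aims at the stimulus it encodes, at the
current hand-to-stimulus distance.  For the neuron tuned exactly to the
stimulus direction this equals the direction-coded goal
`p = r (cos phi, sin phi)`; snapping its neighbours to the same point is a
deliberate choice: with ray-coded goals, the half-truncated population at
the 0° and 180° borders of the direction axis acquires a systematic
off-axis bias that compounds under re-planning.

A *response* registers when hand displacement along the choice axis exceeds
78% of the target distance, mirroring a ±25,000 response threshold on a
±32,000 joystick axis.  A stop trial succeeds iff no response registers
before the display window ends.

# Task protocols and timelines

Pre-stimulus fixation intervals are compressed to a fixed 200 ms settling
period (the fields idle at rest, so the longer human fixation adds nothing);
the stimulus display window is 1500 ms.  Decision trials present one
(instructed) or two opposed (choice) Gaussian sensory bumps.  Flanker trials
present the flanker bump 100 ms before the target bump; incongruent trials
additionally drive the conflict context field from target onset, and the
expected-outcome field carries a bump at the correct target direction from
target onset (it encodes the instructed correct response and biases the
competition).  The conflict context is driven from the task layer when
flanker and target disagree, an explicit routing choice: the theory
describes the conflict field as detecting conflict but gives no detection
computation, and routing the signal from the protocol keeps the mechanism
explicit and testable.  Stop trials drive the stop context from
`SSD` after target onset; the SSD staircase moves ±50 ms on every stop
outcome (initial value 200 ms, floor 0, ceiling 1500 ms; the initial value
is our choice — it only sets where the 1-up/1-down walk starts).

Group differences are carried *only* by tonic pause drives, one per
group × task, applied to the task-relevant sub-population: PD exceeds
neurotypical in the decision and flanker tasks (hyperactive pause at rest),
and neurotypical exceeds PD in the stop-signal task (stronger proactive
braking).  Tonic and phasic pause inputs combine by saturation
(element-wise maximum) rather than summation.  This implements the behavior the
parameterization must reproduce: a pause sub-population already held at a
high tonic level (PD) is *not* driven further in choice trials, which is
why the two groups show nearly equal choice reaction times while differing
everywhere else.  Under summation the PD selection
sub-population would saturate and no choice trial could ever reach
threshold.

# Numerical and design choices

**Sigmoid offset of the reach field (`u0 = 0.3`).**  The gain function of
the reach planning field is offset so that only neurons within reach of the
initiation threshold (`gamma = 0.4`) participate in lateral interactions.
Sub-threshold plans therefore rise quietly and linearly under their feedforward
drive, and the first plan to cross `u0` ignites: its output saturates,
inhibits the rival bump (the kernel has `c_exc = c_inh`, so a winner's local
excitation cancels its own surround inhibition while the rival's inhibition
goes uncompensated), and resolves the competition decisively.  Without the
offset, both bumps saturate far below threshold, the winner-take-all gain
flattens, and choice trials either deadlock or dither across the midline on
most trials.  This is the single most load-bearing numerical choice in the
package.

**Noise placement.**  By default only the reach planning field
(`sigma = 0.02`/ms½) and the pause field (0.01) are noisy.  Sensory,
expected-outcome and context fields saturate under their box/bump drives,
where the logistic gain is flat and noise has no behavioral effect; leaving
them deterministic keeps trials fast and makes the uniform-input context
fields exactly representable by a single neuron (the reduction is
unit-tested).  Reach noise is what breaks the left/right symmetry on choice
trials, sets the reaction-time spread, and produces occasional changes of
mind.

**Motor latency and RT readout.**  An 80 ms constant motor latency separates
the threshold crossing from movement onset.  The session tables carry two
readouts: the primary `rt_ms` from the same velocity rule applied to human
data (natural cubic spline smoothing, analytic differentiation, first time
the speed exceeds 10% of its per-trial maximum) and the secondary
`rt_thresh_ms` (threshold crossing + latency).  On single-plan trials the
two agree within one trajectory sample (5 ms); on choice trials the
velocity rule can be later, because early sub-10% dithering during an
unresolved competition is not an overt movement.

**Horizons.**  The movement horizon is a fixed 600 ms mapped to steps,
independent of distance; re-plans keep the remaining horizon.  After the
nominal movement end the steps-to-go is held at 100 rather than shrinking
to the re-plan interval: near-zero horizons make the terminal gains so
aggressive that a noise flicker of the reach field would yank the
almost-stopped hand across the response threshold and turn successfully
cancelled actions into phantom responses.

**Plant constants.**  Unit mass, damping 0.02/ms, terminal weights
`q_pos = 1e6`, `q_vel = 1e4`, control weight 1.  The damping matters for
stopping: a cancelled policy leaves the hand coasting, and the coast
distance (velocity / damping) must be small against the 78% response
threshold or late stop cues could never succeed.

**Exclusion rules.**  Reaction times under 100 ms (anticipation) and over
1500 ms are removed; then, per task × group × trial-type cell, values more
than 3 SD from the cell mean (one pass, computed after the absolute cuts —
the order is ambiguous in prose, and a one-pass rule is the simplest
defensible reading); change-of-mind trials (an excursion past 5% of the
response range followed by arrival on the opposite side) are excluded from
RT analysis.  Exclusion counts reconcile exactly with the number of removed
rows on every run, by construction and by test.  The two-way ANOVA on RT
uses type-II sums of squares, appropriate for the mildly unbalanced cells
exclusions leave behind.

**Parameter provenance.**  The theory constrains the architecture, the
equations, and the qualitative relations between group parameterizations,
not a complete numeric table.  All numeric defaults in `default_config()`
are this package's own calibration: they were hand-tuned, once, against the qualitative battery
(directional RT orderings, stop psychometrics, staircase convergence,
change-of-mind rarity) and then frozen; nothing is re-tuned per analysis.
If the original parameter table becomes available its values drop into the
same configuration file.

**Randomness.**  One master seed per session; each trial draws its own
subseed, recorded in the session table, so any single trial is reproducible
in isolation.  Within a trial a single RNG stream serves all fields (a
per-field split would add bookkeeping without changing any tested
property).  Campaign sessions derive seeds from the task only, so the two
groups see identical trial sequences and paired trial seeds.

# What the simulations show — and what they cannot

The default battery (200 decision trials, 200 flanker trials, 100 go + 250
stop trials per group; the trial counts of the simulated experiments the
package reproduces) exhibits: slower choice than instructed responses;
slower incongruent than congruent responses; proactive slowing of go
responses relative to instructed ones in both groups, much larger in the
neurotypical parameterization; slower PD responses wherever the pause is
tonically hyperactive, but *faster* PD go responses (the PD proactive brake
is weaker); a stop-success probability that declines with SSD, lower for PD
at matched delays; a staircase that converges to ~50% stop success; and
changes of mind on a small percentage of choice trials.  `Rscript
scripts/acceptance.R` recomputes the three headline t-tests from scratch;
`acceptance_report()` evaluates the full qualitative battery.

These are *qualitative* reproductions.  The parameters were never fitted to
human data, absolute simulated RTs are not comparable to human means, and
the model — like the theory it implements — produces approximately
symmetric RT distributions: it has no attention-lapse mechanism and cannot
generate the right-skewed tails of real RT data.  The synthetic trajectory
generator used by the metric tests (minimum-jerk reaches, templated
changes of mind, stationary hands) shares none of the simulator's
machinery, which is what makes it a fixture: it validates the metric
pipeline, not the model.  Passing the battery therefore says the mechanism
is implemented coherently, not that it is calibrated to any participant
population.
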