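# actionreg

Forward simulation of a neurodynamical theory of **action regulation**: how
the motor system selects between competing reaches, delays responses under
conflicting information, and cancels actions outright when a stop cue
arrives — and how a single disrupted mechanism (a hyperactive or
hypo-engaged basal-ganglia-style "pause") reproduces the motor slowing and
impaired stopping seen in Parkinson's disease (PD).

The package is for computational and cognitive neuroscientists who want a
runnable, testable implementation of the mechanism: every population is a
dynamic neural field, every movement comes from optimal feedback control,
and every behavioral number is computed from simulated trajectories with
the same metric pipeline used on human joystick data.

## The model in brief

Activity `u(x, t)` of each field evolves as

```
tau du/dt = -u + h + S(x,t) + [w * f(u)](x,t) + sum_k [w_jk * f_k(u_k)](x,t)
```

with logistic gain `f(u) = 1/(1 + exp(-beta (u - u0)))` and a
difference-of-Gaussians lateral kernel
`w(d) = C_exc exp(-d^2 / 2 sigma_exc^2) - C_inh exp(-d^2 / 2 sigma_inh^2)`.
A 181-neuron reach planning field (preferred directions 0–180°) receives

```
S_action = eta_pos v_pos + eta_reward v_reward - eta_pau v_pau + xi
```

from the spatial sensory field, the expected-outcome field, and —
inhibitory, one-to-all — a pause field of three 75-neuron sub-populations
(selection, conflict, stop) driven by context fields and by multi-target
detection on the sensory field.  Reach neurons crossing the initiation
threshold `gamma` activate per-neuron finite-horizon LQ controllers
(terminal-precision + control-effort cost, solved by backward Riccati
recursion) over a damped point-mass plant; the executed command is the
relative-desirability-weighted mixture of active policies under
receding-horizon re-planning (re-plan interval 9 steps).  Group
parameterizations differ only in tonic pause drives: PD > neurotypical at
rest (decision, flanker), neurotypical > PD for proactive braking
(stop-signal).

Three protocols are built in: free-choice decision (instructed/choice),
arrow flanker (congruent/incongruent, 100 ms flanker lead), and stop-signal
with a ±50 ms 1-up/1-down SSD staircase.  Behavioral reduction mirrors the
human pipeline: spline-smoothed velocity, RT at 10% of peak speed,
exclusion of RTs < 100 ms or > 1500 ms or beyond 3 SD, change-of-mind
detection at 5% of the response range, stop-probability curves and
group-level ANOVA/t-tests.

## Worked example

```r
library(actionreg)
cfg <- default_config()

ses <- make_session("decision", "neurotypical", cfg, seed = 42,
                    preset = c(instructed = 20, choice = 20))
tab <- run_session(ses, config = cfg)
summary(tab)
#> Session: decision / neurotypical - 40 trials
#>   trial_type rt_ms.mean rt_ms.sd rt_ms.n
#> 1     choice      323.5 85.99235      20
#> 2 instructed      244.1  7.36921      20
```

Choice trials are ~80 ms slower than instructed ones: two reach plans form,
the selection pause sub-population holds both below threshold, and field
noise must break the symmetry before one plan ignites and wins.  A single
stop trial shows the cancellation mechanism — an early stop cue succeeds, a
late one arrives after the commitment point and fails:

```r
spec <- trial_spec("stop_signal", "stop", "right", config = cfg)
spec$ssd <- 450
run_trial(spec, build_architecture(cfg),
          group_task_params("neurotypical", "stop_signal", cfg), seed = 7)
#> <trial_record> stop_signal / stop dir right ssd 450 | rt NA ms | stop success
spec$ssd <- 800   # past the point of no return
#> <trial_record> stop_signal / stop dir right ssd 800 | rt 354 ms | stop fail
```

The full campaign (decision 200 trials, flanker 200, stop 100 go + 250
stop, both groups) runs in a few minutes and feeds the qualitative
behavioral battery:

```r
camp <- run_campaign(cfg, out = "campaign_out", seed = 1)
acceptance_report(camp)
#>                                     check    value pass
#> 1    neurotypical: RT choice > instructed  77.2967 TRUE
#> 2 neurotypical: RT incongruent > congruent 64.8579 TRUE
#> ...                                           (16 rows)
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/actionreg-sim.R campaign --seed 1 --out campaign_out
Rscript inst/cli/actionreg-sim.R accept --dir campaign_out
```

## Limitations

Parameters are hand-calibrated to the qualitative battery, not fitted to
human data; absolute simulated RTs are not comparable to human means, and
the model produces approximately symmetric RT distributions (no
attention-lapse mechanism, hence no right-skewed tails).  See the methods
vignette (`vignettes/action-regulation-model.Rmd`) for every numerical and
design choice.
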