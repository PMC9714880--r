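## Shared fixtures: a memoised default model and the full simulation battery
## (built once per test run; several files draw on them).

.fixtures <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- build_architecture(default_config())
  }
  .fixtures$model
}

## Full task x group battery at the default simulation trial counts,
## computed once and reused by the acceptance checks.
battery <- function() {
  if (is.null(.fixtures$battery)) {
    .fixtures$battery <- run_campaign(default_config(), seed = 1)
  }
  .fixtures$battery
}

battery_filtered <- function(key) {
  cfg <- default_config()
  filter_trials(battery()$sessions[[key]], cfg)$analyzed
}

## Single-trial convenience wrapper.
sim_trial <- function(task, type, group = "neurotypical", seed = 1,
                      ssd = NA, noise = TRUE, ...) {
  cfg <- default_config()
  spec <- trial_spec(task, type, "right", config = cfg)
  if (!is.na(ssd)) spec$ssd <- ssd
  run_trial(spec, default_model(), group_task_params(group, task, cfg),
            seed = seed, noise = noise, ...)
}
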