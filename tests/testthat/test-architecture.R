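test_that("the default architecture has the canonical fields and wiring", {
  m <- default_model()
  sizes <- vapply(m$specs, function(s) s$n_neurons, integer(1))
  expect_identical(sizes[["spatial_sensory"]], 181L)
  expect_identical(sizes[["expected_outcome"]], 181L)
  expect_identical(sizes[["reach_planning"]], 181L)
  expect_identical(sizes[["stop_context"]], 100L)
  expect_identical(sizes[["conflict_context"]], 100L)
  expect_identical(sizes[["pause"]], 225L)   # 3 sub-populations of 75
  expect_identical(m$n_sub, 75)

  rep <- validate_architecture(m)
  expect_identical(sum(rep$kind == "field"), 6L)
  expect_identical(sum(rep$kind == "projection"), 6L)

  edge <- function(src, tgt) {
    Filter(function(p) p$source == src && startsWith(p$target, tgt),
           m$projections)[[1]]
  }
  expect_identical(edge("spatial_sensory", "reach_planning")$topology,
                   "one_to_one")
  expect_identical(edge("expected_outcome", "reach_planning")$sign,
                   "excitatory")
  expect_identical(edge("pause", "reach_planning")$sign, "inhibitory")
  expect_identical(edge("pause", "reach_planning")$topology, "one_to_all")
  expect_identical(edge("stop_context", "pause.stop")$topology, "one_to_all")
})

test_that("mismatched one_to_one wiring is a configuration error", {
  cfg <- default_config()
  cfg$fields$expected_outcome$n <- 100
  cfg$fields$expected_outcome$directional <- FALSE
  expect_error(build_architecture(cfg), "one_to_one")
})

test_that("the unstimulated noise-free circuit settles to a fixed point", {
  cfg <- default_config()
  m <- build_architecture(cfg)
  gt <- group_task_params("neurotypical", "decision", cfg)
  labels <- m$specs$spatial_sensory$labels
  none <- encode_stimuli(numeric(0), 0, 0, 0, 15, labels)
  run_to <- function(t_end) {
    tl <- trial_timeline(t_end, 0, none, none, dirs = numeric(0))
    sim <- rhc_execute(m, tl, gt, noise = FALSE, record_fields = TRUE)
    n <- length(sim$fields$t)
    list(reach = sim$fields$reach[n, ], pause = sim$fields$pause[n, ])
  }
  a <- run_to(2000); b <- run_to(3000)
  expect_equal(a$reach, b$reach, tolerance = 1e-6)
  expect_equal(a$pause, b$pause, tolerance = 1e-6)
  # the reach planning field stays near rest, well below initiation
  expect_true(all(b$reach < m$gamma - 1))
})

test_that("stimulus encoding produces gated, symmetric Gaussian bumps", {
  labels <- seq(0, 180, by = 1)
  s1 <- encode_stimuli(0, onset = 100, offset = 200, amplitude = 3,
                       width = 15, labels = labels)
  v <- stimulus_input(s1, 150)
  expect_equal(which.max(v), 1L)           # peaks at 0 degrees
  expect_equal(max(v), 3)
  expect_identical(stimulus_input(s1, 99), 0)   # inactive before onset
  expect_identical(stimulus_input(s1, 200), 0)  # half-open window

  s2 <- encode_stimuli(c(0, 180), 0, 100, 3, 15, labels)
  v2 <- stimulus_input(s2, 50)
  expect_equal(v2, rev(v2))                # bimodal, mirror symmetric
  expect_gt(min(v2[c(1, 181)]), 2.9)

  s0 <- encode_stimuli(90, 0, 100, 0, 15, labels)
  expect_equal(max(abs(stimulus_input(s0, 50))), 0)

  expect_error(encode_stimuli(190, 0, 100, 3, 15, labels), "direction")
})

test_that("the reach drive is the signed weighted sum of its inputs", {
  gains <- list(eta_pos = 1, eta_reward = 0.5, eta_pau = 0.3)
  n <- 181
  zero <- rep(0, n)
  expect_equal(reach_drive(zero, zero, 0, gains), zero)

  v_pos <- exp(-(seq(0, 180) - 90)^2 / 50)
  v_rew <- exp(-(seq(0, 180) - 45)^2 / 50)
  v_pau <- 0.8
  out <- reach_drive(v_pos, v_rew, v_pau, gains)
  expect_equal(out, 1 * v_pos + 0.5 * v_rew - 0.3 * 0.8)

  # doubling the pause gain strictly lowers every entry when v_pau > 0
  g2 <- gains; g2$eta_pau <- 0.6
  expect_true(all(reach_drive(v_pos, v_rew, v_pau, g2) < out))

  expect_error(reach_drive(v_pos[-1], v_rew, v_pau, gains), "wiring")
  expect_error(reach_drive(v_pos, v_rew, c(1, 2), gains), "scalar")
})

test_that("multi-target detection needs two disjoint supra-threshold runs", {
  one <- c(rep(0, 50), rep(0.9, 20), rep(0, 111))
  two <- c(rep(0.9, 20), rep(0, 140), rep(0.9, 21))
  merged <- rep(0.9, 181)
  expect_false(detect_multi_target(one))
  expect_true(detect_multi_target(two))
  expect_false(detect_multi_target(merged))
  expect_false(detect_multi_target(rep(0.1, 181)))
})

test_that("pause routing gates the selection drive and applies tonics", {
  cfg <- default_config()
  one <- c(rep(0.9, 20), rep(0.01, 161))
  two <- c(rep(0.9, 20), rep(0.01, 140), rep(0.9, 21))
  quiet <- rep(0.02, 100)
  nt <- group_task_params("neurotypical", "decision", cfg)

  d1 <- pause_routing(one, quiet, quiet, nt, cfg$coupling)
  d2 <- pause_routing(two, quiet, quiet, nt, cfg$coupling)
  expect_equal(unname(d1["selection"]), 0)     # tonic-only (zero for NT)
  expect_gt(d2[["selection"]], 0)              # phasic drive when two targets

  pd <- group_task_params("pd", "decision", cfg)
  d1_pd <- pause_routing(one, quiet, quiet, pd, cfg$coupling)
  expect_gt(d1_pd[["selection"]], d1[["selection"]])
})

test_that("tonic pause drives carry the group differences", {
  cfg <- default_config()
  tonic <- function(g, t) sum(group_task_params(g, t, cfg)$pause_tonic)
  # hyperactive pause at rest in PD for decision and flanker tasks
  expect_gt(tonic("pd", "decision"), tonic("neurotypical", "decision"))
  expect_gt(tonic("pd", "flanker"), tonic("neurotypical", "flanker"))
  # proactive slowing: the neurotypical pause is higher before a stop cue
  expect_gt(tonic("neurotypical", "stop_signal"), tonic("pd", "stop_signal"))
})

test_that("a uniform-input noise-free field reduces to one representative neuron", {
  # the reduction the trial simulator uses for the context fields
  cfg <- default_config()
  fc <- cfg$fields$stop_context
  sp <- field_spec(fc$n, tau = fc$tau, h = fc$h, beta = fc$beta)
  st <- field_state(sp)
  u_rep <- fc$h
  for (i in 1:300) {
    drive <- if (i > 100) cfg$stimulus$context_amplitude else 0
    st <- step_field(st, sp, external_input = rep(drive, fc$n), dt = 1)
    u_rep <- u_rep + (1 / fc$tau) * (-u_rep + fc$h + drive)
    expect_equal(st$u, rep(u_rep, fc$n), tolerance = 1e-12)
  }
})
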