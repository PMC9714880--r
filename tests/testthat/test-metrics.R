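test_that("velocity-rule RT recovers the analytic minimum-jerk onset", {
  onset <- 300; duration <- 600; dt <- 5
  traj <- generate_synthetic_trajectory("minimum_jerk", onset = onset,
                                        duration = duration, amplitude = 1,
                                        dt = dt)
  rt <- compute_rt(traj)
  s_star <- minimum_jerk_crossing(0.10)      # analytic 10%-of-peak crossing
  expect_lt(abs(rt - (onset + s_star * duration)), dt)  # within one sample
})

test_that("RT is equivariant under time shifts and invariant to scaling", {
  base <- generate_synthetic_trajectory("minimum_jerk", onset = 250)
  rt0 <- compute_rt(base)

  shifted <- base; shifted$t <- shifted$t + 120
  expect_equal(compute_rt(shifted), rt0 + 120)

  scaled <- base; scaled$x <- base$x * 7; scaled$y <- base$y * 7
  expect_equal(compute_rt(scaled), rt0)   # the 10% rule is relative
})

test_that("a stationary trajectory yields no RT and too few samples error", {
  still <- generate_synthetic_trajectory("stationary")
  expect_true(is.na(compute_rt(still)))
  expect_error(compute_rt(data.frame(t = 1:3, x = 0, y = 0)), "samples")
  expect_error(compute_rt(data.frame(t = c(1, 1, 2, 3), x = 0, y = 0)),
               "increasing")
})

test_that("change-of-mind needs a 5% excursion and an opposite final side", {
  mono <- generate_synthetic_trajectory("minimum_jerk", amplitude = 1)
  expect_false(detect_change_of_mind(mono, range = 1))

  com <- generate_synthetic_trajectory("change_of_mind", amplitude = -1,
                                       excursion = 0.06)
  expect_true(detect_change_of_mind(com, range = 1))

  shallow <- generate_synthetic_trajectory("change_of_mind", amplitude = -1,
                                           excursion = 0.04)
  expect_false(detect_change_of_mind(shallow, range = 1))
})

test_that("the exclusion rules reproduce the worked toy example", {
  cfg <- default_config()
  toy <- data.frame(task = "decision", group = "neurotypical",
                    trial_type = "instructed",
                    rt_ms = c(90, 150, 400, 600, 1600, 420),
                    change_of_mind = FALSE)
  out <- filter_trials(toy, cfg)
  expect_identical(sort(out$analyzed$rt_ms), c(150, 400, 420, 600))
  expect_identical(unname(out$exclusions),
                   c(1L, 1L, 0L, 0L))  # too fast, too slow, 3 SD, CoM
  expect_identical(nrow(toy) - nrow(out$analyzed),
                   as.integer(sum(out$exclusions)))
})

test_that("exclusion edge cases: zero SD, change of mind, empty input", {
  cfg <- default_config()
  same <- data.frame(rt_ms = rep(400, 8), change_of_mind = FALSE)
  expect_identical(nrow(filter_trials(same, cfg)$analyzed), 8L)

  com <- data.frame(rt_ms = c(400, 410, 420), change_of_mind = c(FALSE, TRUE,
                                                                 FALSE))
  out <- filter_trials(com, cfg)
  expect_identical(nrow(out$analyzed), 2L)
  expect_identical(unname(out$exclusions[["change_of_mind"]]), 1L)

  empty <- filter_trials(data.frame(rt_ms = numeric(0),
                                    change_of_mind = logical(0)), cfg)
  expect_identical(nrow(empty$analyzed), 0L)
  expect_identical(sum(empty$exclusions), 0L)
})

test_that("3 SD outliers are cut per condition after the absolute cuts", {
  cfg <- default_config()
  set.seed(1)
  rt <- c(rnorm(50, 400, 10), max(420 + 10 * 3.5 * 10, 900))  # gross outlier
  tab <- data.frame(task = "decision", group = "pd", trial_type = "choice",
                    rt_ms = rt, change_of_mind = FALSE)
  out <- filter_trials(tab, cfg)
  expect_identical(unname(out$exclusions[["outlier_sd"]]), 1L)
  expect_lt(max(out$analyzed$rt_ms), 900)
})

test_that("the stop-probability curve is the per-bin success ratio", {
  rec <- data.frame(ssd = c(100, 100, 100, 100, 200, 200),
                    stop_outcome = c("success", "success", "success", "fail",
                                     "success", "success"))
  cv <- stop_probability_curve(rec)
  expect_equal(cv$p_stop[cv$bin == 100], 0.75)
  expect_equal(cv$p_stop[cv$bin == 200], 1)
  expect_true(all(cv$p_stop >= 0 & cv$p_stop <= 1))

  all_succ <- data.frame(ssd = c(50, 150), stop_outcome = "success")
  expect_true(all(stop_probability_curve(all_succ)$p_stop == 1))
  expect_error(stop_probability_curve(data.frame(ssd = 1,
                                                 stop_outcome = NA)),
               "no stop trials")
})

test_that("group statistics behave at the degenerate extremes", {
  set.seed(4)
  base <- rnorm(30, 400, 20)
  same <- data.frame(task = "stop_signal", trial_type = "go",
                     group = rep(c("neurotypical", "pd"), each = 30),
                     rt_ms = c(base, base))
  gs <- group_stats(same)
  expect_equal(gs$t_test$p.value, 1)
  expect_equal(unname(diff(gs$t_test$estimate)), 0)

  far <- same
  far$rt_ms <- c(rnorm(30, 400, 10), rnorm(30, 300, 10))  # ~10 SD apart
  expect_lt(group_stats(far)$t_test$p.value, 1e-10)
})

test_that("a pure condition main effect leaves a null interaction", {
  resid <- rep(c(-2, 0, 2), 10)   # identical residual pattern per cell
  tab <- expand.grid(group = c("neurotypical", "pd"),
                     trial_type = c("congruent", "incongruent"))
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(task = "flanker", group = tab$group[i],
               trial_type = tab$trial_type[i],
               rt_ms = 300 + 100 * (tab$trial_type[i] == "incongruent") +
                 resid)
  }))
  gs <- group_stats(rows)
  a <- gs$anova
  expect_lt(a$F[a$term == "group:trial_type"], 1e-20)
  expect_lt(a$F[a$term == "group"], 1e-20)
  expect_gt(a$F[a$term == "trial_type"], 1e3)
})

test_that("behavior summaries reconcile their exclusion accounting", {
  tab <- battery()$sessions$decision.neurotypical
  bs <- behavior_summary(tab, default_config())
  expect_identical(bs$n_raw - bs$n_analyzed, as.integer(sum(bs$exclusions)))
  expect_true(all(bs$per_condition$rt_ms.n > 0))
})
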