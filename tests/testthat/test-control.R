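test_that("a policy already at its goal issues zero control", {
  ctrl <- default_config()$control
  pl <- plant_matrices(ctrl, dt = 1)
  pol <- solve_policy(pl, goal = c(0.3, -0.2), horizon = 100,
                      terminal_weight(ctrl), control_weight(ctrl))
  x <- c(0.3, -0.2, 0, 0)
  for (s in c(1, 25, 50, 100)) {
    expect_equal(policy_command(pol, x, step = s), c(0, 0), tolerance = 1e-12)
  }
})

test_that("one-step scalar policy matches the ridge-regression closed form", {
  # 1-D plant x' = x + b u; cost Q (x' - g)^2 + R u^2
  b <- 0.7; Q <- 3; R <- 0.5; g <- 2; x <- -1
  pl <- list(A = matrix(1), B = matrix(b))
  pol <- solve_policy(pl, goal = g, horizon = 1, Q_T = matrix(Q),
                      R = matrix(R))
  u <- policy_command(pol, x, step = 1)
  u_closed <- b * Q * (g - x) / (R + b^2 * Q)   # one-step ridge toward goal
  expect_equal(u, u_closed, tolerance = 1e-10)
})

test_that("the Riccati recursion matches brute-force enumeration", {
  # tiny instance: scalar plant, 2 steps, finely discretized control set
  b <- 1; Q <- 3; R <- 0.5; g <- 1.5; x0 <- 0
  pl <- list(A = matrix(1), B = matrix(b))
  pol <- solve_policy(pl, goal = g, horizon = 2, Q_T = matrix(Q),
                      R = matrix(R))
  # cost of the policy's own trajectory
  x <- x0; cost_lq <- 0
  for (s in 1:2) {
    u <- policy_command(pol, x, step = s)
    cost_lq <- cost_lq + R * u^2
    x <- x + b * u
  }
  cost_lq <- cost_lq + Q * (x - g)^2
  # exhaustive search over all control sequences on a grid
  grid <- seq(-2, 2, length.out = 161)
  cost_bf <- Inf
  for (u1 in grid) for (u2 in grid) {
    xT <- x0 + b * u1 + b * u2
    cost_bf <- min(cost_bf, R * (u1^2 + u2^2) + Q * (xT - g)^2)
  }
  expect_lte(cost_lq, cost_bf + 1e-9)          # optimal beats the grid
  expect_equal(cost_lq, cost_bf, tolerance = 1e-3)  # within grid resolution
})

test_that("ill-conditioned cost matrices raise a numerical error", {
  pl <- list(A = matrix(1), B = matrix(1))
  expect_error(lqr_gains(pl$A, pl$B, matrix(1), matrix(0), 2),
               "ill-conditioned")
})

test_that("relative desirability normalizes supra-threshold activity", {
  u <- rep(-1, 181)
  u[10] <- 1
  d1 <- relative_desirability(u, gamma = 0.4)
  expect_identical(d1$idx, 10L)
  expect_identical(d1$weights, 1)

  u[170] <- 1
  d2 <- relative_desirability(u, gamma = 0.4)
  expect_equal(d2$weights, c(0.5, 0.5))

  d0 <- relative_desirability(rep(-1, 181), gamma = 0.4)
  expect_length(d0$idx, 0)
  expect_length(d0$weights, 0)

  set.seed(3)
  for (i in 1:50) {
    u <- rnorm(181, mean = runif(1, -1, 1))
    d <- relative_desirability(u, gamma = 0.4, beta = 8, u0 = 0.3)
    if (length(d$weights)) {
      expect_equal(sum(d$weights), 1, tolerance = 1e-12)
      expect_true(all(d$weights >= 0))
    }
  }
})

test_that("policy mixing is the desirability-weighted convex combination", {
  ctrl <- default_config()$control
  pl <- plant_matrices(ctrl, dt = 1)
  QT <- terminal_weight(ctrl); R <- control_weight(ctrl)
  pR <- solve_policy(pl, c(1, 0), 300, QT, R)
  pL <- solve_policy(pl, c(-1, 0), 300, QT, R)
  x <- c(0.05, -0.02, 0.001, 0)

  w1 <- structure(list(idx = 1L, weights = 1), class = "desirability")
  expect_equal(mix_policies(list(pR), w1, x, 10),
               policy_command(pR, x, 10))

  # opposed equal-weight goals at the origin: lateral commands cancel
  w5050 <- structure(list(idx = c(1L, 2L), weights = c(0.5, 0.5)),
                     class = "desirability")
  cmd <- mix_policies(list(pR, pL), w5050, c(0, 0, 0, 0), 10)
  expect_equal(cmd, c(0, 0), tolerance = 1e-12)

  # 0.8 / 0.2: hand-computed convex combination
  w82 <- structure(list(idx = c(1L, 2L), weights = c(0.8, 0.2)),
                   class = "desirability")
  expect_equal(mix_policies(list(pR, pL), w82, x, 10),
               0.8 * policy_command(pR, x, 10) +
                 0.2 * policy_command(pL, x, 10),
               tolerance = 1e-12)

  # empty weights: no-command sentinel
  w0 <- structure(list(idx = integer(0), weights = numeric(0)),
                  class = "desirability")
  expect_null(mix_policies(list(), w0, x, 10))
})

test_that("mixing shared-gain policies equals one law toward the mixed goal", {
  # the identity the trial simulator relies on
  ctrl <- default_config()$control
  pl <- plant_matrices(ctrl, dt = 1)
  QT <- terminal_weight(ctrl); R <- control_weight(ctrl)
  set.seed(9)
  for (i in 1:10) {
    g1 <- runif(2, -1, 1); g2 <- runif(2, -1, 1)
    w <- runif(1)
    x <- c(runif(2, -0.5, 0.5), runif(2, -0.005, 0.005))
    p1 <- solve_policy(pl, g1, 200, QT, R)
    p2 <- solve_policy(pl, g2, 200, QT, R)
    pm <- solve_policy(pl, w * g1 + (1 - w) * g2, 200, QT, R)
    mix <- w * policy_command(p1, x, 40) + (1 - w) * policy_command(p2, x, 40)
    expect_equal(mix, policy_command(pm, x, 40), tolerance = 1e-9)
  }
})

test_that("noise-free instructed reaches land on the target, deterministically", {
  r1 <- sim_trial("decision", "instructed", noise = FALSE,
                  keep_trajectory = TRUE)
  r2 <- sim_trial("decision", "instructed", noise = FALSE,
                  keep_trajectory = TRUE)
  expect_true(r1$responded)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$rt, r2$rt)
  tr <- r1$trajectory
  endpoint <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
  expect_equal(endpoint[1], 1, tolerance = 0.15)   # right target at (1, 0)
  expect_lt(abs(endpoint[2]), 0.2)
  expect_identical(r1$choice, "right")
})

test_that("velocity-rule RT matches threshold crossing plus motor latency", {
  # on single-plan trials the overt movement starts at the threshold
  # crossing plus the motor latency; the two readouts agree within one
  # receding-horizon window
  tau_rhc <- default_config()$control$tau_rhc
  for (s in 1:3) {
    r <- sim_trial("decision", "instructed", seed = s)
    expect_lte(abs(r$rt - r$rt_thresh), tau_rhc)
  }
})

test_that("an immediate stop cue with the pause engaged defeats initiation", {
  r <- sim_trial("stop_signal", "stop", ssd = 0, noise = FALSE)
  expect_false(r$responded)
  expect_identical(r$stop_outcome, "success")
  expect_true(is.na(r$rt))
})
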