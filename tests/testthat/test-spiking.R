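test_that("stimulus encoding is deterministic, disjoint, and validated", {
  ag <- spiking_agent(5, 3)
  expect_identical(encode_stimulus(ag, 2), c(0, 0, 1, 0, 0))
  expect_identical(encode_stimulus(ag, 2), encode_stimulus(ag, 2))
  expect_identical(sum(encode_stimulus(ag, 0) * encode_stimulus(ag, 4)), 0)
  expect_error(encode_stimulus(ag, 5), "unknown stimulus")
})

test_that("traces decay exactly and superpose linearly between events", {
  ag <- spiking_agent(2, 3)
  inc <- matrix(0, 2, 3)
  inc[1, 2] <- 1
  ag <- update_traces(ag, inc, dt = 0)
  # cascade: one impulse loads every trace with the increment
  expect_identical(ag$e1[1, 2], 1)
  expect_identical(ag$e2[1, 2], 1)
  expect_identical(ag$e3[1, 2], 1)
  # pure exponential decay to machine precision at t = tau_i
  for (i in 1:3) {
    ag_i <- update_traces(ag, NULL, dt = ag$tau[i])
    tr <- list(ag_i$e1, ag_i$e2, ag_i$e3)[[i]]
    expect_equal(tr[1, 2], exp(-1), tolerance = 1e-12)
  }
  # two impulses separated by dt superpose as a sum of exponentials
  dt <- 0.3
  ag2 <- update_traces(ag, inc, dt = dt)
  expect_equal(ag2$e1[1, 2], exp(-dt / ag$tau[1]) + 1, tolerance = 1e-12)
  expect_equal(ag2$e3[1, 2],
               exp(-dt / ag$tau[3]) + exp(-dt / ag$tau[2]) +
                 exp(-dt / ag$tau[1]) + 1,
               tolerance = 1e-12)
})

test_that("weight updates are local to the third trace and the reward", {
  ag <- spiking_agent(3, 3)
  w0 <- ag$W
  # e3 = 0 everywhere: no update regardless of reward
  expect_identical(apply_reward(ag, 5)$W, w0)
  # eta = 0: no update regardless of traces
  ag0 <- spiking_agent(3, 3, eta = 0)
  ag0$e3[] <- 1
  expect_identical(apply_reward(ag0, 1)$W, w0)
  # R = rbar: zero advantage, no update
  ag1 <- spiking_agent(3, 3)
  ag1$e3[] <- 1
  ag1$rbar <- 0.5
  expect_identical(apply_reward(ag1, 0.5)$W, w0)
})

test_that("decisions are uniform at zero weights and dominated at large ones", {
  set.seed(42)
  ag <- spiking_agent(1, 3)
  acts <- replicate(3000, spiking_decide(ag, 0)$action)
  tab <- tabulate(acts + 1L, 3L) / 3000
  expect_true(all(abs(tab - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))

  ag$W[1, 2] <- 15  # strongly favor action 1
  acts2 <- replicate(300, spiking_decide(ag, 0)$action)
  expect_gt(mean(acts2 == 1), 0.99)

  # binary task with a silenced population: the no-spike action wins
  agb <- spiking_agent(1, 2)
  agb$W[1, 1] <- -100
  actsb <- replicate(100, spiking_decide(agb, 0)$action)
  expect_true(all(actsb == 1))
})

test_that("the rewarded arm of a bandit is strengthened across seeds", {
  n_seeds <- 20
  gains <- vapply(seq_len(n_seeds), function(s) {
    set.seed(1000 + s)
    ag <- spiking_agent(1, 2)
    choices <- integer(80)
    for (i in seq_along(choices)) {
      out <- spiking_decide(ag, 0, time = ag$clock + 0.5)
      ag <- out$agent
      choices[i] <- out$action
      ag <- apply_reward(ag, as.numeric(out$action == 0))
    }
    mean(choices[41:80] == 0) - mean(choices[1:40] == 0)
  }, numeric(1))
  # paired sign test: improvement in a clear majority of seeds
  expect_gt(mean(gains > 0), 0.7)
  expect_gt(mean(gains), 0)
})

test_that("learning can be switched off", {
  env <- build_switch_env(0)
  r <- run_switch_task(env, n_episodes = 20, n_runs = 3, seed = 2, eta = 0)
  # no trend: late episodes are not systematically shorter than early ones
  expect_gt(mean(r$lengths[, 11:20]), 0.5 * mean(r$lengths[, 1:10]))

  env2 <- feedback_env(4, delay_mode = "immediate", seed = 1)
  r2 <- run_feedback_task(env2, n_trials = 300, seed = 3, eta = 0)
  se <- sqrt(0.25 / 300)
  expect_lt(abs(mean(r2$correct) - 0.5), 3 * se)
})

test_that("untrained episode lengths match the absorption-time oracle", {
  env <- make_fixture("gated-detour-3")
  expected <- oracle_absorption_time(env)
  set.seed(7)
  lens <- simulate_random_walk_lengths(env, 400)
  expect_lt(abs(mean(lens) - expected), 3 * stats::sd(lens) / sqrt(400))
})

test_that("the spiking learner masters both tasks", {
  env <- build_switch_env(0)
  r <- run_switch_task(env, n_episodes = 50, n_runs = 8, seed = 21)
  # convergence: mean episode length falls from the first to the last decile
  d <- rowMeans(r$lengths[, 1:5]) - rowMeans(r$lengths[, 46:50])
  expect_lt(suppressWarnings(
    stats::wilcox.test(d, alternative = "greater")$p.value), 0.01)

  env2 <- feedback_env(10, delay_mode = "immediate", seed = 3)
  r2 <- run_feedback_task(env2, n_trials = 250, seed = 11)
  expect_gte(max(sliding_proportion_correct(r2$correct)$y), 0.9)
})

test_that("category reversal dips and then recovers (switching analogue)", {
  env <- feedback_env(10, delay_mode = "immediate", seed = 5)
  r1 <- run_feedback_task(env, n_trials = 250, seed = 13)
  env2 <- swap_categories(env, 0:4)
  r2 <- run_feedback_task(env2, n_trials = 400, seed = 14, agent = r1$agent)
  y <- sliding_proportion_correct(r2$correct)$y
  expect_lt(min(y[1:50]), 0.5)            # dip right after the swap
  expect_gt(max(y[250:length(y)]), 0.85)  # recovery
  expect_gt(mean(utils::tail(y, 100)), mean(y[1:100]))
})
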