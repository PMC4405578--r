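test_that("responsibility weights normalize over candidate responses", {
  ag <- delay_bayes_agent(2)
  # single outstanding response takes all the weight
  ag$responses <- data.frame(time = 0, image = 0L, action = "left",
                             attributed = 0)
  r <- responsibility_weights(ag, list(time = 2, reward = 1))
  expect_identical(r$w, 1)
  # two responses at equal predictive density split evenly (uniform
  # posterior: every bin has the same mass)
  ag$responses <- data.frame(time = c(0, 1), image = c(0L, 1L),
                             action = c("left", "left"),
                             attributed = c(0, 0))
  r2 <- responsibility_weights(ag, list(time = 2, reward = 1))
  expect_equal(r2$w, c(0.5, 0.5))
  # fully attributed responses and future responses are not candidates
  ag$responses$attributed <- c(1, 0)
  r3 <- responsibility_weights(ag, list(time = 2, reward = 1))
  expect_identical(r3$idx, 2L)
})

test_that("delay posterior obeys the Dirichlet-process limits", {
  # alpha large: posterior stays at the base measure
  ag <- delay_bayes_agent(2, alpha = 1e9)
  ag <- update_delay_posterior(ag, lags = rep(3, 100), w = rep(1, 100))
  expect_equal(delay_posterior_mass(ag), ag$base, tolerance = 1e-5)
  # alpha small with hard lags in one bin: mass concentrates there
  ag2 <- delay_bayes_agent(2, alpha = 1e-9)
  ag2 <- update_delay_posterior(ag2, lags = rep(3, 50), w = rep(1, 50))
  b <- nonmarkov:::delay_bin(ag2, 3)
  expect_gt(delay_posterior_mass(ag2)[b], 0.999)
  # immediate (lag 0) events put the mode at the zero bin
  ag3 <- delay_bayes_agent(2)
  ag3 <- update_delay_posterior(ag3, lags = rep(0, 500), w = rep(1, 500))
  expect_identical(which.max(delay_posterior_mass(ag3)), 1L)
})

test_that("with oracle attribution the posterior mean recovers k*theta", {
  set.seed(77)
  ag <- delay_bayes_agent(2)
  lags <- stats::rgamma(2000, shape = 2, scale = 1.5)
  ag <- update_delay_posterior(ag, lags, rep(1, 2000))
  expect_lt(abs(delay_posterior_mean(ag) - 3.0), 0.15)
})

test_that("category belief updates follow the conjugate fractional rule", {
  # forget = 1: exact Beta-Bernoulli counting, P(left|A) = 2/3 after one
  # correct "left" on image A under the uniform prior
  ag <- delay_bayes_agent(2, forget = 1)
  ag$responses <- data.frame(time = 0, image = 0L, action = "left",
                             attributed = 0)
  ag <- update_category_belief(ag, list(time = 0, reward = 1),
                               list(idx = 1L, w = 1))
  b <- ag$belief[1, ]
  expect_equal((b[1] + 1) / (sum(b) + 2), 2 / 3)
  # zero-weight responses leave the belief untouched
  ag2 <- delay_bayes_agent(2)
  ag2$responses <- data.frame(time = 0, image = 0L, action = "left",
                              attributed = 0)
  ag2 <- update_category_belief(ag2, list(time = 0, reward = 1),
                                list(idx = 1L, w = 0))
  expect_identical(ag2$belief[1, ], c(0, 0))
  # symmetric half-correct half-incorrect evidence keeps a fresh belief
  # at chance (forget = 1: pure conjugate counting, order-independent)
  ag3 <- delay_bayes_agent(2, forget = 1)
  ag3$responses <- data.frame(time = c(0, 0), image = c(0L, 0L),
                              action = c("left", "left"),
                              attributed = c(0, 0))
  ag3 <- update_category_belief(ag3, list(time = 0, reward = 1),
                                list(idx = 1L, w = 0.5))
  ag3 <- update_category_belief(ag3, list(time = 0, reward = -1),
                                list(idx = 2L, w = 0.5))
  b3 <- ag3$belief[1, ]
  expect_equal((b3[1] + 1) / (sum(b3) + 2), 0.5)
})

test_that("greedy decisions are argmax with random ties only", {
  ag <- delay_bayes_agent(1)
  ag$belief[1, ] <- c(10, 0)
  expect_identical(act_delay_bayes(ag, 0), "left")
  ag$belief[1, ] <- c(0, 10)
  expect_identical(act_delay_bayes(ag, 0), "right")
  ag$belief[1, ] <- c(0, 0)
  set.seed(4)
  draws <- replicate(200, act_delay_bayes(ag, 0))
  expect_true(all(c("left", "right") %in% draws))
})

test_that("immediate mode reduces to the plain leaky Beta-Bernoulli
           learner (trace equality)", {
  env <- feedback_env(10, delay_mode = "immediate", seed = 6)
  full <- run_feedback_session(env, delay_bayes_agent(10), 120, seed = 21)
  plain <- run_feedback_session(env, plain_bb_agent(10), 120, seed = 21)
  a1 <- full$log[full$log$event_type == "response", "action"]
  a2 <- plain$log[plain$log$event_type == "response", "action"]
  expect_identical(a1, a2)
})

test_that("the learner reaches ceiling within a 40-trial immediate
           session", {
  for (s in 1:5) {
    env <- feedback_env(10, delay_mode = "immediate", seed = s)
    r <- run_delay_bayes(env, 40, seed = 100 + s)
    expect_identical(utils::tail(sliding_proportion_correct(r$correct)$y, 1), 1)
  }
})

test_that("model attribution beats uniform attribution on gamma delays", {
  set.seed(31)
  # train the delay posterior on the true lag distribution, then present
  # feedback events among B distractor responses and measure the weight
  # put on the true originating response
  ag <- delay_bayes_agent(2)
  ag <- update_delay_posterior(ag, stats::rgamma(500, 2, scale = 1.5),
                               rep(1, 500))
  n_ev <- 300
  b_size <- 5
  w_true <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    times <- sort(stats::runif(b_size, 0, 10))
    origin <- sample.int(b_size, 1)
    ag$responses <- data.frame(time = times, image = 0L, action = "left",
                               attributed = 0)
    ev <- list(time = times[origin] + stats::rgamma(1, 2, scale = 1.5),
               reward = 1)
    r <- responsibility_weights(ag, ev)
    w_true[i] <- sum(r$w[r$idx == origin])
  }
  expect_gt(mean(w_true), 1 / b_size)
})

test_that("learning improves under 400 intermixed-feedback trials", {
  # 30 seeds rather than 50 to keep the default run inside its budget;
  # the paired one-sided test stays at the alpha = 0.01 level
  diffs <- vapply(1:30, function(s) {
    env <- feedback_env(10, delay_mode = "gamma", seed = s)
    r <- run_delay_bayes(env, 400, seed = 200 + s)
    y <- sliding_proportion_correct(r$correct)$y
    mean(utils::tail(y, 50)) - mean(utils::head(y, 50))
  }, numeric(1))
  expect_lt(suppressWarnings(
    stats::wilcox.test(diffs, alternative = "greater")$p.value), 0.01)
})
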