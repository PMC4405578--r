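#' One-parameter softmax policy-gradient baseline
#'
#' A tabular softmax policy (temperature fixed at 1) over observations —
#' the current state id in the navigation task, the image id in the
#' classification task. The policy follows the gradient of the average
#' collected reward: a REINFORCE update with a running-mean baseline. Its
#' only free parameter is the learning rate `eta`.
#'
#' @param eta learning rate (> 0).
#' @param n_actions number of actions.
#' @return an object of class `pg_policy`.
#' @export
pg_policy <- function(eta, n_actions) {
  stopifnot(eta >= 0, n_actions >= 2L)
  structure(list(eta = eta, n_actions = as.integer(n_actions),
                 pref = list(), rbar = 0, n_rewards = 0L),
            class = "pg_policy")
}

pg_pref <- function(pol, obs_key) {
  p <- pol$pref[[obs_key]]
  if (is.null(p)) numeric(pol$n_actions) else p
}

#' Softmax action probabilities for an observation
#'
#' @param pol a `pg_policy`.
#' @param observation observation id (coerced to a key).
#' @return probability vector over actions (each in (0,1), summing to 1).
#' @export
pg_probs <- function(pol, observation) {
  h <- pg_pref(pol, as.character(observation))
  e <- exp(h - max(h))
  e / sum(e)
}

#' Sample an action from the softmax policy
#'
#' @param pol a `pg_policy`.
#' @param observation observation id.
#' @return 0-based action id.
#' @export
pg_act <- function(pol, observation) {
  sample.int(pol$n_actions, 1L, prob = pg_probs(pol, observation)) - 1L
}

#' REINFORCE update with a running-mean baseline
#'
#' For each (observation, action) pair in the trajectory the chosen
#' action's preference moves by `eta * (R - Rbar) * (1 - pi(a|o))` and every
#' other action's by `-eta * (R - Rbar) * pi(a'|o)`; the baseline `Rbar` is
#' then updated as the running mean of all rewards seen.
#'
#' @param pol a `pg_policy`.
#' @param trajectory list of `list(observation, action)` steps (0-based
#'   actions).
#' @param R scalar reward for the trajectory.
#' @return the updated policy.
#' @export
pg_update <- function(pol, trajectory, R) {
  stopifnot(length(trajectory) >= 1L)
  adv <- R - pol$rbar
  for (step in trajectory) {
    key <- as.character(step$observation)
    h <- pg_pref(pol, key)
    pi <- pg_probs(pol, step$observation)
    a <- step$action + 1L
    g <- -pi
    g[a] <- g[a] + 1
    pol$pref[[key]] <- h + pol$eta * adv * g
  }
  pol$n_rewards <- pol$n_rewards + 1L
  pol$rbar <- pol$rbar + (R - pol$rbar) / pol$n_rewards
  pol
}

# ---- task-runner contract -------------------------------------------------

#' Policy-gradient agent for the task runners
#'
#' Navigation task: the observation is the current state id; one update per
#' episode with the episode's binary reward. Classification task: the
#' observation is the image id; one update per delivered feedback, applied
#' to the most recent response (the baseline has no attribution machinery —
#' under intermixed feedback this credit assignment is simply wrong some of
#' the time, which is the point of the comparison).
#'
#' @param eta learning rate.
#' @param n_actions number of actions (3 for navigation, 2 for
#'   classification).
#' @return an agent object of class `pg_agent`.
#' @export
pg_agent <- function(eta = 0.1, n_actions) {
  structure(list(pol = pg_policy(eta, n_actions),
                 traj = list(), last_step = NULL),
            class = "pg_agent")
}

#' @export
agent_begin_episode.pg_agent <- function(agent) {
  agent$traj <- list()
  agent
}

#' @export
agent_act.pg_agent <- function(agent, obs) {
  o <- if (!is.null(obs$state)) obs$state else obs$stimulus
  a <- pg_act(agent$pol, o)
  agent$last_step <- list(observation = o, action = a)
  agent$traj <- c(agent$traj, list(agent$last_step))
  action <- if (!is.null(obs$state)) a else c("left", "right")[a + 1L]
  list(agent = agent, action = action)
}

#' @export
agent_episode_end.pg_agent <- function(agent, success, length) {
  if (length(agent$traj)) {
    agent$pol <- pg_update(agent$pol, agent$traj,
                           R = as.numeric(success))
  }
  agent
}

#' @export
agent_feedback.pg_agent <- function(agent, event) {
  if (!is.null(agent$last_step)) {
    agent$pol <- pg_update(agent$pol, list(agent$last_step), event$reward)
  }
  agent
}

#' Run the policy-gradient baseline on the switch-state task
#'
#' @param env a `switch_env`.
#' @param eta learning rate.
#' @param n_episodes,n_runs,seed,max_steps as in [run_switch_task()].
#' @return list with `lengths` (runs x episodes) and `curve`.
#' @export
run_switch_pg <- function(env, eta = 0.1, n_episodes = 50L, n_runs = 20L,
                          seed = 1L, max_steps = 100L) {
  seeds <- derive_seeds(seed, n_runs)
  lengths <- matrix(NA_integer_, n_runs, n_episodes)
  for (r in seq_len(n_runs)) {
    agent <- pg_agent(eta, env$n_actions)
    run <- run_switch_agent(env, agent, n_episodes, max_steps,
                            seed = seeds[r])
    lengths[r, ] <- run$lengths
  }
  list(lengths = lengths, curve = average_curves(lengths))
}

#' Run the policy-gradient baseline on a classification session
#'
#' @param env a `feedback_env`.
#' @param eta learning rate.
#' @param n_trials,seed session controls.
#' @return list with `correct`, `log`, `agent`.
#' @export
run_feedback_pg <- function(env, eta = 0.1, n_trials = 400L, seed = 1L) {
  agent <- pg_agent(eta, n_actions = 2L)
  out <- run_feedback_session(env, agent, n_trials, seed = seed)
  list(correct = log_correctness(out$log, env), log = out$log,
       agent = out$agent)
}

#' Fit the learning rate to a reference curve
#'
#' Grid search: for each candidate `eta` the supplied `curve_fn` produces
#' the model's mean learning curve (it should average a fixed seed set so
#' the objective is deterministic); the returned `eta` minimizes the
#' residual sum of squares against the reference.
#'
#' @param curve_fn function(eta) -> numeric vector or `learning_curve`.
#' @param reference reference curve (numeric vector or `learning_curve`).
#' @param eta_grid candidate learning rates; default 21 log-spaced points
#'   in `[1e-3, 1]`.
#' @return list with `eta` (the argmin), `rss` (its residual), and `table`
#'   (data frame of all candidates).
#' @export
fit_learning_rate <- function(curve_fn, reference,
                              eta_grid = 10^seq(-3, 0, length.out = 21)) {
  stopifnot(length(eta_grid) >= 1L)
  res <- vapply(eta_grid, function(e) rss(curve_fn(e), reference),
                numeric(1L))
  best <- which.min(res)
  list(eta = eta_grid[best], rss = res[best],
       table = data.frame(eta = eta_grid, rss = res))
}
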