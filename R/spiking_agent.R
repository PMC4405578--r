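#' Population-of-spiking-neurons policy-gradient learner
#'
#' A three-layer network: an input layer X with one sub-population of
#' Poisson neurons per stimulus (fixed, non-learned encoding), a hidden
#' spiking layer Y, and a decision layer that reads out Y. Decisions are
#' made from spike counts: for binary tasks the action is whether the
#' majority of the readout population spiked in the decision window; with
#' more actions each action has its own readout population and the largest
#' spike count wins (ties uniform at random). Spike sampling is the
#' exploration mechanism — no explicit softmax or epsilon-greedy.
#'
#' Learning is policy-gradient through a cascade of three eligibility
#' traces kept per X->Y synapse group. Spiking events feed the first trace;
#' each trace feeds the next, and between events every trace decays
#' exponentially with its own time constant — `tau1` at the timescale of
#' individual spikes, `tau2` at the stimulus duration, `tau3` at the reward
#' delay, so decision information persists until reward reception. The
#' weight update uses only the third trace and the reward:
#' `dW = eta * (R - Rbar) * e3`, with `Rbar` a running average baseline
#' (variance reduction; settable to a fixed 0).
#'
#' The per-event increment to the first trace is the Poisson/binomial score
#' (observed minus expected spike count of the readout, normalized by the
#' population count-scale), times the presynaptic activity of the active
#' stimulus sub-population: the REINFORCE gradient estimator for spiking
#' readouts.
#'
#' @param n_stimuli number of distinct stimuli the X layer encodes.
#' @param n_actions number of available actions (2 uses the majority rule,
#'   otherwise argmax over per-action readout populations).
#' @param eta learning rate (the model's single free parameter).
#' @param n_neurons neurons per sub-population (default 50).
#' @param rate0 baseline firing rate in Hz of a readout population
#'   (argmax mode).
#' @param min_rate floor on readout rates in Hz; keeps spike sampling (and
#'   with it the gradient and exploration) alive however depressed a
#'   synapse becomes.
#' @param t_stim stimulus duration / decision window in seconds.
#' @param tau decay constants `c(tau1, tau2, tau3)` in seconds.
#' @param baseline_rate update rate of the running reward baseline `Rbar`
#'   (0 freezes the baseline at its initial value 0).
#' @param w_clip symmetric bound on synaptic weights (keeps rates finite).
#' @return an object of class `spiking_agent`.
#' @export
spiking_agent <- function(n_stimuli, n_actions, eta = 0.3,
                          n_neurons = 50L, rate0 = 5, t_stim = 0.5,
                          tau = c(0.02, 0.5, 4), baseline_rate = 0.1,
                          min_rate = 0.5, w_clip = 20) {
  stopifnot(n_stimuli >= 1L, n_actions >= 2L, eta >= 0,
            length(tau) == 3L, all(diff(tau) > 0))
  n_pop <- if (n_actions == 2L) 1L else n_actions
  zero <- matrix(0, nrow = n_stimuli, ncol = n_pop)
  structure(list(n_stimuli = as.integer(n_stimuli),
                 n_actions = as.integer(n_actions),
                 binary = n_actions == 2L,
                 eta = eta, n_neurons = as.integer(n_neurons),
                 rate0 = rate0, t_stim = t_stim, tau = tau,
                 baseline_rate = baseline_rate, min_rate = min_rate,
                 w_clip = w_clip,
                 W = zero, e1 = zero, e2 = zero, e3 = zero,
                 rbar = 0, clock = 0),
            class = "spiking_agent")
}

#' Encode a stimulus as an X-layer rate pattern
#'
#' Deterministic one-sub-population-active encoding: distinct stimuli map to
#' disjoint active sub-populations. Returns the normalized per-sub-population
#' activity vector (the Poisson rate pattern driving the hidden layer).
#'
#' @param agent a `spiking_agent`.
#' @param stimulus 0-based stimulus id.
#' @return numeric vector of length `n_stimuli` with a single 1 at the
#'   active sub-population.
#' @export
encode_stimulus <- function(agent, stimulus) {
  stimulus <- as.integer(stimulus)
  if (is.na(stimulus) || stimulus < 0L || stimulus >= agent$n_stimuli) {
    stop("unknown stimulus id: ", stimulus)
  }
  x <- numeric(agent$n_stimuli)
  x[stimulus + 1L] <- 1
  x
}

# decay all traces from agent$clock to `time`
decay_traces_to <- function(agent, time) {
  dt <- time - agent$clock
  if (dt > 0) {
    agent$e1 <- agent$e1 * exp(-dt / agent$tau[1L])
    agent$e2 <- agent$e2 * exp(-dt / agent$tau[2L])
    agent$e3 <- agent$e3 * exp(-dt / agent$tau[3L])
    agent$clock <- time
  }
  agent
}

#' Advance the eligibility-trace cascade by one event
#'
#' Pure exponential decay over `dt`, then the event increment: the first
#' trace receives the (pre x post-score) spike term, the second accumulates
#' the first, the third accumulates the second.
#'
#' @param agent a `spiking_agent`.
#' @param increment matrix increment for the first trace (same shape as the
#'   weight matrix), or `NULL` for decay only.
#' @param dt elapsed time in seconds since the previous event (> 0 allowed
#'   to be 0 for simultaneous events).
#' @return the updated agent.
#' @export
update_traces <- function(agent, increment = NULL, dt = 0) {
  stopifnot(dt >= 0)
  agent <- decay_traces_to(agent, agent$clock + dt)
  if (!is.null(increment)) {
    agent$e1 <- agent$e1 + increment
    agent$e2 <- agent$e2 + agent$e1
    agent$e3 <- agent$e3 + agent$e2
  }
  agent
}

#' Spike the readout and pick an action
#'
#' Binary mode: one readout population; each neuron spikes with probability
#' `1 - exp(-rate * t_stim)` where the rate is `log(2)/t_stim + W[s, 1]`
#' (chance level 1/2 at zero weight); the action is "did the majority
#' spike". Argmax mode: per-action Poisson populations with rate
#' `max(0, rate0 + W[s, a])`; the largest aggregate count wins.
#'
#' The eligibility increment recorded with the decision is the centered
#' spike-count score of every readout population, scaled by the population
#' count scale, on the active stimulus row only.
#'
#' @param agent a `spiking_agent`.
#' @param stimulus 0-based stimulus id.
#' @param time decision time in seconds (traces decay to this time first).
#' @return list(agent, action) with a 0-based action id.
#' @export
spiking_decide <- function(agent, stimulus, time = agent$clock) {
  agent <- decay_traces_to(agent, time)
  s <- as.integer(stimulus) + 1L
  if (s < 1L || s > agent$n_stimuli) stop("unknown stimulus id: ", stimulus)
  N <- agent$n_neurons
  inc <- matrix(0, nrow = agent$n_stimuli, ncol = ncol(agent$W))
  if (agent$binary) {
    rate <- log(2) / agent$t_stim + agent$W[s, 1L]
    p <- 1 - exp(-pmax(rate, agent$min_rate) * agent$t_stim)
    n_spiked <- stats::rbinom(1L, N, p)
    action <- if (n_spiked > N / 2) {
      0L
    } else if (n_spiked < N / 2) {
      1L
    } else {
      sample(0:1, 1L)
    }
    inc[s, 1L] <- (n_spiked - N * p) / N
  } else {
    rates <- pmax(agent$rate0 + agent$W[s, ], agent$min_rate)
    lambda <- N * agent$t_stim * rates
    counts <- stats::rpois(length(lambda), lambda)
    action <- argmax_tie(counts) - 1L
    inc[s, ] <- (counts - lambda) / (N * agent$t_stim)
  }
  agent <- update_traces(agent, increment = inc, dt = 0)
  list(agent = agent, action = action)
}

#' Apply a reward to the network
#'
#' `dW = eta * (R - Rbar) * e3`; nothing but the third trace and the reward
#' enters the update. The running baseline is then moved toward `R`.
#'
#' @param agent a `spiking_agent`.
#' @param R scalar reward.
#' @param time delivery time in seconds.
#' @return the updated agent.
#' @export
apply_reward <- function(agent, R, time = agent$clock) {
  stopifnot(is.finite(R))
  agent <- decay_traces_to(agent, time)
  agent$W <- agent$W + agent$eta * (R - agent$rbar) * agent$e3
  agent$W <- pmin(pmax(agent$W, -agent$w_clip), agent$w_clip)
  agent$rbar <- agent$rbar + agent$baseline_rate * (R - agent$rbar)
  agent
}

# reset traces at an episode boundary (decisions cannot be credited across
# episodes in the episodic switch task)
reset_traces <- function(agent) {
  agent$e1[] <- 0
  agent$e2[] <- 0
  agent$e3[] <- 0
  agent
}

# ---- task-runner contract -------------------------------------------------

#' @export
agent_begin_episode.spiking_agent <- function(agent) reset_traces(agent)

#' @export
agent_act.spiking_agent <- function(agent, obs) {
  if (!is.null(obs$state)) {
    spiking_decide(agent, obs$state, time = agent$clock + agent$t_stim)
  } else {
    out <- spiking_decide(agent, obs$stimulus, time = obs$time)
    out$action <- c("left", "right")[out$action + 1L]
    out
  }
}

#' @export
agent_observe_step.spiking_agent <- function(agent, obs, action, next_state,
                                             reward, done) {
  if (done) apply_reward(agent, reward) else agent
}

#' @export
agent_episode_end.spiking_agent <- function(agent, success, length) {
  if (!success) apply_reward(agent, 0) else agent
}

#' @export
agent_feedback.spiking_agent <- function(agent, event) {
  apply_reward(agent, event$reward, time = event$time)
}

#' Run the spiking learner on the switch-state task
#'
#' @param env a `switch_env`.
#' @param n_episodes episodes per run (default 50).
#' @param n_runs number of independently seeded runs (>= 1; 20 gives stable
#'   medians).
#' @param seed master seed; run seeds are derived from it.
#' @param max_steps episode truncation cap.
#' @param ... passed to [spiking_agent()].
#' @return list with `lengths` (runs x episodes matrix), `curve` (mean
#'   episode-length `learning_curve` with SEM), and `first_optimal`
#'   (per run, the first episode whose length equals the environment
#'   minimum; NA when never attained).
#' @export
run_switch_task <- function(env, n_episodes = 50L, n_runs = 20L, seed = 1L,
                            max_steps = 100L, ...) {
  seeds <- derive_seeds(seed, n_runs)
  opt <- shortest_episode_length(env)
  lengths <- matrix(NA_integer_, nrow = n_runs, ncol = n_episodes)
  for (r in seq_len(n_runs)) {
    agent <- spiking_agent(n_stimuli = env$n_states,
                           n_actions = env$n_actions, ...)
    run <- run_switch_agent(env, agent, n_episodes, max_steps,
                            seed = seeds[r])
    lengths[r, ] <- run$lengths
  }
  first_optimal <- apply(lengths, 1L, function(l) {
    hit <- which(l == opt)
    if (length(hit)) hit[1L] else NA_integer_
  })
  list(lengths = lengths, curve = average_curves(lengths),
       first_optimal = first_optimal)
}

#' Run the spiking learner on the classification task
#'
#' Delayed rewards are applied through the third eligibility trace at
#' delivery time, so credit spreads over recent decisions exactly as far as
#' the trace has decayed.
#'
#' @param env a `feedback_env`.
#' @param n_trials trials per session.
#' @param seed session seed.
#' @param agent optionally a pre-trained `spiking_agent` to continue from.
#' @param ... passed to [spiking_agent()] when `agent` is NULL.
#' @return list with `correct` (logical per trial), `log`, and `agent`.
#' @export
run_feedback_task <- function(env, n_trials = 400L, seed = 1L,
                              agent = NULL, ...) {
  if (is.null(agent)) {
    agent <- spiking_agent(n_stimuli = env$n_images, n_actions = 2L, ...)
  }
  out <- run_feedback_session(env, agent, n_trials, seed = seed)
  list(correct = log_correctness(out$log, env), log = out$log,
       agent = out$agent)
}
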