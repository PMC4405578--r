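#' Agent contract
#'
#' All learner families implement a small S3 contract so that the task
#' runners ([run_switch_agent()], [run_feedback_session()]) are agnostic to
#' the learning algorithm:
#'
#' * `agent_act(agent, obs)` — observe and choose; returns
#'   `list(agent = <updated agent>, action = <action>)`. For the switch task
#'   `obs` is `list(state = <0-based state id>)`; for the feedback task it is
#'   `list(stimulus = <0-based image id>, time = <seconds>)`.
#' * `agent_feedback(agent, event)` — receive one feedback event
#'   (`list(time, reward)`, reward +1 correct / -1 incorrect); returns the
#'   updated agent.
#' * `agent_begin_episode(agent)` / `agent_episode_end(agent, success,
#'   length)` — episode bracketing for the switch task.
#' * `agent_observe_step(agent, obs, action, next_state, reward, done)` —
#'   per-step learning signal for the switch task.
#'
#' Defaults are no-ops so agents implement only what they use.
#'
#' @param agent an agent object.
#' @param obs observation (see above).
#' @param event feedback event.
#' @param success,length episode outcome.
#' @param action,next_state,reward,done step transition record.
#' @name agent_contract
NULL

#' @rdname agent_contract
#' @export
agent_act <- function(agent, obs) UseMethod("agent_act")

#' @rdname agent_contract
#' @export
agent_feedback <- function(agent, event) UseMethod("agent_feedback")

#' @rdname agent_contract
#' @export
agent_feedback.default <- function(agent, event) agent

#' @rdname agent_contract
#' @export
agent_begin_episode <- function(agent) UseMethod("agent_begin_episode")

#' @rdname agent_contract
#' @export
agent_begin_episode.default <- function(agent) agent

#' @rdname agent_contract
#' @export
agent_episode_end <- function(agent, success, length) {
  UseMethod("agent_episode_end")
}

#' @rdname agent_contract
#' @export
agent_episode_end.default <- function(agent, success, length) agent

#' @rdname agent_contract
#' @export
agent_observe_step <- function(agent, obs, action, next_state, reward, done) {
  UseMethod("agent_observe_step")
}

#' @rdname agent_contract
#' @export
agent_observe_step.default <- function(agent, obs, action, next_state,
                                       reward, done) agent

#' Run an agent on the switch-state task
#'
#' Episodes are truncated at `max_steps` actions (the analogue of the human
#' 10-minute wall clock); truncation is recorded.
#'
#' @param env a `switch_env`.
#' @param agent any agent implementing the switch-task contract.
#' @param n_episodes number of episodes (default 50).
#' @param max_steps episode truncation cap in actions (default 100).
#' @param seed optional integer; when given, the run draws from a private
#'   seeded RNG stream.
#' @return list with `lengths` (integer vector of episode lengths in
#'   actions), `truncated` (logical vector), and `agent` (final state).
#' @export
run_switch_agent <- function(env, agent, n_episodes = 50L, max_steps = 100L,
                             seed = NULL) {
  body <- function() {
    lengths <- integer(n_episodes)
    truncated <- logical(n_episodes)
    for (ep in seq_len(n_episodes)) {
      agent <- agent_begin_episode(agent)
      es <- new_episode(env)
      done <- FALSE
      while (!done && es$step_count < max_steps) {
        obs <- list(state = es$current_state)
        act <- agent_act(agent, obs)
        agent <- act$agent
        step <- env_step(env, es, act$action)
        agent <- agent_observe_step(agent, obs, act$action,
                                    step$state$current_state,
                                    step$reward, step$done)
        es <- step$state
        done <- step$done
      }
      lengths[ep] <- es$step_count
      truncated[ep] <- !done
      agent <- agent_episode_end(agent, success = done,
                                 length = es$step_count)
    }
    list(lengths = lengths, truncated = truncated, agent = agent)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}
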