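#' Switch-state navigation environment
#'
#' A deterministic directed graph over `n_states` image states plus a goal
#' state. Each image state offers `n_actions` discrete actions. The goal is
#' reachable from exactly one state (the pre-goal state) via one designated
#' action, and only if a designated switch state has been visited earlier in
#' the episode; otherwise the same action redirects to a decoy state. This
#' gating makes the task non-Markovian: the effect of an action depends on
#' episode history, not just the current state.
#'
#' States and actions are 0-based integers; the goal state id is `n_states`.
#'
#' @name switch_env
NULL

#' Build a random switch-state environment
#'
#' Transition structure is rejection-sampled until all structural constraints
#' hold: deterministic transitions, goal gated on the switch state, at least
#' one recurrent (self-loop) and one outward connection, and a shortest
#' successful episode of exactly `min_episode` actions (verified by
#' breadth-first search over the (state, switch-visited) product space).
#'
#' @param seed integer seed; the construction is deterministic given the seed.
#' @param n_states number of image states (>= 3; default 8).
#' @param n_actions number of actions per state (default 3).
#' @param min_episode required shortest successful episode length in actions
#'   (>= 2; default 5).
#' @param max_attempts rejection-sampling budget before giving up.
#' @return an object of class `switch_env` with fields `n_states`,
#'   `n_actions`, `start`, `goal`, `switch_state`, `pre_goal_state`,
#'   `goal_action`, `decoy_state`, `transitions` (an `n_states x n_actions`
#'   matrix of successor image states, 0-based), and `seed`.
#' @export
build_switch_env <- function(seed, n_states = 8L, n_actions = 3L,
                             min_episode = 5L, max_attempts = 20000L) {
  n_states <- as.integer(n_states)
  n_actions <- as.integer(n_actions)
  min_episode <- as.integer(min_episode)
  stopifnot(n_states >= 3L, n_actions >= 2L, min_episode >= 2L)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      env <- propose_switch_env(n_states, n_actions, min_episode, seed)
      if (is.null(env)) next
      if (switch_env_valid(env, min_episode)) return(env)
    }
    stop("no valid switch-state graph found in ", max_attempts,
         " attempts; constraints may be inconsistent")
  })
}

# one random candidate graph (NULL if the role draw is degenerate)
propose_switch_env <- function(n_states, n_actions, min_episode, seed) {
  states <- 0:(n_states - 1L)
  start <- 0L
  # roles: switch and pre-goal distinct from start; for very small graphs
  # (tiny fixtures) the switch may coincide with the pre-goal state
  roles <- sample(states[-1L], min(2L, n_states - 1L), replace = n_states < 5L)
  switch_state <- roles[1L]
  pre_goal <- if (length(roles) >= 2L) roles[2L] else roles[1L]
  if (n_states >= 5L && switch_state == pre_goal) return(NULL)
  decoy_pool <- setdiff(states, pre_goal)
  decoy <- if (length(decoy_pool) == 1L) decoy_pool else sample(decoy_pool, 1L)
  trans <- matrix(sample(states, n_states * n_actions, replace = TRUE),
                  nrow = n_states, ncol = n_actions)
  goal_action <- sample(0:(n_actions - 1L), 1L)
  # the goal-directed action's ungated outcome is the decoy redirect
  trans[pre_goal + 1L, goal_action + 1L] <- decoy
  structure(list(n_states = n_states, n_actions = n_actions,
                 start = start, goal = n_states,
                 switch_state = switch_state, pre_goal_state = pre_goal,
                 goal_action = goal_action, decoy_state = decoy,
                 transitions = trans, seed = seed),
            class = "switch_env")
}

# structural acceptance for a candidate graph
switch_env_valid <- function(env, min_episode) {
  tr <- env$transitions
  self_ref <- any(tr == matrix(0:(env$n_states - 1L), nrow = env$n_states,
                               ncol = env$n_actions))
  outward <- any(tr != matrix(0:(env$n_states - 1L), nrow = env$n_states,
                              ncol = env$n_actions))
  if (!self_ref || !outward) return(FALSE)
  shortest_episode_length(env) == min_episode &&
    !is.finite(shortest_episode_length(env, gated = FALSE))
}

#' @export
print.switch_env <- function(x, ...) {
  cat("<switch_env> ", x$n_states, " states x ", x$n_actions, " actions; ",
      "start=", x$start, " switch=", x$switch_state,
      " pre-goal=", x$pre_goal_state, " decoy=", x$decoy_state,
      "; shortest episode=", shortest_episode_length(x), "\n", sep = "")
  invisible(x)
}

#' Start a new episode
#'
#' @param env a `switch_env`.
#' @return an `episode_state` with the agent at the start state, the
#'   switch-visited flag reset (set immediately if the start IS the switch
#'   state), and a zero step count.
#' @export
new_episode <- function(env) {
  structure(list(current_state = env$start,
                 switch_visited = env$start == env$switch_state,
                 step_count = 0L, done = FALSE),
            class = "episode_state")
}

#' Take one action in the switch-state environment
#'
#' From the pre-goal state, the goal action leads to the goal (reward 1,
#' episode done) when the switch state has been visited this episode, and to
#' the decoy state otherwise. All other transitions follow the environment's
#' deterministic transition table with zero reward. The switch-visited flag
#' is set on arrival at the switch state and is monotone within an episode.
#'
#' @param env a `switch_env`.
#' @param es an `episode_state`.
#' @param action 0-based action id.
#' @return list with fields `state` (updated `episode_state`), `reward`
#'   (0 or 1), and `done` (logical).
#' @export
env_step <- function(env, es, action) {
  if (es$done) stop("episode is finished; reset with new_episode()")
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action >= env$n_actions) {
    stop("undefined action id: ", action)
  }
  s <- es$current_state
  reward <- 0
  done <- FALSE
  if (s == env$pre_goal_state && action == env$goal_action && es$switch_visited) {
    nxt <- env$goal
    reward <- 1
    done <- TRUE
  } else {
    nxt <- env$transitions[s + 1L, action + 1L]
  }
  es$current_state <- nxt
  es$switch_visited <- es$switch_visited || identical(nxt, env$switch_state)
  es$step_count <- es$step_count + 1L
  es$done <- done
  list(state = es, reward = reward, done = done)
}

#' Shortest successful episode length
#'
#' Breadth-first search over the product space (state, switch-visited flag).
#' Serves as the independent check on the construction constraint.
#'
#' @param env a `switch_env`.
#' @param gated if `FALSE`, the search is restricted to the
#'   switch-not-visited layer (the switch state is treated as a wall), which
#'   verifies that the goal is unreachable without the switch.
#' @return integer number of actions on the shortest start-to-goal path, or
#'   `Inf` if the goal is unreachable.
#' @export
shortest_episode_length <- function(env, gated = TRUE) {
  n <- env$n_states
  # product node index: state + n * flag (flag in {0,1}); goal is absorbing
  node_id <- function(s, f) s + n * f + 1L
  start_flag <- as.integer(env$start == env$switch_state)
  if (!gated && start_flag == 1L) return(Inf)
  dist <- rep(NA_integer_, 2L * n)
  start <- node_id(env$start, start_flag)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt_frontier <- integer(0)
    for (v in frontier) {
      f <- (v - 1L) %/% n
      s <- (v - 1L) %% n
      for (a in 0:(env$n_actions - 1L)) {
        if (s == env$pre_goal_state && a == env$goal_action && f == 1L) {
          return(dist[v] + 1L)
        }
        s2 <- env$transitions[s + 1L, a + 1L]
        f2 <- as.integer(f == 1L || s2 == env$switch_state)
        if (!gated && f2 == 1L) next
        w <- node_id(s2, f2)
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt_frontier <- c(nxt_frontier, w)
        }
      }
    }
    frontier <- nxt_frontier
  }
  Inf
}
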