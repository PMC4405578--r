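#' Posterior over action sequences
#'
#' For every action sequence `s` the learner tracks two Beta-Bernoulli
#' posteriors: `P(C|s)`, the probability that the sequence continues (is
#' non-terminal), and `P(R|~C, s)`, the probability of reward given that the
#' episode terminates at `s`. In the deterministic environment a single
#' observation collapses each to a point mass: observed-terminal nodes have
#' `P(C|s) = 0`, observed prefixes of longer episodes have `P(C|s) = 1`, and
#' unobserved nodes keep their prior predictive (0.5 under the uniform
#' Beta(1,1) prior).
#'
#' @param n_actions size of the action alphabet.
#' @param prior_c,prior_r Beta prior parameters `c(a, b)` for continuation
#'   and reward (default uniform Beta(1,1)).
#' @param deterministic if `TRUE` (the switch task), contradictory
#'   observations raise an error and observations collapse to point masses.
#' @return an object of class `sequence_posterior`.
#' @export
sequence_posterior <- function(n_actions, prior_c = c(1, 1),
                               prior_r = c(1, 1), deterministic = TRUE) {
  structure(list(n_actions = as.integer(n_actions),
                 prior_c = prior_c, prior_r = prior_r,
                 deterministic = deterministic,
                 nodes = list()),
            class = "sequence_posterior")
}

seq_key <- function(actions) paste(actions, collapse = ".")

# predictive P(continue) and P(reward | terminal) for a vector of keys
node_probs <- function(post, keys) {
  pc <- numeric(length(keys))
  pr <- numeric(length(keys))
  pc0 <- post$prior_c[1L] / sum(post$prior_c)
  pr0 <- post$prior_r[1L] / sum(post$prior_r)
  for (i in seq_along(keys)) {
    nd <- post$nodes[[keys[i]]]
    if (is.null(nd)) {
      pc[i] <- pc0
      pr[i] <- pr0
    } else {
      pc[i] <- (post$prior_c[1L] + nd["cont"]) /
        (sum(post$prior_c) + nd["cont"] + nd["term"])
      pr[i] <- (post$prior_r[1L] + nd["rew"]) /
        (sum(post$prior_r) + nd["rew"] + nd["norew"])
      if (post$deterministic) {
        if (nd["cont"] > 0) pc[i] <- 1
        if (nd["term"] > 0) {
          pc[i] <- 0
          pr[i] <- as.numeric(nd["rew"] > 0)
        }
      }
    }
  }
  list(pc = pc, pr = pr)
}

#' Record one finished episode in a sequence posterior
#'
#' Every proper prefix of the episode's action sequence is marked as
#' continuing; the full sequence is marked terminal with its reward flag.
#' No other node is touched.
#'
#' @param post a `sequence_posterior`.
#' @param actions integer vector of 0-based actions taken in the episode.
#' @param rewarded logical: did the episode terminate with reward?
#' @return the updated posterior.
#' @export
update_sequence_posterior <- function(post, actions, rewarded) {
  stopifnot(length(actions) >= 1L)
  touch <- function(key, field) {
    nd <- post$nodes[[key]]
    if (is.null(nd)) {
      nd <- c(cont = 0, term = 0, rew = 0, norew = 0)
    }
    if (post$deterministic) {
      if (field == "cont" && nd["term"] > 0) {
        stop("contradiction: sequence ", key,
             " observed both terminal and continuing")
      }
      if (field != "cont" && nd["cont"] > 0) {
        stop("contradiction: sequence ", key,
             " observed both terminal and continuing")
      }
      if (field == "rew" && nd["norew"] > 0 ||
          field == "norew" && nd["rew"] > 0) {
        stop("contradiction: sequence ", key,
             " observed with conflicting rewards")
      }
    }
    nd[field] <- nd[field] + 1
    if (field %in% c("rew", "norew")) nd["term"] <- nd["term"] + 1
    post$nodes[[key]] <<- nd
    invisible(NULL)
  }
  n <- length(actions)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) touch(seq_key(actions[seq_len(i)]), "cont")
  }
  touch(seq_key(actions), if (rewarded) "rew" else "norew")
  post
}

#' Sample outcome trees and tally rewarded sequences
#'
#' Each tree grows breadth-first over the action alphabet. At every node the
#' tree samples "continue" from `P(C|s)` and, for terminal nodes, "reward"
#' from `P(R|~C, s)`. As soon as a depth contains a sampled rewarded
#' terminal, the counters of the rewarded sequences at that depth are
#' incremented and the tree is not grown any deeper. Trees that hit the
#' depth cap are discarded and counted.
#'
#' @param post a `sequence_posterior`.
#' @param n_trees number of trees to sample (>= 1).
#' @param depth_cap maximum tree depth (default 12).
#' @return list with `counters` (named numeric, one entry per sequence ever
#'   credited) and `discarded` (trees that hit the cap).
#' @export
sample_outcome_trees <- function(post, n_trees, depth_cap = 12L) {
  n_actions <- post$n_actions
  counters <- numeric(0)
  keys <- as.character(0:(n_actions - 1L))
  active <- matrix(TRUE, nrow = n_trees, ncol = n_actions)
  discarded <- 0L
  for (d in seq_len(depth_cap)) {
    if (!any(active)) break
    pp <- node_probs(post, keys)
    nk <- length(keys)
    cont <- active &
      matrix(stats::runif(n_trees * nk), n_trees, nk) <
        matrix(pp$pc, n_trees, nk, byrow = TRUE)
    term <- active & !cont
    rew <- term &
      matrix(stats::runif(n_trees * nk), n_trees, nk) <
        matrix(pp$pr, n_trees, nk, byrow = TRUE)
    hit <- rowSums(rew) > 0
    if (any(hit)) {
      inc <- colSums(rew[hit, , drop = FALSE])
      for (i in which(inc > 0)) {
        counters[keys[i]] <- (if (is.na(counters[keys[i]])) 0
                              else counters[keys[i]]) + inc[i]
      }
      cont[hit, ] <- FALSE
    }
    if (d == depth_cap) {
      discarded <- sum(rowSums(cont) > 0)
      break
    }
    keep <- which(colSums(cont) > 0)
    if (!length(keep)) break
    keys <- as.vector(vapply(keys[keep], function(k) {
      paste(k, 0:(n_actions - 1L), sep = ".")
    }, character(n_actions)))
    active <- cont[, rep(keep, each = n_actions), drop = FALSE]
  }
  list(counters = counters, discarded = discarded)
}

#' Sample a single outcome tree
#'
#' Convenience wrapper around [sample_outcome_trees()] with `n_trees = 1`.
#'
#' @inheritParams sample_outcome_trees
#' @return list with `credited` (character keys of credited sequences,
#'   possibly empty) and `discarded` (logical).
#' @export
sample_outcome_tree <- function(post, depth_cap = 12L) {
  out <- sample_outcome_trees(post, 1L, depth_cap)
  list(credited = names(out$counters), discarded = out$discarded > 0L)
}

#' MAP action sequence by Monte-Carlo tree counting
#'
#' The sequence with the highest counter across `n_trees` sampled outcome
#' trees is the MAP estimate of the best sequence. Ties are broken uniformly
#' at random. If every counter is zero the learner falls back to the
#' shallowest unexplored sequence (exploration).
#'
#' @param post a `sequence_posterior`.
#' @param n_trees trees to sample (default 5000, "thousands").
#' @param depth_cap maximum tree depth.
#' @return integer vector of 0-based actions.
#' @export
map_sequence <- function(post, n_trees = 5000L, depth_cap = 12L) {
  stopifnot(n_trees >= 1L)
  out <- sample_outcome_trees(post, n_trees, depth_cap)
  if (!length(out$counters)) {
    return(shortest_unexplored(post, depth_cap))
  }
  best <- names(out$counters)[argmax_tie(out$counters)]
  as.integer(strsplit(best, ".", fixed = TRUE)[[1L]])
}

# shallowest sequence with no observation yet, uniform among candidates
shortest_unexplored <- function(post, depth_cap = 12L) {
  frontier <- lapply(0:(post$n_actions - 1L), identity)
  for (d in seq_len(depth_cap)) {
    unexplored <- frontier[vapply(frontier, function(a) {
      is.null(post$nodes[[seq_key(a)]])
    }, logical(1L))]
    if (length(unexplored)) {
      return(as.integer(unexplored[[sample.int(length(unexplored), 1L)]]))
    }
    frontier <- unlist(lapply(frontier, function(a) {
      keep <- post$nodes[[seq_key(a)]]
      if (!is.null(keep) && keep[["term"]] > 0) return(list())
      lapply(0:(post$n_actions - 1L), function(x) c(a, x))
    }), recursive = FALSE)
    if (!length(frontier)) break
  }
  sample.int(post$n_actions, 1L) - 1L
}

# ---- transition posterior (Models 2 and 3) --------------------------------

#' Dirichlet-categorical posterior over state transitions
#'
#' Per (state, action) pair, a categorical posterior over successor states
#' (including the goal). The predictive is the empirical visit-count ratio,
#' so a deterministic transition collapses to a point mass after one
#' observation; an unvisited pair has no predictive and is treated
#' optimistically by the planner.
#'
#' @param n_states number of image states.
#' @param n_actions actions per state.
#' @return an object of class `transition_posterior`.
#' @export
transition_posterior <- function(n_states, n_actions) {
  counts <- array(0, dim = c(n_states, n_actions, n_states + 1L))
  structure(list(n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions),
                 counts = counts),
            class = "transition_posterior")
}

#' Record one observed transition
#'
#' @param tp a `transition_posterior`.
#' @param s,a,s2 0-based state, action, successor (successor may be the
#'   goal id `n_states`).
#' @return the updated posterior.
#' @export
tp_update <- function(tp, s, a, s2) {
  tp$counts[s + 1L, a + 1L, s2 + 1L] <- tp$counts[s + 1L, a + 1L, s2 + 1L] + 1
  tp
}

#' Posterior-predictive successor distribution
#'
#' @param tp a `transition_posterior`.
#' @param s,a 0-based state and action.
#' @return numeric vector of length `n_states + 1` (last entry = goal), or
#'   `NULL` if the pair has never been tried.
#' @export
tp_predictive <- function(tp, s, a) {
  cnt <- tp$counts[s + 1L, a + 1L, ]
  n <- sum(cnt)
  if (n == 0) return(NULL)
  cnt / n
}

#' Action values by value iteration on the learned Markov model
#'
#' Reward 1 on any transition into the goal, discount `gamma` to prefer
#' short routes; unvisited (state, action) pairs carry the optimistic value
#' 1 (as if they led straight to the goal), which drives systematic
#' exploration. The gating flag is *not* part of the state — the Markov
#' assumption is precisely these models' limitation.
#'
#' @param tp a `transition_posterior`.
#' @param gamma discount factor in (0, 1).
#' @param tol,max_iter convergence controls.
#' @param v0 optional warm-start state values from a previous call.
#' @return an `n_states x n_actions` matrix of Q values, with the converged
#'   state values attached as attribute `"v"`.
#' @export
plan_values <- function(tp, gamma = 0.95, tol = 1e-9, max_iter = 500L,
                        v0 = NULL) {
  ns <- tp$n_states
  na <- tp$n_actions
  cnt <- matrix(tp$counts, ns * na, ns + 1L)  # row = (s, a) pair
  tot <- rowSums(cnt)
  tried <- tot > 0
  p <- cnt / pmax(tot, 1)
  r <- p[, ns + 1L]
  p_img <- p[, seq_len(ns), drop = FALSE]
  v <- if (is.null(v0)) numeric(ns) else v0
  q <- rep(1, ns * na)
  for (it in seq_len(max_iter)) {
    q[tried] <- r[tried] + gamma * as.vector(p_img %*% v)[tried]
    v_new <- apply(matrix(q, ns, na), 1L, max)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  out <- matrix(q, ns, na)
  attr(out, "v") <- v
  out
}

#' Model 2 action choice: greedy on the learned Markov model
#'
#' @param tp a `transition_posterior`.
#' @param state current 0-based state.
#' @param q optional precomputed value matrix from [plan_values()].
#' @return 0-based action (ties uniform at random).
#' @export
act_model2 <- function(tp, state, q = NULL) {
  if (is.null(q)) q <- plan_values(tp)
  argmax_tie(q[state + 1L, ]) - 1L
}

#' Model 3 action choice: Model 2 restricted to unvisited successors
#'
#' Actions whose maximum a posteriori successor has already been visited in
#' the current episode are excluded; if that excludes everything, the
#' restriction is dropped and Model 2's choice stands.
#'
#' @param tp a `transition_posterior`.
#' @param state current 0-based state.
#' @param visited integer vector of 0-based states visited this episode.
#' @param q optional precomputed value matrix.
#' @return 0-based action.
#' @export
act_model3 <- function(tp, state, visited, q = NULL) {
  if (is.null(q)) q <- plan_values(tp)
  na <- tp$n_actions
  allowed <- vapply(seq_len(na), function(a) {
    p <- tp_predictive(tp, state, a - 1L)
    if (is.null(p)) return(TRUE)  # unknown successor: cannot exclude
    (which.max(p) - 1L) %in% visited == FALSE
  }, logical(1L))
  if (!any(allowed)) allowed[] <- TRUE
  qa <- q[state + 1L, ]
  qa[!allowed] <- -Inf
  argmax_tie(qa) - 1L
}

# ---- agents for the task runner -------------------------------------------

#' Sequence-MAP Bayesian learner (Model 1)
#'
#' Plans a full action sequence at every episode start via [map_sequence()]
#' and executes it step by step; when the plan is exhausted before the
#' episode ends, it continues with uniformly random actions. Keys on the
#' action history only — it never looks at the observed images.
#'
#' @param n_actions size of the action alphabet.
#' @param n_trees trees per planning call.
#' @param depth_cap planner depth cap.
#' @return an agent object of class `bayes1_agent`.
#' @export
bayes1_agent <- function(n_actions, n_trees = 2000L, depth_cap = 12L) {
  structure(list(post = sequence_posterior(n_actions),
                 n_actions = as.integer(n_actions),
                 n_trees = as.integer(n_trees),
                 depth_cap = as.integer(depth_cap),
                 plan = integer(0), pos = 0L, history = integer(0)),
            class = "bayes1_agent")
}

#' @export
agent_begin_episode.bayes1_agent <- function(agent) {
  agent$plan <- map_sequence(agent$post, agent$n_trees, agent$depth_cap)
  agent$pos <- 0L
  agent$history <- integer(0)
  agent
}

#' @export
agent_act.bayes1_agent <- function(agent, obs) {
  agent$pos <- agent$pos + 1L
  action <- if (agent$pos <= length(agent$plan)) {
    agent$plan[agent$pos]
  } else {
    sample.int(agent$n_actions, 1L) - 1L
  }
  list(agent = agent, action = action)
}

#' @export
agent_observe_step.bayes1_agent <- function(agent, obs, action, next_state,
                                            reward, done) {
  agent$history <- c(agent$history, action)
  agent
}

#' @export
agent_episode_end.bayes1_agent <- function(agent, success, length) {
  agent$post <- update_sequence_posterior(agent$post, agent$history, success)
  agent
}

#' Markov model-based Bayesian learner (Models 2 and 3)
#'
#' Model 2 learns state-action transition dynamics under the Markov
#' assumption and acts greedily on the planned values. Model 3 additionally
#' avoids actions whose predicted successor was already visited in the
#' current episode.
#'
#' A deterministic greedy policy on a learned Markov model can livelock in
#' a gated environment: once every reachable pair has been tried, the greedy
#' cycle through the pre-goal state need not pass the switch state, and with
#' deterministic transitions nothing ever changes. A small exploration
#' probability `epsilon` (uniform random action) breaks such cycles; Model
#' 3's no-revisit rule provides additional within-episode coverage.
#'
#' @param n_states,n_actions environment dimensions.
#' @param avoid_revisits `TRUE` for Model 3.
#' @param gamma planner discount.
#' @param epsilon probability of a uniform random action per step.
#' @return an agent object of class `bayes_markov_agent`.
#' @export
bayes_markov_agent <- function(n_states, n_actions, avoid_revisits = FALSE,
                               gamma = 0.95, epsilon = 0.1) {
  structure(list(tp = transition_posterior(n_states, n_actions),
                 n_actions = as.integer(n_actions),
                 avoid_revisits = avoid_revisits, gamma = gamma,
                 epsilon = epsilon,
                 visited = integer(0), dirty = TRUE, q = NULL),
            class = "bayes_markov_agent")
}

#' @export
agent_begin_episode.bayes_markov_agent <- function(agent) {
  agent$visited <- integer(0)
  agent
}

#' @export
agent_act.bayes_markov_agent <- function(agent, obs) {
  agent$visited <- union(agent$visited, obs$state)
  if (agent$epsilon > 0 && stats::runif(1) < agent$epsilon) {
    return(list(agent = agent,
                action = sample.int(agent$n_actions, 1L) - 1L))
  }
  if (agent$dirty) {
    v0 <- if (is.null(agent$q)) NULL else attr(agent$q, "v")
    agent$q <- plan_values(agent$tp, agent$gamma, v0 = v0)
    agent$dirty <- FALSE
  }
  action <- if (agent$avoid_revisits) {
    act_model3(agent$tp, obs$state, agent$visited, agent$q)
  } else {
    act_model2(agent$tp, obs$state, agent$q)
  }
  list(agent = agent, action = action)
}

#' @export
agent_observe_step.bayes_markov_agent <- function(agent, obs, action,
                                                  next_state, reward, done) {
  # the posterior predictive only changes when the pair is new, this
  # successor is new for the pair, or the pair is stochastic-looking
  # (several observed successors whose ratio shifts with every count)
  cnt <- agent$tp$counts[obs$state + 1L, action + 1L, ]
  if (sum(cnt) == 0 || cnt[next_state + 1L] == 0 || sum(cnt > 0) > 1L) {
    agent$dirty <- TRUE
  }
  agent$tp <- tp_update(agent$tp, obs$state, action, next_state)
  agent
}

#' Run a Bayesian learner on the switch-state task over several seeds
#'
#' @param env a `switch_env`.
#' @param model 1, 2, or 3.
#' @param n_episodes episodes per run.
#' @param n_runs independent runs.
#' @param seed master seed.
#' @param max_steps truncation cap.
#' @param ... passed to the agent constructor.
#' @return list with `lengths` (runs x episodes) and `curve`.
#' @export
run_switch_bayes <- function(env, model, n_episodes = 50L, n_runs = 10L,
                             seed = 1L, max_steps = 100L, ...) {
  seeds <- derive_seeds(seed, n_runs)
  lengths <- matrix(NA_integer_, n_runs, n_episodes)
  for (r in seq_len(n_runs)) {
    agent <- switch(as.character(model),
      "1" = bayes1_agent(env$n_actions, ...),
      "2" = bayes_markov_agent(env$n_states, env$n_actions,
                               avoid_revisits = FALSE, ...),
      "3" = bayes_markov_agent(env$n_states, env$n_actions,
                               avoid_revisits = TRUE, ...),
      stop("model must be 1, 2, or 3"))
    run <- run_switch_agent(env, agent, n_episodes, max_steps,
                            seed = seeds[r])
    lengths[r, ] <- run$lengths
  }
  list(lengths = lengths, curve = average_curves(lengths))
}
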