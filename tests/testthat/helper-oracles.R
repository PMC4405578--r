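# Independent oracles used by the tests. These deliberately re-derive
# quantities with different algorithms than the package implementations.

# --- exact expected tree-counter enumeration -------------------------------
# Expected per-tree counter increment for every sequence up to depth_cap,
# computed by dynamic programming over active node sets: a node's credit
# probability at its depth is P(reach that depth with the node active) *
# P(terminal & rewarded); conditioned on "no rewarded terminal at this
# depth", active nodes continue independently.
oracle_expected_counters <- function(post, depth_cap = 3L) {
  n_actions <- post$n_actions
  probs_of <- function(key) {
    nd <- post$nodes[[key]]
    ac <- post$prior_c
    ar <- post$prior_r
    if (is.null(nd)) nd <- c(cont = 0, term = 0, rew = 0, norew = 0)
    pc <- (ac[1] + nd[["cont"]]) / (sum(ac) + nd[["cont"]] + nd[["term"]])
    pr <- (ar[1] + nd[["rew"]]) / (sum(ar) + nd[["rew"]] + nd[["norew"]])
    if (post$deterministic) {
      if (nd[["cont"]] > 0) pc <- 1
      if (nd[["term"]] > 0) {
        pc <- 0
        pr <- as.numeric(nd[["rew"]] > 0)
      }
    }
    c(pc = pc, pr = pr)
  }
  counters <- new.env()
  add <- function(key, val) {
    cur <- if (is.null(counters[[key]])) 0 else counters[[key]]
    counters[[key]] <- cur + unname(val)
  }
  recurse <- function(active, depth, reach_prob) {
    if (!length(active) || depth > depth_cap || reach_prob <= 0) return()
    pp <- vapply(active, probs_of, numeric(2L))
    t_i <- (1 - pp["pc", ]) * pp["pr", ]      # terminal & rewarded
    u_i <- (1 - pp["pc", ]) * (1 - pp["pr", ])  # terminal & unrewarded
    c_i <- pp["pc", ]
    for (i in seq_along(active)) add(active[i], reach_prob * t_i[i])
    p_nostop <- prod(1 - t_i)
    if (p_nostop <= 0 || depth == depth_cap) return()
    cc <- c_i / (1 - t_i)   # P(continue | not rewarded-terminal)
    k <- length(active)
    for (mask in 0:(2^k - 1L)) {
      inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      p_subset <- prod(ifelse(inset, cc, 1 - cc))
      if (p_subset <= 0) next
      kids <- unlist(lapply(active[inset], function(key) {
        paste(key, 0:(n_actions - 1L), sep = ".")
      }))
      recurse(kids, depth + 1L, reach_prob * p_nostop * p_subset)
    }
  }
  recurse(as.character(0:(n_actions - 1L)), 1L, 1)
  out <- unlist(as.list(counters))
  if (is.null(out)) numeric(0) else out
}

# random (general-mode) sequence posterior over 2 actions, depth <= 3
random_seq_posterior <- function() {
  post <- sequence_posterior(2L, deterministic = FALSE)
  keys <- unlist(lapply(1:3, function(d) {
    apply(expand.grid(rep(list(0:1), d)), 1L, paste, collapse = ".")
  }))
  for (k in sample(keys, sample(3:8, 1L))) {
    post$nodes[[k]] <- c(cont = stats::rpois(1, 2), term = stats::rpois(1, 2),
                         rew = stats::rpois(1, 1), norew = stats::rpois(1, 1))
  }
  post
}

# --- plain leaky Beta-Bernoulli category learner ---------------------------
# The reduction target for the delay-Bayes learner in immediate mode: same
# greedy decisions and leaky evidence counting, but no attribution or delay
# machinery at all.
plain_bb_agent <- function(n_images,
                           forget = formals(delay_bayes_agent)$forget) {
  structure(list(belief = matrix(0, n_images, 2L), forget = forget,
                 last = NULL),
            class = "plain_bb_agent")
}

agent_act.plain_bb_agent <- function(agent, obs) {
  b <- agent$belief[obs$stimulus + 1L, ]
  p_left <- (b[1L] + 1) / (sum(b) + 2)
  action <- if (p_left > 0.5) {
    "left"
  } else if (p_left < 0.5) {
    "right"
  } else {
    sample(c("left", "right"), 1L)
  }
  agent$last <- list(image = obs$stimulus + 1L, action = action)
  list(agent = agent, action = action)
}

agent_feedback.plain_bb_agent <- function(agent, event) {
  img <- agent$last$image
  act <- agent$last$action
  side <- if (event$reward > 0) act else if (act == "left") "right" else "left"
  col <- if (side == "left") 1L else 2L
  agent$belief[img, ] <- agent$belief[img, ] * agent$forget
  agent$belief[img, col] <- agent$belief[img, col] + 1
  agent
}

registerS3method("agent_act", "plain_bb_agent", agent_act.plain_bb_agent,
                 envir = asNamespace("nonmarkov"))
registerS3method("agent_feedback", "plain_bb_agent",
                 agent_feedback.plain_bb_agent,
                 envir = asNamespace("nonmarkov"))

# --- direct-formula gamma density ------------------------------------------
oracle_gamma_pdf <- function(t, k, theta) {
  stats::dgamma(t, shape = k, scale = theta)
}

# small utility: mean episode length of a uniform random agent by simulation
simulate_random_walk_lengths <- function(env, n_episodes, max_steps = 10000L) {
  vapply(seq_len(n_episodes), function(i) {
    es <- new_episode(env)
    repeat {
      st <- env_step(env, es, sample.int(env$n_actions, 1L) - 1L)
      es <- st$state
      if (st$done || es$step_count >= max_steps) break
    }
    es$step_count
  }, numeric(1L))
}
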