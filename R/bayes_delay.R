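#' Dirichlet-process learner for intermixed feedback
#'
#' The learner does not know which response a delayed feedback event belongs
#' to. It therefore puts a Dirichlet-process prior over the unknown
#' feedback-delay distribution — realized computably as a finite Dirichlet
#' on a grid of delay bins — and updates the posterior whenever new data are
#' observed. Each incoming feedback event is softly attributed to recent
#' responses with responsibilities proportional to the posterior-predictive
#' delay density at the respective lags (decision making marginalizes over
#' delay distributions: the predictive is the posterior mean of the
#' Dirichlet, which is exact and deterministic). The same responsibilities
#' weight the evidence carried to each image's category belief, a Beta
#' posterior over "left is correct".
#'
#' Category beliefs use leaky evidence counts (exponential forgetting with
#' factor `forget` per observation of an image) so the learner can track
#' reversals, as in the switching control experiment where half of the
#' images swap their correct category.
#'
#' @param n_images number of images in the task set.
#' @param alpha DP concentration; `alpha -> Inf` pins the posterior to the
#'   base measure, `alpha -> 0` to the empirical lags.
#' @param grid_max largest representable delay in seconds.
#' @param bin_width delay-bin width in seconds.
#' @param buffer number of most recent responses over which a feedback
#'   event can be attributed (gamma(2, 1.5) mass beyond 10 inter-trial
#'   intervals is negligible).
#' @param forget per-observation forgetting factor in (0, 1] for the
#'   category evidence (1 = no forgetting, exact Beta-Bernoulli counting).
#' @return an agent object of class `delay_bayes_agent`.
#' @export
delay_bayes_agent <- function(n_images, alpha = 1, grid_max = 15,
                              bin_width = 0.25, buffer = 10L, forget = 0.7) {
  n_bins <- as.integer(round(grid_max / bin_width))
  structure(list(n_images = as.integer(n_images),
                 alpha = alpha, bin_width = bin_width, n_bins = n_bins,
                 bin_mid = (seq_len(n_bins) - 0.5) * bin_width,
                 base = rep(1 / n_bins, n_bins),
                 counts = rep(0, n_bins),
                 buffer = as.integer(buffer), forget = forget,
                 # per image: leaky evidence that left (col 1) / right
                 # (col 2) is the correct category
                 belief = matrix(0, n_images, 2L),
                 responses = data.frame(time = numeric(0),
                                        image = integer(0),
                                        action = character(0),
                                        attributed = numeric(0)),
                 pending = 0L),
            class = "delay_bayes_agent")
}

#' Posterior over the delay distribution (bin masses)
#'
#' Mean of the finite Dirichlet: `(alpha * base + counts) / (alpha + n)`.
#'
#' @param agent a `delay_bayes_agent`.
#' @return numeric vector of bin masses summing to 1.
#' @export
delay_posterior_mass <- function(agent) {
  m <- agent$alpha * agent$base + agent$counts
  m / sum(m)
}

#' Posterior mean delay
#'
#' @param agent a `delay_bayes_agent`.
#' @return expected delay in seconds under the posterior-predictive.
#' @export
delay_posterior_mean <- function(agent) {
  sum(delay_posterior_mass(agent) * agent$bin_mid)
}

delay_bin <- function(agent, lag) {
  pmin(pmax(floor(lag / agent$bin_width) + 1L, 1L), agent$n_bins)
}

#' Responsibility weights of past responses for a feedback event
#'
#' Candidate responses are the most recent `buffer` responses that are not
#' yet fully attributed and have non-negative lag. Each candidate's weight
#' is proportional to the posterior-predictive delay density at its lag;
#' weights are normalized to sum to one. With no candidate, the event is
#' held pending (counted in `agent$pending`).
#'
#' @param agent a `delay_bayes_agent`.
#' @param event feedback event `list(time, reward)`.
#' @return list with `idx` (row indices into `agent$responses`, possibly
#'   empty) and `w` (normalized weights).
#' @export
responsibility_weights <- function(agent, event) {
  rs <- agent$responses
  cand <- which(rs$attributed < 1 & event$time - rs$time >= 0)
  cand <- utils::tail(cand, agent$buffer)
  if (!length(cand)) return(list(idx = integer(0), w = numeric(0)))
  mass <- delay_posterior_mass(agent)
  dens <- mass[delay_bin(agent, event$time - rs$time[cand])]
  if (sum(dens) <= 0) dens <- rep(1, length(cand))
  list(idx = cand, w = dens / sum(dens))
}

#' Update the delay posterior with softly attributed lags
#'
#' Adds each candidate's weight as a fractional count to the bin of its
#' lag.
#'
#' @param agent a `delay_bayes_agent`.
#' @param lags numeric lags in seconds.
#' @param w weights (same length, summing to at most 1 per event).
#' @return the updated agent.
#' @export
update_delay_posterior <- function(agent, lags, w) {
  stopifnot(length(lags) == length(w))
  for (i in seq_along(lags)) {
    b <- delay_bin(agent, lags[i])
    agent$counts[b] <- agent$counts[b] + w[i]
  }
  agent
}

#' Update category beliefs with weighted feedback evidence
#'
#' For each candidate response `i` with weight `w[i]`, the belief of the
#' image responded to is moved by fractional evidence `w[i]` toward "the
#' chosen action was correct" (positive reward) or "was incorrect"
#' (negative reward). Both evidence columns of that image first leak by
#' `forget^w[i]`, so equal and opposite fractional evidence leaves a
#' symmetric belief unchanged.
#'
#' @param agent a `delay_bayes_agent`.
#' @param event feedback event `list(time, reward)`.
#' @param resp list from [responsibility_weights()].
#' @return the updated agent.
#' @export
update_category_belief <- function(agent, event, resp) {
  for (j in seq_along(resp$idx)) {
    i <- resp$idx[j]
    w <- resp$w[j]
    if (w <= 0) next
    img <- agent$responses$image[i] + 1L
    act <- agent$responses$action[i]
    correct_side <- if (event$reward > 0) act else {
      if (act == "left") "right" else "left"
    }
    col <- if (correct_side == "left") 1L else 2L
    agent$belief[img, ] <- agent$belief[img, ] * agent$forget^w
    agent$belief[img, col] <- agent$belief[img, col] + w
  }
  agent
}

#' Greedy category choice
#'
#' Argmax of the Beta posterior mean `(a + 1) / (a + b + 2)` for "left";
#' exact ties are broken uniformly at random (the only use of randomness).
#'
#' @param agent a `delay_bayes_agent`.
#' @param image 0-based image id.
#' @return "left" or "right".
#' @export
act_delay_bayes <- function(agent, image) {
  b <- agent$belief[image + 1L, ]
  p_left <- (b[1L] + 1) / (sum(b) + 2)
  if (p_left > 0.5) {
    "left"
  } else if (p_left < 0.5) {
    "right"
  } else {
    sample(c("left", "right"), 1L)
  }
}

#' @export
agent_act.delay_bayes_agent <- function(agent, obs) {
  action <- act_delay_bayes(agent, obs$stimulus)
  agent$responses <- rbind(agent$responses,
                           data.frame(time = obs$time,
                                      image = as.integer(obs$stimulus),
                                      action = action, attributed = 0))
  list(agent = agent, action = action)
}

#' @export
agent_feedback.delay_bayes_agent <- function(agent, event) {
  resp <- responsibility_weights(agent, event)
  if (!length(resp$idx)) {
    agent$pending <- agent$pending + 1L
    return(agent)
  }
  lags <- event$time - agent$responses$time[resp$idx]
  agent <- update_delay_posterior(agent, lags, resp$w)
  agent <- update_category_belief(agent, event, resp)
  agent$responses$attributed[resp$idx] <-
    agent$responses$attributed[resp$idx] + resp$w
  agent
}

#' Run the delay-Bayes learner on a classification session
#'
#' @param env a `feedback_env`.
#' @param n_trials trials in the session.
#' @param seed session seed.
#' @param agent optionally a pre-trained agent to continue from.
#' @param ... passed to [delay_bayes_agent()] when `agent` is NULL.
#' @return list with `correct` (logical per trial), `log`, and `agent`.
#' @export
run_delay_bayes <- function(env, n_trials = 400L, seed = 1L, agent = NULL,
                            ...) {
  if (is.null(agent)) agent <- delay_bayes_agent(env$n_images, ...)
  out <- run_feedback_session(env, agent, n_trials, seed = seed)
  list(correct = log_correctness(out$log, env), log = out$log,
       agent = out$agent)
}
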