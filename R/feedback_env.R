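#' Delayed, intermixed feedback environment
#'
#' Image classification with two categories ("left"/"right"). In `immediate`
#' mode every feedback event is delivered before the next stimulus. In
#' `gamma` mode the delivery time of each feedback is the response time plus
#' a gamma-distributed delay (shape `k = 2`, scale `theta = 1.5` s by
#' default), so feedback for one response can arrive after feedback for a
#' later response — the unique response-to-feedback mapping is broken.
#'
#' @param n_images number of images (4 for training parts, 10 for the main
#'   experiment and its controls).
#' @param category_map optional character vector of length `n_images` with
#'   entries "left"/"right"; randomly assigned under `seed` when `NULL`.
#' @param delay_mode `"immediate"` or `"gamma"`.
#' @param shape,scale gamma delay parameters (k, theta seconds).
#' @param iti inter-trial interval in seconds (stimulus-onset asynchrony).
#' @param seed integer seed used for the random category assignment.
#' @return an object of class `feedback_env`.
#' @export
feedback_env <- function(n_images = 10L, category_map = NULL,
                         delay_mode = c("gamma", "immediate"),
                         shape = 2, scale = 1.5, iti = 1.5, seed = 1L) {
  delay_mode <- match.arg(delay_mode)
  n_images <- as.integer(n_images)
  stopifnot(n_images >= 2L, shape > 0, scale > 0, iti > 0)
  if (is.null(category_map)) {
    category_map <- with_seed(seed, sample(c("left", "right"), n_images,
                                           replace = TRUE))
  }
  stopifnot(length(category_map) == n_images,
            all(category_map %in% c("left", "right")))
  structure(list(n_images = n_images, category_map = category_map,
                 delay_mode = delay_mode, shape = shape, scale = scale,
                 iti = iti, seed = seed),
            class = "feedback_env")
}

#' Swap the rewarded category for selected images
#'
#' Used by the switching (reversal) control experiment, where half of the
#' images exchange their left/right assignment.
#'
#' @param env a `feedback_env`.
#' @param images 0-based image ids to swap (default: the first half).
#' @return the modified environment.
#' @export
swap_categories <- function(env, images = seq_len(env$n_images %/% 2) - 1L) {
  i <- images + 1L
  env$category_map[i] <- ifelse(env$category_map[i] == "left",
                                "right", "left")
  env
}

#' Gamma probability density of the feedback delay
#'
#' \eqn{p(t | \theta, k) = t^{k-1} \exp(-t/\theta) / (\Gamma(k)\,\theta^k)},
#' the density used to delay feedback in the intermixed-feedback task.
#'
#' @param t delay in seconds (>= 0; vectorized).
#' @param k shape parameter (dimensionless; width).
#' @param theta scale parameter in seconds (peak location `(k-1)*theta`).
#' @return density per second.
#' @export
gamma_pdf <- function(t, k = 2, theta = 1.5) {
  stopifnot(k > 0, theta > 0)
  if (any(t < 0)) stop("delay t must be non-negative")
  t^(k - 1) * exp(-t / theta) / (gamma(k) * theta^k)
}

#' Sample feedback delays
#'
#' @param env a `feedback_env` in gamma mode.
#' @param n number of i.i.d. draws.
#' @return numeric vector of delays in seconds (draws from the ambient RNG).
#' @export
sample_delay <- function(env, n = 1L) {
  if (env$delay_mode != "gamma") {
    stop("sample_delay applies only to gamma delay mode")
  }
  stats::rgamma(n, shape = env$shape, scale = env$scale)
}

#' Run one classification session
#'
#' Presents images in uniformly random order (each image equally often up to
#' rounding), collects the agent's responses, enqueues one feedback event per
#' response (+1 correct / -1 incorrect) at `response time + delay`, delivers
#' all due feedback to the agent in due-time order at each trial onset, and
#' drains the queue after the last trial.
#'
#' @param env a `feedback_env`.
#' @param agent an agent implementing `agent_act` / `agent_feedback`.
#' @param n_trials number of stimulus presentations (>= 1).
#' @param seed optional integer; seeds a private RNG stream for the session.
#' @return list with `log` (a `trial_log` data frame: one row per event with
#'   columns event_type, trial, time, stimulus, action, reward, origin — the
#'   origin column identifies the response that generated each feedback and
#'   exists for oracle tests only) and `agent` (final state).
#' @export
run_feedback_session <- function(env, agent, n_trials, seed = NULL) {
  stopifnot(n_trials >= 1L)
  body <- function() {
    agent <- agent  # local binding so deliver_due()'s `<<-` stays in scope
    m <- env$n_images
    order_pool <- rep(0:(m - 1L), length.out = m * ceiling(n_trials / m))
    stimuli <- sample(order_pool)[seq_len(n_trials)]
    pending <- data.frame(due = numeric(0), reward = numeric(0),
                          origin = integer(0))
    rows <- vector("list", 2L * n_trials)
    nrow_i <- 0L
    push <- function(row) {
      nrow_i <<- nrow_i + 1L
      rows[[nrow_i]] <<- row
    }
    deliver_due <- function(now) {
      repeat {
        if (!nrow(pending)) break
        j <- which.min(pending$due)
        if (is.finite(now) && pending$due[j] > now) break
        ev <- pending[j, ]
        pending <<- pending[-j, , drop = FALSE]
        agent <<- agent_feedback(agent, list(time = ev$due,
                                             reward = ev$reward))
        push(data.frame(event_type = "feedback", trial = NA_integer_,
                        time = ev$due, stimulus = NA_integer_,
                        action = NA_character_, reward = ev$reward,
                        origin = ev$origin))
      }
    }
    for (j in seq_len(n_trials)) {
      now <- (j - 1L) * env$iti
      deliver_due(now)
      stim <- stimuli[j]
      act <- agent_act(agent, list(stimulus = stim, time = now))
      agent <- act$agent
      if (!act$action %in% c("left", "right")) {
        stop("agent returned an invalid category: ", act$action)
      }
      correct <- act$action == env$category_map[stim + 1L]
      delay <- if (env$delay_mode == "gamma") sample_delay(env, 1L) else 0
      pending <- rbind(pending,
                       data.frame(due = now + delay,
                                  reward = if (correct) 1 else -1,
                                  origin = j - 1L))
      push(data.frame(event_type = "response", trial = j - 1L, time = now,
                      stimulus = stim, action = act$action,
                      reward = NA_real_, origin = NA_integer_))
    }
    deliver_due(Inf)
    log <- do.call(rbind, rows[seq_len(nrow_i)])
    rownames(log) <- NULL
    class(log) <- c("trial_log", "data.frame")
    list(log = log, agent = agent)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Per-trial correctness from a trial log
#'
#' @param log a `trial_log`.
#' @param env the `feedback_env` the log came from.
#' @return logical vector, one entry per response in trial order.
#' @export
log_correctness <- function(log, env) {
  resp <- log[log$event_type == "response", ]
  resp <- resp[order(resp$trial), ]
  resp$action == env$category_map[resp$stimulus + 1L]
}

#' Write a trial log as tidy CSV
#'
#' @param log a `trial_log`.
#' @param path output file.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
}

#' An oracle agent that knows the category map
#'
#' Always answers correctly; used to validate session plumbing.
#'
#' @param env a `feedback_env`.
#' @return an agent object.
#' @export
oracle_agent <- function(env) {
  structure(list(map = env$category_map), class = "oracle_agent")
}

#' @export
agent_act.oracle_agent <- function(agent, obs) {
  list(agent = agent, action = agent$map[obs$stimulus + 1L])
}
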