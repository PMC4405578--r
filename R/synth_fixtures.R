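#' Surrogate human learning curves
#'
#' The study's per-participant traces are not published, so the evaluation
#' layer is exercised against synthetic surrogate curves with the
#' qualitative shapes of the human data: episode lengths that decay
#' exponentially toward the environment minimum (navigation task, learned in
#' under 50 episodes) and proportion correct that rises from chance 0.5
#' toward an asymptote (classification task). These are test scaffolding,
#' not claims about the human data.
#'
#' @param task `"switch"` or `"feedback"`.
#' @param n_points episodes (switch) or trials (feedback).
#' @param n_subjects number of surrogate subjects (defaults: 10 navigation,
#'   14 classification — the study's sample sizes).
#' @param l0,l_min,tau_learn switch family: `L(e) = l_min + (l0 - l_min) *
#'   exp(-e / tau_learn)`.
#' @param p_inf feedback family asymptote: `P(t) = 0.5 + (p_inf - 0.5) *
#'   (1 - exp(-t / tau_learn))`.
#' @param noise_sd Gaussian per-point noise SD for the switch family.
#' @param window binomial trial count per point for the feedback family
#'   (emulating a `window`-trial average of Bernoulli outcomes).
#' @param seed integer seed.
#' @return list with `subjects` (n_subjects x n_points matrix), `mean` (a
#'   `learning_curve` with SEM), and `spec` (the generating parameters).
#' @export
generate_surrogate_curves <- function(task = c("switch", "feedback"),
                                      n_points = if (task == "switch") 50L else 400L,
                                      n_subjects = if (task == "switch") 10L else 14L,
                                      l0 = 40, l_min = 5, tau_learn = if (task == "switch") 10 else 100,
                                      p_inf = 0.9, noise_sd = 5,
                                      window = 10L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_points >= 1L, n_subjects >= 1L)
  if (task == "switch" && l0 < l_min) stop("l0 must be >= l_min")
  if (task == "feedback" && (p_inf < 0.5 || p_inf > 1)) {
    stop("p_inf must lie in [0.5, 1]")
  }
  with_seed(seed, {
    t <- seq_len(n_points)
    if (task == "switch") {
      f <- l_min + (l0 - l_min) * exp(-t / tau_learn)
      subjects <- t(vapply(seq_len(n_subjects), function(i) {
        pmax(f + stats::rnorm(n_points, 0, noise_sd), l_min)
      }, numeric(n_points)))
    } else {
      f <- 0.5 + (p_inf - 0.5) * (1 - exp(-t / tau_learn))
      subjects <- t(vapply(seq_len(n_subjects), function(i) {
        stats::rbinom(n_points, window, f) / window
      }, numeric(n_points)))
    }
    list(subjects = subjects, mean = average_curves(subjects, x = t),
         spec = list(task = task, n_points = n_points,
                     n_subjects = n_subjects, l0 = l0, l_min = l_min,
                     tau_learn = tau_learn, p_inf = p_inf,
                     noise_sd = noise_sd, window = window, seed = seed))
  })
}

#' Miniature fixture environments with precomputed oracle answers
#'
#' Hand-specified environments small enough for exhaustive oracles:
#'
#' * `"gated-chain-3"`: 3 image states, 2 actions; the switch state is also
#'   the pre-goal state, and the shortest successful episode is 2 actions.
#' * `"gated-detour-3"`: 3 image states, 2 actions; the switch state lies
#'   off the direct route, so the shortest path is 2 actions ignoring the
#'   gate but 3 actions with it — the minimal environment in which gating
#'   actually binds.
#' * `"two-image-immediate"`: a 2-image immediate-feedback classification
#'   task with a fixed category map.
#'
#' Each fixture carries an `oracle` list computed by the independent
#' brute-force oracles ([oracle_shortest_path()], [oracle_absorption_time()])
#' at construction time.
#'
#' @param name fixture identifier.
#' @return the fixture environment with an `oracle` attribute.
#' @export
make_fixture <- function(name) {
  known <- c("gated-chain-3", "gated-detour-3", "two-image-immediate")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  if (name == "two-image-immediate") {
    env <- feedback_env(2L, category_map = c("left", "right"),
                        delay_mode = "immediate")
    attr(env, "oracle") <- list(oracle_proportion_correct = 1.0)
    return(env)
  }
  if (name == "gated-chain-3") {
    # 0 -> 1 (switch = pre-goal) -> goal; action 1 wanders
    trans <- matrix(c(1L, 0L,   # state 0: a0 -> 1, a1 -> 0
                      2L, 0L,   # state 1: a0 -> (goal action), a1 -> 0
                      1L, 2L),  # state 2: a0 -> 1, a1 -> 2 (recurrent)
                    nrow = 3L, byrow = TRUE)
    env <- structure(list(n_states = 3L, n_actions = 2L, start = 0L,
                          goal = 3L, switch_state = 1L, pre_goal_state = 1L,
                          goal_action = 0L, decoy_state = 2L,
                          transitions = trans, seed = NA_integer_),
                     class = "switch_env")
    env$transitions[env$pre_goal_state + 1L, env$goal_action + 1L] <-
      env$decoy_state
  } else {
    # direct route 0 -> 2 -> goal is blocked until the detour through the
    # switch state 1 has been taken: gating adds exactly one action
    trans <- matrix(c(2L, 1L,   # state 0: a0 -> 2 (direct), a1 -> 1 (switch)
                      2L, 1L,   # state 1: a0 -> 2, a1 -> 1 (recurrent)
                      0L, 0L),  # state 2: a0 = goal action, a1 -> 0
                    nrow = 3L, byrow = TRUE)
    env <- structure(list(n_states = 3L, n_actions = 2L, start = 0L,
                          goal = 3L, switch_state = 1L, pre_goal_state = 2L,
                          goal_action = 0L, decoy_state = 0L,
                          transitions = trans, seed = NA_integer_),
                     class = "switch_env")
  }
  attr(env, "oracle") <- list(
    shortest_gated = oracle_shortest_path(env, gated = TRUE),
    shortest_ungated = oracle_shortest_path(env, gated = FALSE),
    absorption_time = oracle_absorption_time(env))
  env
}

#' Exhaustive shortest-path oracle
#'
#' Enumerates all action sequences in order of length (up to `max_len`) and
#' simulates each with [env_step()]; independent of the breadth-first
#' search in [shortest_episode_length()].
#'
#' @param env a `switch_env`.
#' @param gated if `FALSE` the switch gate is ignored (the goal action
#'   succeeds from the pre-goal state regardless of history).
#' @param max_len longest sequence length to enumerate.
#' @return shortest successful sequence length, or `Inf`.
#' @export
oracle_shortest_path <- function(env, gated = TRUE, max_len = 8L) {
  na <- env$n_actions
  for (len in seq_len(max_len)) {
    grid <- as.matrix(expand.grid(rep(list(0:(na - 1L)), len)))
    for (r in seq_len(nrow(grid))) {
      es <- new_episode(env)
      if (!gated) es$switch_visited <- TRUE
      ok <- FALSE
      for (a in grid[r, ]) {
        st <- env_step(env, es, a)
        es <- st$state
        if (st$done) {
          ok <- TRUE
          break
        }
      }
      if (ok && es$step_count == len) return(len)
    }
  }
  Inf
}

#' Mean episode length of the uniform random policy
#'
#' Expected absorption time of the random walk on the (state,
#' switch-visited) product chain, by linear solve of
#' `(I - P) h = 1` — the independent oracle for untrained-agent episode
#' lengths (no truncation cap).
#'
#' @param env a `switch_env`.
#' @return expected number of actions from the start to the goal.
#' @export
oracle_absorption_time <- function(env) {
  n <- env$n_states
  na <- env$n_actions
  nn <- 2L * n  # transient product states; goal absorbing
  p <- matrix(0, nn, nn)
  idx <- function(s, f) s + n * f + 1L
  for (s in 0:(n - 1L)) {
    for (f in 0:1) {
      for (a in 0:(na - 1L)) {
        if (s == env$pre_goal_state && a == env$goal_action && f == 1L) {
          next  # absorbed at goal
        }
        s2 <- env$transitions[s + 1L, a + 1L]
        f2 <- as.integer(f == 1L || s2 == env$switch_state)
        p[idx(s, f), idx(s2, f2)] <- p[idx(s, f), idx(s2, f2)] + 1 / na
      }
    }
  }
  start <- idx(env$start, as.integer(env$start == env$switch_state))
  reach <- reachable_from(p, start)
  h <- solve(diag(sum(reach)) - p[reach, reach, drop = FALSE],
             rep(1, sum(reach)))
  h[match(start, which(reach))]
}

reachable_from <- function(p, start) {
  reach <- logical(nrow(p))
  reach[start] <- TRUE
  repeat {
    new <- reach | (colSums(p[reach, , drop = FALSE]) > 0)
    if (all(new == reach)) break
    reach <- new
  }
  reach
}

#' Run every learner on both tasks and build the full comparison report
#'
#' The end-to-end analogue of the study's figures and tables: runs the five
#' navigation learners (spiking population, Bayes models 1-3, policy
#' gradient) against a surrogate-human episode-length curve, and the three
#' classification learners (spiking population, delay-Bayes, policy
#' gradient) against a surrogate proportion-correct curve, then ranks each
#' set by AICc.
#'
#' @param config list of options; recognized fields (with defaults):
#'   `env_seed` (0), `n_episodes` (50), `n_trials` (200), `n_runs` (4),
#'   `seed` (1), `window` (10), `models_switch`, `models_feedback`
#'   (character subsets of the model names above), `surrogate_switch`,
#'   `surrogate_feedback` (parameter lists passed to
#'   [generate_surrogate_curves()]).
#' @param out optional directory; when given, curves and tables are written
#'   there as CSV.
#' @return list with `table_switch`, `table_feedback` (ranked model-fit data
#'   frames), `curves` (all learning curves), and `config` (the resolved
#'   configuration).
#' @export
end_to_end_replica <- function(config = list(), out = NULL) {
  cfg <- utils::modifyList(list(
    env_seed = 0L, n_episodes = 50L, n_trials = 200L, n_runs = 4L,
    seed = 1L, window = 10L,
    models_switch = c("spiking", "bayes1", "bayes2", "bayes3", "pg"),
    models_feedback = c("spiking", "delay_bayes", "pg"),
    surrogate_switch = list(), surrogate_feedback = list()), config)
  k_values <- c(spiking = 1L, bayes1 = 0L, bayes2 = 0L, bayes3 = 0L,
                pg = 1L, delay_bayes = 0L)
  env <- build_switch_env(cfg$env_seed)
  seeds <- derive_seeds(cfg$seed, 2L)

  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop("replica stage [", tag, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- navigation task -----------------------------------------------------
  sur_sw <- stage("surrogate-switch", do.call(generate_surrogate_curves,
    utils::modifyList(list(task = "switch", n_points = cfg$n_episodes,
                           seed = seeds[1L]), cfg$surrogate_switch)))
  curves_sw <- list()
  for (m in cfg$models_switch) {
    curves_sw[[m]] <- stage(paste0("switch-", m), switch(m,
      spiking = run_switch_task(env, cfg$n_episodes, cfg$n_runs,
                                seed = seeds[1L])$curve,
      bayes1 = run_switch_bayes(env, 1, cfg$n_episodes, cfg$n_runs,
                                seed = seeds[1L])$curve,
      bayes2 = run_switch_bayes(env, 2, cfg$n_episodes, cfg$n_runs,
                                seed = seeds[1L])$curve,
      bayes3 = run_switch_bayes(env, 3, cfg$n_episodes, cfg$n_runs,
                                seed = seeds[1L])$curve,
      pg = run_switch_pg(env, n_episodes = cfg$n_episodes,
                         n_runs = cfg$n_runs, seed = seeds[1L])$curve,
      stop("unknown switch model: ", m)))
  }
  table_switch <- stage("compare-switch",
    compare_models(sur_sw$mean, curves_sw, k_values[cfg$models_switch]))

  # --- classification task -------------------------------------------------
  sur_fb <- stage("surrogate-feedback", do.call(generate_surrogate_curves,
    utils::modifyList(list(task = "feedback", n_points = cfg$n_trials,
                           seed = seeds[2L]), cfg$surrogate_feedback)))
  fb_env <- feedback_env(10L, delay_mode = "gamma", seed = cfg$env_seed)
  run_seeds <- derive_seeds(seeds[2L], cfg$n_runs)
  fb_curve <- function(runner) {
    ys <- lapply(run_seeds, function(s) {
      sliding_proportion_correct(runner(s), window = cfg$window)$y
    })
    average_curves(ys)
  }
  curves_fb <- list()
  for (m in cfg$models_feedback) {
    curves_fb[[m]] <- stage(paste0("feedback-", m), switch(m,
      spiking = fb_curve(function(s) {
        run_feedback_task(fb_env, cfg$n_trials, seed = s)$correct
      }),
      delay_bayes = fb_curve(function(s) {
        run_delay_bayes(fb_env, cfg$n_trials, seed = s)$correct
      }),
      pg = fb_curve(function(s) {
        run_feedback_pg(fb_env, n_trials = cfg$n_trials, seed = s)$correct
      }),
      stop("unknown feedback model: ", m)))
  }
  # surrogate curve is per trial; compare on the sliding-window support
  sur_fb_win <- learning_curve(curves_fb[[1L]]$x,
                               sur_fb$mean$y[curves_fb[[1L]]$x])
  table_feedback <- stage("compare-feedback",
    compare_models(sur_fb_win, curves_fb, k_values[cfg$models_feedback]))

  result <- list(table_switch = table_switch,
                 table_feedback = table_feedback,
                 curves = list(switch = curves_sw, feedback = curves_fb,
                               surrogate_switch = sur_sw$mean,
                               surrogate_feedback = sur_fb$mean),
                 config = cfg)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table_switch, file.path(out, "table_switch.csv"),
                     row.names = FALSE)
    utils::write.csv(table_feedback, file.path(out, "table_feedback.csv"),
                     row.names = FALSE)
    for (m in names(curves_sw)) {
      write_curve(curves_sw[[m]], file.path(out, paste0("switch_", m, ".csv")))
    }
    for (m in names(curves_fb)) {
      write_curve(curves_fb[[m]], file.path(out, paste0("feedback_", m, ".csv")))
    }
  }
  result
}
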