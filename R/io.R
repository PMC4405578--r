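#' Serialize environments and posteriors to JSON
#'
#' Environment specifications and learner snapshots are plain JSON so that
#' sessions are resumable and configurations shareable.
#'
#' @param env a `switch_env` or `feedback_env`.
#' @param path output file.
#' @export
write_env_json <- function(env, path) {
  spec <- unclass(env)
  spec$.class <- class(env)[1L]
  if (!is.null(spec$transitions)) {
    spec$transitions <- as.data.frame(spec$transitions)
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_env_json
#' @param path JSON file written by [write_env_json()].
#' @return the restored environment object.
#' @export
read_env_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- spec$.class
  spec$.class <- NULL
  if (!is.null(spec$transitions)) {
    spec$transitions <- unname(as.matrix(spec$transitions))
  }
  for (f in c("n_states", "n_actions", "start", "goal", "switch_state",
              "pre_goal_state", "goal_action", "decoy_state", "n_images")) {
    if (!is.null(spec[[f]])) spec[[f]] <- as.integer(spec[[f]])
  }
  structure(spec, class = cls)
}

#' Snapshot a delay-Bayes learner's posteriors to JSON
#'
#' Saves the delay-bin posterior masses and the per-image category beliefs
#' (not the raw response history).
#'
#' @param agent a `delay_bayes_agent`.
#' @param path output file.
#' @export
write_delay_snapshot <- function(agent, path) {
  jsonlite::write_json(list(
    delay_mass = delay_posterior_mass(agent),
    bin_mid = agent$bin_mid,
    belief = as.data.frame(agent$belief)), path,
    auto_unbox = TRUE, digits = NA)
}
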