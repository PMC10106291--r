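#' Multi-goal pursuit environment
#'
#' Two actions can each lead to a reward state and/or a punishment state;
#' the four transition probabilities P(state | action) drift independently
#' by bounded Gaussian random walks and are *not* constrained to sum to 1,
#' so an action may reach both states, one, or neither. Each trial carries
#' an instructed goal: seek the reward state (+1 point when reached) or
#' avoid the punishment state (-1 point when reached); reaching a state the
#' instructions did not mention has no consequence.
#'
#' @param n_trials session length, default 180.
#' @param drift_sd random-walk step s.d., default 0.04.
#' @param bounds reflecting bounds, default [0.1, 0.9].
#' @param goals optional goal sequence (`"seek_reward"` / `"avoid_punish"`);
#'   by default a balanced randomized order over `n_trials`.
#' @param seed optional integer seed.
#' @return an object of class `multi_goal_env`.
#' @export
multi_goal_env <- function(n_trials = 180, drift_sd = 0.04,
                           bounds = c(0.1, 0.9), goals = NULL, seed = NULL) {
  stopifnot(bounds[1] < bounds[2], bounds[1] >= 0, bounds[2] <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(goals)) {
    goals <- sample(rep(c("seek_reward", "avoid_punish"),
                        length.out = n_trials))
  }
  if (!all(goals %in% c("seek_reward", "avoid_punish")))
    stop("goal labels must be 'seek_reward' or 'avoid_punish'")
  probs <- matrix(runif(4, bounds[1], bounds[2]), 2, 2,
                  dimnames = list(action = c("1", "2"),
                                  state = c("reward", "punish")))
  structure(list(n_trials = n_trials, drift_sd = drift_sd, bounds = bounds,
                 goals = goals, probs = probs, t = 0L),
            class = "multi_goal_env")
}

#' Advance a multi-goal environment one trial
#'
#' Each state is reached independently with its current P(state | action);
#' points are +1 iff the reward state is reached on a seek-reward trial,
#' -1 iff the punishment state is reached on an avoid-punishment trial,
#' and 0 otherwise. All four probabilities then take one reflected
#' random-walk step.
#'
#' @param env a [multi_goal_env()].
#' @param action action in {1, 2} (1 = "g", 2 = "j").
#' @return list with `reached` (named logical: reward, punish), `points`,
#'   `goal` (this trial's instructed goal) and the advanced `env`.
#' @export
step_multigoal <- function(env, action) {
  stopifnot(inherits(env, "multi_goal_env"), action %in% 1:2)
  if (env$t >= env$n_trials) stop("environment has no trials left")
  goal <- env$goals[env$t + 1L]
  reached <- runif(2) < env$probs[action, ]
  names(reached) <- c("reward", "punish")
  points <- 0
  if (goal == "seek_reward" && reached["reward"]) points <- 1
  if (goal == "avoid_punish" && reached["punish"]) points <- -1
  if (env$drift_sd > 0) {
    p <- env$probs + rnorm(4, 0, env$drift_sd)
    env$probs[] <- reflect_bounds(p, env$bounds[1], env$bounds[2])
  }
  env$t <- env$t + 1L
  list(reached = reached, points = points, goal = goal, env = env)
}
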