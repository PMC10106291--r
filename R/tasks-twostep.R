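#' Two-step task environment
#'
#' Sequential decision task with two first-stage actions, two second-stage
#' states and two second-stage actions. First-stage transitions are stable:
#' action 1 leads to state 1 with probability `p_common` (default 0.7) and
#' action 2 to state 2 likewise. Second-stage reward probabilities drift
#' across trials by independent Gaussian random walks reflected at the
#' configured bounds.
#'
#' @param n_trials session length, default 200.
#' @param p_common common-transition probability, default 0.7.
#' @param drift_sd random-walk step s.d. for reward probabilities.
#' @param bounds reflecting bounds for reward probabilities.
#' @param seed optional integer seed for the initial reward probabilities.
#' @return an object of class `two_step_env`.
#' @export
two_step_env <- function(n_trials = 200, p_common = 0.7, drift_sd = 0.025,
                         bounds = c(0.25, 0.75), seed = NULL) {
  stopifnot(p_common > 0.5, p_common <= 1, bounds[1] < bounds[2])
  if (!is.null(seed)) set.seed(seed)
  reward_probs <- matrix(runif(4, bounds[1], bounds[2]), 2, 2,
                         dimnames = list(state = c("1", "2"),
                                         action = c("1", "2")))
  structure(list(n_trials = n_trials, p_common = p_common,
                 drift_sd = drift_sd, bounds = bounds,
                 reward_probs = reward_probs, t = 0L),
            class = "two_step_env")
}

#' Advance a two-step environment one trial
#'
#' Draws the second-stage state from the true transition matrix, the reward
#' from the current (drifting) reward probability of the chosen second-stage
#' action, then advances every reward probability one reflected random-walk
#' step.
#'
#' @param env a [two_step_env()].
#' @param first_action,second_action actions in {1, 2}.
#' @return list with `state2`, `reward`, `common` (was the transition the
#'   common one) and the advanced `env`.
#' @export
step_two_step <- function(env, first_action, second_action) {
  stopifnot(inherits(env, "two_step_env"),
            first_action %in% 1:2, second_action %in% 1:2)
  common <- runif(1) < env$p_common
  state2 <- if (common) first_action else 3L - first_action
  reward <- as.numeric(runif(1) < env$reward_probs[state2, second_action])
  if (env$drift_sd > 0) {
    p <- env$reward_probs + rnorm(4, 0, env$drift_sd)
    env$reward_probs[] <- reflect_bounds(p, env$bounds[1], env$bounds[2])
  }
  env$t <- env$t + 1L
  list(state2 = state2, reward = reward, common = common, env = env)
}

reflect_bounds <- function(x, lo, hi) {
  while (any(x < lo | x > hi)) {
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
  }
  x
}
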