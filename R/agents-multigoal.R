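#' Multi-goal agent parameters
#'
#' Parameters of the four-strategy integrated model: a model-based strategy
#' evaluated against the trial's instructed goal, a goal-perseveration
#' strategy that always seeks reward and avoids punishment, a model-free
#' strategy over points, and an action-perseveration bias. Softmax
#' temperature is absorbed into the strategy weights.
#'
#' @param gamma transition learning rate in [0, 1].
#' @param beta_mb_reward,beta_mb_punish model-based weights for reward
#'   seeking and punishment avoidance.
#' @param beta_gp_reward,beta_gp_punish goal-perseveration weights.
#' @param beta_mf model-free weight.
#' @param beta_ap action-perseveration weight.
#' @param alpha_mf model-free learning rate in [0, 1].
#' @return named numeric vector in the canonical parameter order.
#' @export
multigoal_params <- function(gamma = 0.4, beta_mb_reward = 4,
                             beta_mb_punish = 4, beta_gp_reward = 1,
                             beta_gp_punish = 1, beta_mf = 0.5,
                             beta_ap = 0.2, alpha_mf = 0.4) {
  p <- c(gamma = gamma, beta_mb_reward = beta_mb_reward,
         beta_mb_punish = beta_mb_punish, beta_gp_reward = beta_gp_reward,
         beta_gp_punish = beta_gp_punish, beta_mf = beta_mf,
         beta_ap = beta_ap, alpha_mf = alpha_mf)
  validate_multigoal_params(p)
  p
}

validate_multigoal_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 8)
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (p[["gamma"]] < 0 || p[["gamma"]] > 1 ||
      p[["alpha_mf"]] < 0 || p[["alpha_mf"]] > 1)
    stop("rates must lie in [0, 1]")
  invisible(p)
}

#' Integrated action values and policy for the multi-goal task
#'
#' Model-based values multiply the transition estimate by the instructed
#' goal vector — (1, 0) on seek-reward trials, (0, -1) on avoid-punishment
#' trials — so the strategy only values the goal-relevant state.
#' Goal-perseveration values use the fixed vector (1, -1). The strategies
#' are combined in a weighted sum and passed through a softmax.
#'
#' @param belief a multi-goal [transition_belief()] (columns reward,
#'   punish).
#' @param goal `"seek_reward"` or `"avoid_punish"`.
#' @param Q_mf length-2 model-free values.
#' @param prev_action previous action or `NA`.
#' @param params a [multigoal_params()] vector.
#' @return list with `policy`, `Q_integrated` and the per-strategy value
#'   components.
#' @export
multigoal_action_values <- function(belief, goal, Q_mf, prev_action,
                                    params) {
  validate_multigoal_params(params)
  if (!goal %in% c("seek_reward", "avoid_punish"))
    stop("unknown goal label: ", goal)
  p_r <- belief[, "reward"]
  p_p <- belief[, "punish"]
  q_mb_reward <- if (goal == "seek_reward") p_r * 1 else p_r * 0
  q_mb_punish <- if (goal == "avoid_punish") p_p * -1 else p_p * 0
  q_gp_reward <- p_r * 1
  q_gp_punish <- p_p * -1
  q_ap <- if (is.na(prev_action)) c(0, 0) else as.numeric(1:2 == prev_action)
  q_int <- params[["beta_mb_reward"]] * q_mb_reward +
    params[["beta_mb_punish"]] * q_mb_punish +
    params[["beta_gp_reward"]] * q_gp_reward +
    params[["beta_gp_punish"]] * q_gp_punish +
    params[["beta_mf"]] * Q_mf +
    params[["beta_ap"]] * q_ap
  list(policy = softmax(q_int), Q_integrated = q_int,
       Q_mb_reward = q_mb_reward, Q_mb_punish = q_mb_punish,
       Q_gp_reward = q_gp_reward, Q_gp_punish = q_gp_punish, Q_ap = q_ap)
}

#' Simulate one agent on the multi-goal pursuit task
#'
#' @param params a [multigoal_params()] vector.
#' @param n_trials session length, default 180.
#' @param drift_sd,bounds environment settings (see [multi_goal_env()]).
#' @param goals optional goal sequence; by default balanced randomized.
#' @param decay_unchosen decay the untaken action's belief toward 0.5.
#' @param seed optional integer seed.
#' @return tibble with one row per trial: `trial`, `goal`, `action`,
#'   `reached_reward`, `reached_punish`, `points`.
#' @export
simulate_multigoal_agent <- function(params, n_trials = 180,
                                     drift_sd = 0.04, bounds = c(0.1, 0.9),
                                     goals = NULL, decay_unchosen = TRUE,
                                     seed = NULL) {
  validate_multigoal_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(goals)) {
    goals <- sample(rep(c("seek_reward", "avoid_punish"),
                        length.out = n_trials))
  }
  gcode <- match(goals, c("seek_reward", "avoid_punish"))
  if (anyNA(gcode)) stop("goal labels must be 'seek_reward'/'avoid_punish'")
  sim <- simulate_multigoal_cpp(as.numeric(params), as.integer(gcode),
                                drift_sd, bounds[1], bounds[2],
                                decay_unchosen)
  tibble::tibble(
    trial = seq_len(n_trials),
    goal = goals,
    action = sim$action,
    reached_reward = sim$reached_reward,
    reached_punish = sim$reached_punish,
    points = sim$points
  )
}

#' Per-session choice log-likelihood on the multi-goal task
#'
#' @param params a parameter vector or K x 8 matrix in the
#'   [multigoal_params()] order.
#' @param trials trial log with columns `goal`, `action`, `reached_reward`,
#'   `reached_punish`, `points`.
#' @param decay_unchosen decay the untaken action's belief toward 0.5.
#' @return numeric log-likelihood, one per parameter vector.
#' @export
loglik_multigoal <- function(params, trials, decay_unchosen = TRUE) {
  if (is.null(dim(params))) params <- matrix(params, nrow = 1)
  req <- c("goal", "action", "reached_reward", "reached_punish", "points")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  gcode <- match(trials$goal, c("seek_reward", "avoid_punish"))
  if (anyNA(gcode)) stop("goal labels must be 'seek_reward'/'avoid_punish'")
  loglik_multigoal_cpp(params, as.integer(trials$action),
                       as.integer(trials$reached_reward),
                       as.integer(trials$reached_punish),
                       as.numeric(trials$points), as.integer(gcode),
                       decay_unchosen)
}
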