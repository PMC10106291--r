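# Model objects bind a parameter table (names + prior families), a
# vectorized session log-likelihood and a generative simulator, so the
# fitting machinery is agnostic to the task.

#' Two-step decision model (ISTL or Typical)
#'
#' @param type `"istl"` (incremental state-transition learner, with free
#'   learning rate `gamma`) or `"typical"` (counting transition learner,
#'   no `gamma`).
#' @param n_trials default session length used by the simulator.
#' @param p_common,drift_sd,bounds environment settings.
#' @param decay_unchosen decay the untaken action's belief toward 0.5.
#' @return a `decision_model` object usable with [iis_fit()],
#'   [subject_loglik()] and [recover_parameters()].
#' @export
twostep_model <- function(type = c("istl", "typical"), n_trials = 200,
                          p_common = 0.7, drift_sd = 0.025,
                          bounds = c(0.25, 0.75), decay_unchosen = TRUE) {
  type <- match.arg(type)
  all_names <- c("gamma", "alpha", "decay", "beta_mb", "beta_mf", "beta_2",
                 "stickiness")
  families <- c(gamma = "beta", alpha = "beta", decay = "beta",
                beta_mb = "gamma", beta_mf = "normal", beta_2 = "gamma",
                stickiness = "normal")
  par_names <- if (type == "istl") all_names else setdiff(all_names, "gamma")
  pad <- function(params) {
    if (is.null(dim(params))) params <- matrix(params, nrow = 1,
                                               dimnames = list(NULL, par_names))
    full <- matrix(0.5, nrow(params), 7,
                   dimnames = list(NULL, all_names))
    full[, colnames(params)] <- params
    full
  }
  structure(list(
    name = type, task = "twostep",
    par_names = par_names,
    families = families[par_names],
    loglik = function(params, trials) {
      loglik_twostep(pad(params), trials, model = type,
                     decay_unchosen = decay_unchosen)
    },
    simulate = function(params, n = n_trials, seed = NULL) {
      simulate_twostep_agent(pad(params)[1, ], model = type, n_trials = n,
                             p_common = p_common, drift_sd = drift_sd,
                             bounds = bounds,
                             decay_unchosen = decay_unchosen, seed = seed)
    }
  ), class = "decision_model")
}

#' Multi-goal integrated decision model
#'
#' Four-strategy model for the multi-goal pursuit task: goal-conditioned
#' model-based values, goal perseveration, model-free values over points,
#' and action perseveration, combined in a weighted softmax.
#'
#' @param n_trials default session length used by the simulator.
#' @param drift_sd,bounds environment settings.
#' @param decay_unchosen decay the untaken action's belief toward 0.5.
#' @return a `decision_model` object.
#' @export
multigoal_model <- function(n_trials = 180, drift_sd = 0.04,
                            bounds = c(0.1, 0.9), decay_unchosen = TRUE) {
  par_names <- c("gamma", "beta_mb_reward", "beta_mb_punish",
                 "beta_gp_reward", "beta_gp_punish", "beta_mf", "beta_ap",
                 "alpha_mf")
  families <- c(gamma = "beta", beta_mb_reward = "gamma",
                beta_mb_punish = "gamma", beta_gp_reward = "gamma",
                beta_gp_punish = "gamma", beta_mf = "normal",
                beta_ap = "normal", alpha_mf = "beta")
  structure(list(
    name = "multigoal", task = "multigoal",
    par_names = par_names, families = families,
    loglik = function(params, trials) {
      if (is.null(dim(params))) params <- matrix(params, nrow = 1,
                                                 dimnames = list(NULL, par_names))
      loglik_multigoal(params[, par_names, drop = FALSE], trials,
                       decay_unchosen = decay_unchosen)
    },
    simulate = function(params, n = n_trials, seed = NULL) {
      simulate_multigoal_agent(params[par_names], n_trials = n,
                               drift_sd = drift_sd, bounds = bounds,
                               decay_unchosen = decay_unchosen, seed = seed)
    }
  ), class = "decision_model")
}

#' Moderate generating prior for recovery studies
#'
#' Group distributions used to draw "true" participants in
#' simulate-and-refit studies: rates from Beta(2, 2), model-based and
#' second-stage weights from moderately dispersed Gammas, signed weights
#' from Normals centered at small positive values.
#'
#' @param model a `decision_model`.
#' @return a [group_prior()].
#' @export
moderate_prior <- function(model) {
  spec <- list(
    gamma = c("beta", 2, 2), alpha = c("beta", 2, 2),
    decay = c("beta", 2, 2), beta_mb = c("gamma", 2, 2),
    beta_mf = c("normal", 1.5, 0.75), beta_2 = c("gamma", 3, 1),
    stickiness = c("normal", 0.2, 0.5),
    beta_mb_reward = c("gamma", 2, 2), beta_mb_punish = c("gamma", 2, 2),
    beta_gp_reward = c("gamma", 2, 0.5), beta_gp_punish = c("gamma", 2, 0.5),
    beta_ap = c("normal", 0.2, 0.5), alpha_mf = c("beta", 2, 2)
  )
  if (model$task == "multigoal") spec$beta_mf <- c("normal", 0.5, 0.5)
  rows <- spec[model$par_names]
  group_prior(setNames(vapply(rows, `[`, "", 1), model$par_names),
              par1 = as.numeric(vapply(rows, `[`, "", 2)),
              par2 = as.numeric(vapply(rows, `[`, "", 3)))
}
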