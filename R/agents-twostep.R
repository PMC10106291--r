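#' Two-step agent parameters
#'
#' @param gamma transition learning rate in [0, 1] (ignored by the Typical
#'   counting learner).
#' @param alpha value learning rate in [0, 1]; chosen-action values decay
#'   by the complement 1 - alpha.
#' @param decay unchosen-action value decay D in [0, 1].
#' @param beta_mb model-based weight (non-negative).
#' @param beta_mf model-free weight.
#' @param beta_2 second-stage inverse temperature (non-negative).
#' @param stickiness first-stage choice-perseveration weight.
#' @return named numeric vector in the canonical parameter order.
#' @export
two_step_params <- function(gamma = 0.3, alpha = 0.5, decay = 0.3,
                            beta_mb = 4, beta_mf = 1, beta_2 = 3,
                            stickiness = 0.2) {
  p <- c(gamma = gamma, alpha = alpha, decay = decay, beta_mb = beta_mb,
         beta_mf = beta_mf, beta_2 = beta_2, stickiness = stickiness)
  validate_two_step_params(p)
  p
}

validate_two_step_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 7)
  if (any(!is.finite(p))) stop("parameters must be finite")
  rates <- p[c("gamma", "alpha", "decay")]
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (p[["beta_mb"]] < 0) stop("beta_mb must be non-negative")
  if (p[["beta_2"]] < 0) stop("beta_2 must be non-negative")
  invisible(p)
}

#' First- and second-stage policies of the hybrid two-step chooser
#'
#' Model-based values are the expected best second-stage value under the
#' current transition estimate, Q_MB(a) = sum_s P(s | a) max_a' Q2(s, a').
#' The first-stage policy is a softmax over beta_mb * Q_MB + beta_mf * Q_MF
#' + stickiness * 1[a = previous action]; the second-stage policy is a
#' softmax over beta_2 * Q2(s, .).
#'
#' @param trans 2 x 2 transition estimate (belief or inferred matrix),
#'   rows = first-stage actions.
#' @param Q2 2 x 2 second-stage values, rows = states.
#' @param Q_mf length-2 first-stage model-free values.
#' @param params a [two_step_params()] vector.
#' @param prev_action previous first-stage action, or `NA` on trial 1.
#' @return list with `policy1` (first-stage choice probabilities), `Q_mb`,
#'   and `policy2` (2 x 2 matrix of second-stage choice probabilities per
#'   state).
#' @export
two_step_choice_values <- function(trans, Q2, Q_mf, params,
                                   prev_action = NA) {
  validate_two_step_params(params)
  if (any(!is.finite(trans)) || any(!is.finite(Q2)) || any(!is.finite(Q_mf)))
    stop("non-finite values in belief or action values")
  q_mb <- as.numeric(trans %*% apply(Q2, 1, max))
  stick <- if (is.na(prev_action)) c(0, 0) else
    params[["stickiness"]] * (1:2 == prev_action)
  net <- params[["beta_mb"]] * q_mb + params[["beta_mf"]] * Q_mf + stick
  policy2 <- t(apply(Q2, 1, function(q) softmax(params[["beta_2"]] * q)))
  list(policy1 = softmax(net), Q_mb = q_mb, policy2 = policy2)
}

#' Simulate one agent on the two-step task
#'
#' Generative run of the hybrid chooser with either the incremental (ISTL)
#' or counting (Typical) transition learner, against the stable 0.7/0.3
#' transition structure with drifting second-stage reward probabilities.
#'
#' @param params a [two_step_params()] vector.
#' @param model `"istl"` or `"typical"`.
#' @param n_trials session length.
#' @param p_common,drift_sd,bounds environment settings (see
#'   [two_step_env()]).
#' @param decay_unchosen decay the untaken action's belief toward 0.5
#'   (ISTL only).
#' @param seed optional integer seed.
#' @return tibble with one row per trial: `trial`, `action1`, `state2`,
#'   `common`, `action2`, `reward`.
#' @export
simulate_twostep_agent <- function(params, model = c("istl", "typical"),
                                   n_trials = 200, p_common = 0.7,
                                   drift_sd = 0.025, bounds = c(0.25, 0.75),
                                   decay_unchosen = TRUE, seed = NULL) {
  model <- match.arg(model)
  validate_two_step_params(params)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_twostep_cpp(ifelse(model == "istl", 0L, 1L),
                              as.numeric(params), n_trials, p_common,
                              drift_sd, bounds[1], bounds[2], decay_unchosen)
  tibble::tibble(
    trial = seq_len(n_trials),
    action1 = sim$action1,
    state2 = sim$state2,
    common = sim$action1 == sim$state2,
    action2 = sim$action2,
    reward = sim$reward
  )
}

#' Per-session choice log-likelihood on the two-step task
#'
#' Sum over trials of the log choice probability of both stage choices
#' under the hybrid chooser, evaluated for one or many parameter vectors.
#'
#' @param params a parameter vector or a K x 7 matrix (rows = parameter
#'   vectors) in the [two_step_params()] order.
#' @param trials trial log with columns `action1`, `state2`, `action2`,
#'   `reward`.
#' @param model `"istl"` or `"typical"`.
#' @param decay_unchosen decay the untaken action's belief toward 0.5.
#' @return numeric log-likelihood, one per parameter vector.
#' @export
loglik_twostep <- function(params, trials, model = c("istl", "typical"),
                           decay_unchosen = TRUE) {
  model <- match.arg(model)
  if (is.null(dim(params))) params <- matrix(params, nrow = 1)
  req <- c("action1", "state2", "action2", "reward")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  loglik_twostep_cpp(ifelse(model == "istl", 0L, 1L), params,
                     as.integer(trials$action1), as.integer(trials$state2),
                     as.integer(trials$action2), as.numeric(trials$reward),
                     decay_unchosen)
}
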