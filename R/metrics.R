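#' Model-agnostic model-basedness score
#'
#' Proportion of post-rare-transition trials on which behavior complies
#' with model-based control: switching after a rewarded rare transition
#' and staying after an unrewarded one,
#' (#switch after rare & rewarded + #stay after rare & unrewarded) /
#' (#rare & rewarded + #rare & unrewarded).
#'
#' @param trial_log a two-step trial log with columns `action1`, `common`
#'   (logical; or `state2` from which it is derived) and `reward`. If a
#'   `participant_id` column with several ids is present the score is
#'   computed per participant.
#' @return a single proportion (NA when no rare transitions occurred), or
#'   a tibble `participant_id` / `model_basedness` for multi-participant
#'   logs.
#' @export
model_basedness <- function(trial_log) {
  if ("participant_id" %in% names(trial_log) &&
      length(unique(trial_log$participant_id)) > 1) {
    parts <- split(trial_log, trial_log$participant_id)
    return(tibble::tibble(
      participant_id = names(parts),
      model_basedness = vapply(parts, model_basedness, numeric(1))
    ))
  }
  if (!"common" %in% names(trial_log)) {
    if (!"state2" %in% names(trial_log))
      stop("trial log needs a 'common' or 'state2' column")
    trial_log$common <- trial_log$action1 == trial_log$state2
  }
  n <- nrow(trial_log)
  if (n < 2) return(NA_real_)
  prev <- trial_log[-n, ]
  stay <- trial_log$action1[-1] == prev$action1
  rare_rew <- !prev$common & prev$reward == 1
  rare_unrew <- !prev$common & prev$reward == 0
  denom <- sum(rare_rew) + sum(rare_unrew)
  if (denom == 0) return(NA_real_)
  (sum(!stay & rare_rew) + sum(stay & rare_unrew)) / denom
}

#' Stay-probability table
#'
#' Probability of repeating the previous first-stage action, conditioned
#' on whether that action was followed by a common or rare transition and
#' whether it was rewarded.
#'
#' @param trial_log a two-step trial log (one participant, or pooled).
#' @return tibble with one row per {common, rare} x {rewarded,
#'   unrewarded} cell: `transition`, `rewarded`, `stay_prob`, `n`.
#' @export
stay_probability_table <- function(trial_log) {
  if (!"common" %in% names(trial_log))
    trial_log$common <- trial_log$action1 == trial_log$state2
  if ("participant_id" %in% names(trial_log) &&
      length(unique(trial_log$participant_id)) > 1) {
    parts <- split(trial_log, trial_log$participant_id)
    tabs <- lapply(parts, stay_probability_table)
    out <- tabs[[1]][, c("transition", "rewarded")]
    out$stay_prob <- rowMeans(vapply(tabs, function(t) t$stay_prob,
                                     numeric(4)))
    out$n <- rowSums(vapply(tabs, function(t) as.numeric(t$n), numeric(4)))
    return(out)
  }
  n <- nrow(trial_log)
  prev <- trial_log[-n, ]
  stay <- trial_log$action1[-1] == prev$action1
  cells <- expand.grid(transition = c("common", "rare"),
                       rewarded = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cells <- cells[order(cells$transition, -cells$rewarded), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- (prev$common == (cells$transition[i] == "common")) &
      (prev$reward == as.numeric(cells$rewarded[i]))
    data.frame(stay_prob = if (any(sel)) mean(stay[sel]) else NA_real_,
               n = sum(sel))
  })
  out <- cbind(cells, do.call(rbind, res))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Regress a trait on model parameters and covariates
#'
#' Ordinary least squares on standardized variables, with two-sided
#' t-tests per coefficient.
#'
#' @param estimates data frame of per-participant parameter estimates
#'   (the predictors).
#' @param traits numeric vector (or single-column data frame) of trait
#'   scores, aligned with `estimates`.
#' @param covariates optional data frame of covariates (e.g. age, sex,
#'   IQ), standardized and entered alongside the predictors.
#' @return tibble with `term`, `estimate`, `se`, `t`, `p`.
#' @export
trait_parameter_regression <- function(estimates, traits,
                                       covariates = NULL) {
  if (is.data.frame(traits)) traits <- traits[[1]]
  X <- as.data.frame(estimates)
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  stopifnot(nrow(X) == length(traits))
  X <- as.data.frame(lapply(X, function(col) as.numeric(scale(col))))
  dat <- cbind(data.frame(.trait = as.numeric(scale(traits))), X)
  fit <- lm(.trait ~ ., data = dat)
  if (any(is.na(coef(fit))))
    stop("singular design: predictors are collinear (",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")
  s <- summary(fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], se = s[, 2],
                 t = s[, 3], p = s[, 4])
}

#' Mediation analysis of the learning-rate/trait relation
#'
#' Runs the three regressions used to test whether the model-based weight
#' mediates the association between the transition learning rate and a
#' trait: trait ~ gamma, trait ~ beta_mb, and the joint model trait ~
#' gamma + beta_mb (all with optional covariates). Because the two
#' parameters are nonlinearly related, both are log-transformed by
#' default. The verdict is "full mediation" when gamma is individually
#' significant but non-significant in the joint model while beta_mb
#' remains significant; "no mediation" otherwise (with "none" when gamma
#' is not even individually significant).
#'
#' @param gamma,beta_mb per-participant parameter estimates (positive
#'   when `log_transform` is on).
#' @param trait per-participant trait scores.
#' @param covariates optional covariate data frame.
#' @param log_transform log-transform gamma and beta_mb first.
#' @param alpha significance level for the verdict.
#' @return a `mediation_result` list: `paths` (tibble of the three
#'   regressions' gamma/beta_mb coefficients) and `verdict`.
#' @export
mediation_analysis <- function(gamma, beta_mb, trait, covariates = NULL,
                               log_transform = TRUE, alpha = 0.05) {
  stopifnot(length(gamma) == length(beta_mb),
            length(gamma) == length(trait))
  if (log_transform) {
    if (any(gamma <= 0) || any(beta_mb <= 0))
      stop("log transform requires strictly positive gamma and beta_mb; ",
           "pass log_transform = FALSE or floor the estimates first")
    gamma <- log(gamma)
    beta_mb <- log(beta_mb)
  }
  reg <- function(preds) {
    trait_parameter_regression(preds, trait, covariates)
  }
  m_gamma <- reg(data.frame(gamma = gamma))
  m_bmb <- reg(data.frame(beta_mb = beta_mb))
  m_joint <- reg(data.frame(gamma = gamma, beta_mb = beta_mb))
  pick <- function(m, term, model) {
    row <- m[m$term == term, ]
    cbind(data.frame(model = model), as.data.frame(row))
  }
  paths <- tibble::as_tibble(rbind(
    pick(m_gamma, "gamma", "trait ~ gamma"),
    pick(m_bmb, "beta_mb", "trait ~ beta_mb"),
    pick(m_joint, "gamma", "trait ~ gamma + beta_mb"),
    pick(m_joint, "beta_mb", "trait ~ gamma + beta_mb")
  ))
  p_of <- function(model, term) paths$p[paths$model == model &
                                          paths$term == term]
  gamma_alone <- p_of("trait ~ gamma", "gamma") < alpha
  gamma_joint <- p_of("trait ~ gamma + beta_mb", "gamma") < alpha
  bmb_joint <- p_of("trait ~ gamma + beta_mb", "beta_mb") < alpha
  verdict <- if (gamma_alone && !gamma_joint && bmb_joint) {
    "full mediation"
  } else if (gamma_alone) {
    "no mediation"
  } else {
    "none"
  }
  structure(list(paths = paths, verdict = verdict, alpha = alpha),
            class = "mediation_result")
}

#' Regress simulated model-basedness on the learning rate and model-based weight
#'
#' Posterior-predictive style check of what the compliance metric tracks:
#' simulates a cohort in which only the transition learning rate and the
#' model-based weight vary — drawn from low, right-skewed distributions
#' emulating fitted two-step populations — with the remaining parameters
#' fixed at central values, then regresses each agent's model-basedness
#' on the two varied parameters. Across such cohorts the learning-rate
#' coefficient is negative and the model-based-weight coefficient
#' positive: fast transition learning mimics reduced model-based control.
#'
#' The learning-rate and weight effects are antagonistic at high
#' learning rates (strong model-based control expresses the *reduced*
#' signature when the belief flips trial-to-trial), so the signs are only
#' interpretable over an empirically plausible low-rate range; hence the
#' default distributions.
#'
#' @param n_agents cohort size.
#' @param n_trials trials per agent.
#' @param gamma_shape Beta shape parameters of the learning-rate
#'   distribution.
#' @param beta_mb_shape Gamma shape and scale of the model-based-weight
#'   distribution.
#' @param fixed the remaining [two_step_params()] values.
#' @param seed integer seed.
#' @return list with `coefficients` (the standardized regression table),
#'   `params` (per-agent gamma and beta_mb) and `model_basedness`.
#' @export
model_basedness_parameter_regression <- function(
    n_agents = 400, n_trials = 200, gamma_shape = c(1.3, 5.5),
    beta_mb_shape = c(1.5, 2.5),
    fixed = c(alpha = 0.6, decay = 0.3, beta_mf = 1.5, beta_2 = 3,
              stickiness = 0.1),
    seed = 1) {
  set.seed(seed)
  model <- twostep_model("istl")
  gamma <- rbeta(n_agents, gamma_shape[1], gamma_shape[2])
  beta_mb <- rgamma(n_agents, beta_mb_shape[1], scale = beta_mb_shape[2])
  mb <- vapply(seq_len(n_agents), function(i) {
    pars <- c(gamma = gamma[i], beta_mb = beta_mb[i], fixed)
    model_basedness(model$simulate(pars[model$par_names], n = n_trials))
  }, numeric(1))
  coefs <- trait_parameter_regression(
    data.frame(gamma = gamma, beta_mb = beta_mb), mb)
  list(coefficients = coefs,
       params = tibble::tibble(gamma = gamma, beta_mb = beta_mb),
       model_basedness = mb)
}

#' Reward optimality sweep over transition learning rates
#'
#' Simulates agents across a grid of transition learning rates with all
#' other parameters fixed, averages total reward over many plays per grid
#' point, and min-max normalizes the curve. A refined grid around the
#' argmax is also evaluated.
#'
#' @param task `"twostep"` (stable transitions) or `"multigoal"`
#'   (changing transitions).
#' @param gamma_grid learning-rate grid.
#' @param n_reps plays per grid point.
#' @param fixed_params remaining model parameters
#'   ([two_step_params()] / [multigoal_params()] order); defaults to
#'   [sweep_default_params()].
#' @param n_trials trials per play.
#' @param seed integer seed.
#' @param refine evaluate a refined grid around the argmax.
#' @param refine_halfwidth,refine_points refined-grid geometry.
#' @return list with `curve` (tibble gamma / mean_reward / normalized),
#'   `refined` (same shape, or NULL), `gamma_opt` (argmax of the coarse
#'   curve).
#' @export
optimality_sweep <- function(task = c("twostep", "multigoal"),
                             gamma_grid = seq(0, 1, by = 0.1),
                             n_reps = 20000, fixed_params = NULL,
                             n_trials = NULL, seed = 1, refine = TRUE,
                             refine_halfwidth = 0.1, refine_points = 5) {
  task <- match.arg(task)
  stopifnot(all(gamma_grid >= 0 & gamma_grid <= 1), n_reps >= 1)
  if (is.null(fixed_params)) fixed_params <- sweep_default_params(task)
  set.seed(seed)
  run <- function(grid) {
    if (task == "twostep") {
      sweep_twostep_cpp(grid, as.numeric(fixed_params), n_reps,
                        if (is.null(n_trials)) 200L else as.integer(n_trials),
                        0.7, 0.025, 0.25, 0.75, 0L, TRUE)
    } else {
      sweep_multigoal_cpp(grid, as.numeric(fixed_params), n_reps,
                          if (is.null(n_trials)) 180L else as.integer(n_trials),
                          0.04, 0.1, 0.9, TRUE)
    }
  }
  mean_reward <- run(gamma_grid)
  normalized <- if (diff(range(mean_reward)) > 0) {
    (mean_reward - min(mean_reward)) / diff(range(mean_reward))
  } else {
    rep(0, length(mean_reward))
  }
  curve <- tibble::tibble(gamma = gamma_grid, mean_reward = mean_reward,
                          normalized = normalized)
  gamma_opt <- gamma_grid[which.max(mean_reward)]
  refined <- NULL
  if (refine) {
    lo <- max(0, gamma_opt - refine_halfwidth)
    hi <- min(1, gamma_opt + refine_halfwidth)
    rg <- seq(lo, hi, length.out = refine_points)
    mr <- run(rg)
    refined <- tibble::tibble(gamma = rg, mean_reward = mr)
  }
  list(curve = curve, refined = refined, gamma_opt = gamma_opt,
       task = task, fixed_params = fixed_params)
}

#' Default fixed parameters for optimality sweeps
#'
#' The model-based weight is set high — the 97.5th percentile of the
#' moderate generating distribution, approximating an extreme value still
#' within the plausible range — and the remaining parameters to the
#' generating distribution's central values (median for the skewed Gamma
#' weights, mean otherwise; see [skewed_z()] for the skewness rule).
#'
#' @param task `"twostep"` or `"multigoal"`.
#' @return named parameter vector.
#' @export
sweep_default_params <- function(task = c("twostep", "multigoal")) {
  task <- match.arg(task)
  hi_mb <- qgamma(0.975, shape = 2, scale = 2)
  if (task == "twostep") {
    two_step_params(gamma = 0.3, alpha = 0.5, decay = 0.5,
                    beta_mb = hi_mb, beta_mf = 1.5, beta_2 = 3,
                    stickiness = 0.2)
  } else {
    multigoal_params(gamma = 0.4, beta_mb_reward = hi_mb,
                     beta_mb_punish = hi_mb, beta_gp_reward = 1,
                     beta_gp_punish = 1, beta_mf = 0.5, beta_ap = 0.2,
                     alpha_mf = 0.4)
  }
}

#' Skewness z-score
#'
#' Sample skewness divided by its standard error; distributions with
#' |z| > 4 are treated as highly skewed (fixed at their median rather
#' than mean in sweeps).
#'
#' @param x numeric sample.
#' @return the skewness z-score.
#' @export
skewed_z <- function(x) {
  n <- length(x)
  s <- mean((x - mean(x))^3) / sd(x)^3
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  s / se
}
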