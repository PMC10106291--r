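# Synthetic cohorts with planted ground truth: correlated latent trait
# factors, Likert questionnaire items with a planted loading structure,
# covariates, and trait-coupled model parameters on transformed scales
# (logit for rates, log for non-negative weights) so native-scale
# invariants hold by construction.

#' Cohort specification for the synthetic-data generator
#'
#' @param n number of participants.
#' @param n_factors latent trait factors (default 3).
#' @param factor_corr common inter-factor correlation, or a full
#'   correlation matrix.
#' @param items_per_factor questionnaire items loading on each factor.
#' @param loading primary loading of each item on its factor (no
#'   cross-loadings are planted).
#' @param likert_levels number of Likert response levels (set `NULL` for
#'   continuous items).
#' @param model a `decision_model` whose parameters the cohort carries
#'   (defaults to the incremental two-step learner).
#' @param coupling matrix of trait-to-parameter slopes, parameters x
#'   factors, applied on the transformed parameter scale in standardized
#'   units; defaults to all zero. Rows must be named by parameter.
#' @param param_scale named list per parameter: `m` and `s`, the mean and
#'   s.d. of the transformed-scale parameter distribution; defaults are
#'   derived from [moderate_prior()] by moment-matching on the
#'   transformed scale.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 200, n_factors = 3, factor_corr = 0.2,
                        items_per_factor = 10, loading = 0.6,
                        likert_levels = 5, model = twostep_model("istl"),
                        coupling = NULL, param_scale = NULL, seed = 1) {
  if (length(factor_corr) == 1) {
    fc <- matrix(factor_corr, n_factors, n_factors)
    diag(fc) <- 1
  } else {
    fc <- factor_corr
    stopifnot(all(dim(fc) == n_factors))
  }
  if (is.null(coupling)) {
    coupling <- matrix(0, length(model$par_names), n_factors,
                       dimnames = list(model$par_names, NULL))
  }
  stopifnot(nrow(coupling) == length(model$par_names),
            ncol(coupling) == n_factors)
  if (is.null(rownames(coupling))) rownames(coupling) <- model$par_names
  if (any(rowSums(coupling^2) >= 1))
    stop("coupling rows must have squared norm < 1 (the residual ",
         "variance on the transformed scale must stay positive)")
  if (is.null(param_scale)) param_scale <- default_param_scale(model)
  structure(list(n = n, n_factors = n_factors, factor_corr = fc,
                 items_per_factor = items_per_factor, loading = loading,
                 likert_levels = likert_levels, model = model,
                 coupling = coupling, param_scale = param_scale,
                 seed = seed),
            class = "cohort_spec")
}

# transformed-scale (logit / log / identity) location and spread per
# parameter, moment-matched to the moderate generating prior
default_param_scale <- function(model) {
  prior <- moderate_prior(model)
  out <- list()
  for (i in seq_len(nrow(prior))) {
    x <- draw_prior(prior, 2000)[, prior$parameter[i]]
    z <- switch(prior$family[i],
                beta = qlogis(pmin(pmax(x, 1e-4), 1 - 1e-4)),
                gamma = log(pmax(x, 1e-4)),
                normal = x)
    out[[prior$parameter[i]]] <- list(m = mean(z), s = sd(z),
                                      family = prior$family[i])
  }
  out
}

param_from_z <- function(z, scale) {
  x <- scale$m + scale$s * z
  switch(scale$family, beta = plogis(x), gamma = exp(x), normal = x)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws correlated latent trait factors, Likert questionnaire items from
#' the planted loading structure, covariates (age, sex, IQ) and model
#' parameters coupled to the traits on transformed scales. The returned
#' ground truth is sufficient to recompute every planted effect without
#' the pipeline.
#'
#' @param spec a [cohort_spec()].
#' @return list with `participants` (tibble: ids, factor scores,
#'   covariates, native-scale parameters), `items` (participants x items
#'   matrix) and `ground_truth` (the spec plus the exact latent draws).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  Fm <- chol(spec$factor_corr)
  factors <- matrix(rnorm(n * spec$n_factors), n) %*% Fm
  colnames(factors) <- paste0("F", seq_len(spec$n_factors))

  lam <- spec$loading
  p_items <- spec$items_per_factor * spec$n_factors
  items <- matrix(NA_real_, n, p_items)
  for (f in seq_len(spec$n_factors)) {
    for (j in seq_len(spec$items_per_factor)) {
      col <- (f - 1) * spec$items_per_factor + j
      items[, col] <- lam * factors[, f] +
        sqrt(1 - lam^2) * rnorm(n)
    }
  }
  colnames(items) <- paste0("item", seq_len(p_items))
  if (!is.null(spec$likert_levels)) {
    k <- spec$likert_levels
    cuts <- qnorm(seq_len(k - 1) / k)
    items[] <- findInterval(items, cuts) + 1
  }

  par_names <- spec$model$par_names
  params <- matrix(NA_real_, n, length(par_names),
                   dimnames = list(NULL, par_names))
  z_resid <- matrix(rnorm(n * length(par_names)), n)
  for (i in seq_along(par_names)) {
    p <- par_names[i]
    cvec <- spec$coupling[p, ]
    z <- as.numeric(factors %*% cvec) +
      sqrt(1 - sum(cvec^2)) * z_resid[, i]
    params[, p] <- param_from_z(z, spec$param_scale[[p]])
  }

  participants <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = round(runif(n, 18, 65)),
    sex = rbinom(n, 1, 0.5),
    iq = round(rnorm(n, 100, 15))
  )
  participants <- cbind(participants, as.data.frame(factors),
                        as.data.frame(params))
  participants <- tibble::as_tibble(participants)

  list(participants = participants, items = items,
       ground_truth = list(spec = spec, factors = factors,
                           params = params))
}

#' Generate task behavior for a synthetic cohort
#'
#' Composes the task environments with the generative agents: each
#' participant plays the requested task with their own parameters. For
#' the one-step revaluation study, per-block correctness is generated
#' from a logistic ground-truth model on the log-odds scale instead
#' (see `study1_effects`).
#'
#' @param participants the `participants` table from [generate_cohort()]
#'   (must carry the model's parameter columns, or the trait factors for
#'   `task = "onestep"`).
#' @param task `"twostep"`, `"multigoal"` or `"onestep"`.
#' @param model a `decision_model` for the sequential tasks; ignored for
#'   `"onestep"`.
#' @param n_trials trials per participant (sequential tasks).
#' @param n_blocks blocks per participant (one-step task).
#' @param study1_effects for `"onestep"`: list with `intercept` (log-odds
#'   of block correctness at baseline), `participant_sd`, `condition_sd`
#'   and `trait_betas` (log-odds slope per factor column).
#' @param seed integer seed.
#' @return for sequential tasks, a long trial-log tibble; for
#'   `"onestep"`, a tibble with one row per (participant, block):
#'   `participant_id`, `condition`, `correct`, plus the trait columns.
#' @export
generate_study_behavior <- function(participants,
                                    task = c("twostep", "multigoal",
                                             "onestep"),
                                    model = NULL, n_trials = 200,
                                    n_blocks = 5,
                                    study1_effects = list(
                                      intercept = qlogis(0.6),
                                      participant_sd = 0.5,
                                      condition_sd = 0.3,
                                      trait_betas = c(0, 0, -0.33)),
                                    seed = 1) {
  task <- match.arg(task)
  set.seed(seed)
  if (task == "onestep") {
    fcols <- grep("^F\\d+$", names(participants), value = TRUE)
    stopifnot(length(study1_effects$trait_betas) == length(fcols))
    n <- nrow(participants)
    u <- rnorm(n, 0, study1_effects$participant_sd)
    cond_labels <- c("neutral", "pos_common", "pos_rare", "neg_common",
                     "neg_rare")[seq_len(n_blocks)]
    cond_eff <- rnorm(n_blocks, 0, study1_effects$condition_sd)
    Fmat <- as.matrix(participants[, fcols])
    out <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      eta <- study1_effects$intercept + u + cond_eff[b] +
        as.numeric(Fmat %*% study1_effects$trait_betas)
      data.frame(participant_id = participants$participant_id,
                 condition = cond_labels[b],
                 correct = rbinom(n, 1, plogis(eta)))
    }))
    out <- cbind(out, Fmat[rep(seq_len(n), n_blocks), , drop = FALSE])
    rownames(out) <- NULL
    return(tibble::as_tibble(out))
  }
  if (is.null(model)) {
    model <- if (task == "twostep") twostep_model("istl")
             else multigoal_model()
  }
  stopifnot(model$task == task)
  miss <- setdiff(model$par_names, names(participants))
  if (length(miss))
    stop("participants table lacks model parameters: ",
         paste(miss, collapse = ", "))
  logs <- lapply(seq_len(nrow(participants)), function(i) {
    pars <- unlist(participants[i, model$par_names])
    log <- model$simulate(pars, n = n_trials)
    log$participant_id <- participants$participant_id[i]
    log
  })
  out <- do.call(rbind, logs)
  tibble::as_tibble(out[, c("participant_id",
                            setdiff(names(out), "participant_id"))])
}
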