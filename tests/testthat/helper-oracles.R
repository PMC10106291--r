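# Independent oracles and small fixtures built in code.

# Brute-force trial-by-trial replay of the two-step session likelihood,
# written directly from the model definition and independent of the
# package's vectorized implementation.
replay_loglik_twostep <- function(pars, trials, model = "istl",
                                  decay_unchosen = TRUE) {
  g <- pars[["gamma"]]; a_ <- pars[["alpha"]]; D <- pars[["decay"]]
  bmb <- pars[["beta_mb"]]; bmf <- pars[["beta_mf"]]
  b2 <- pars[["beta_2"]]; st <- pars[["stickiness"]]
  P <- matrix(0.5, 2, 2)
  C <- matrix(0, 2, 2)
  Q2 <- matrix(0, 2, 2)   # rows states
  Qmf <- c(0, 0)
  prev <- NA
  ll <- 0
  sm <- function(v, i) { e <- exp(v - max(v)); log(e[i] / sum(e)) }
  for (t in seq_len(nrow(trials))) {
    a1 <- trials$action1[t]; s2 <- trials$state2[t]
    a2 <- trials$action2[t]; r <- trials$reward[t]
    Tm <- if (model == "istl") P else {
      d <- C[1, 1] + C[2, 2]; o <- C[1, 2] + C[2, 1]
      p <- if (d > o) 0.7 else if (d < o) 0.3 else 0.5
      matrix(c(p, 1 - p, 1 - p, p), 2, 2, byrow = TRUE)
    }
    qmb <- as.numeric(Tm %*% apply(Q2, 1, max))
    v <- bmb * qmb + bmf * Qmf + if (!is.na(prev)) st * (1:2 == prev) else 0
    ll <- ll + sm(v, a1) + sm(b2 * Q2[s2, ], a2)
    if (model == "istl") {
      P[a1, s2] <- P[a1, s2] + g * (1 - P[a1, s2])
      P[a1, 3 - s2] <- 1 - P[a1, s2]
      if (decay_unchosen) {
        u <- 3 - a1
        P[u, 1] <- P[u, 1] + g * (0.5 - P[u, 1])
        P[u, 2] <- 1 - P[u, 1]
      }
    } else {
      C[a1, s2] <- C[a1, s2] + 1
    }
    Qmf[a1] <- (1 - a_) * Qmf[a1] + a_ * r
    Qmf[3 - a1] <- (1 - D) * Qmf[3 - a1]
    Q2[s2, a2] <- (1 - a_) * Q2[s2, a2] + a_ * r
    Q2[s2, 3 - a2] <- (1 - D) * Q2[s2, 3 - a2]
    Q2[3 - s2, ] <- (1 - D) * Q2[3 - s2, ]
    prev <- a1
  }
  ll
}

# tiny Bernoulli "decision model" with one free rate parameter, for
# checking the importance-sampling fitter against the Beta conjugate
# closed form
bernoulli_model <- function() {
  structure(list(
    name = "bernoulli", task = "coin",
    par_names = "p", families = c(p = "beta"),
    loglik = function(params, trials) {
      s <- sum(trials$y)
      f <- length(trials$y) - s
      s * log(params[, "p"]) + f * log(1 - params[, "p"])
    }
  ), class = "decision_model")
}

quick_params <- function(...) {
  defaults <- list(gamma = 0.4, alpha = 0.5, decay = 0.3, beta_mb = 5,
                   beta_mf = 1, beta_2 = 3, stickiness = 0.2)
  do.call(two_step_params, utils::modifyList(defaults, list(...)))
}

# many-agent two-step cohort at fixed parameters; returns a long log
simulate_cohort_log <- function(n_agents, params, n_trials = 150,
                                model = "istl", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_agents), function(i) {
    l <- simulate_twostep_agent(params, model, n_trials = n_trials)
    l$participant_id <- sprintf("A%04d", i)
    l
  }))
}
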