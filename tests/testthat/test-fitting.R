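test_that("session log-likelihood matches an independent replay oracle", {
  p <- quick_params(gamma = 0.35, beta_mf = 0.8)
  log <- simulate_twostep_agent(p, "istl", n_trials = 20, seed = 31)
  for (model in c("istl", "typical")) {
    m <- twostep_model(model)
    expect_equal(subject_loglik(m, p[m$par_names], log),
                 replay_loglik_twostep(p, log, model),
                 tolerance = 1e-10)
  }
})

test_that("an indifferent parameter set scores log(1/2) per choice", {
  p <- two_step_params(gamma = 0.5, alpha = 0.5, decay = 0.3, beta_mb = 0,
                       beta_mf = 0, beta_2 = 0, stickiness = 0)
  log <- simulate_twostep_agent(p, "istl", n_trials = 40, seed = 32)
  # two binary choices per trial
  expect_equal(loglik_twostep(p, log), 80 * log(0.5))
})

test_that("adding trials never increases the log-likelihood", {
  p <- quick_params()
  log <- simulate_twostep_agent(p, "istl", n_trials = 60, seed = 33)
  lls <- vapply(c(10, 30, 60), function(n) loglik_twostep(p, log[1:n, ]),
                numeric(1))
  expect_true(all(diff(lls) <= 0))
})

test_that("importance-sampling posterior matches the Beta conjugate closed form", {
  m <- bernoulli_model()
  set.seed(34)
  y <- rbinom(40, 1, 0.3)
  cfg <- iis_config(K = 1e5, max_iter = 1, min_iter = 1, seed = 35)
  fit <- suppressMessages(iis_fit(m, list(s1 = list(y = y)), cfg))
  conj_mean <- (1 + sum(y)) / (2 + length(y))
  expect_equal(fit$estimates$p, conj_mean, tolerance = 0.02)
  # single-subject evidence approximates the true marginal likelihood
  true_evidence <- lbeta(1 + sum(y), 1 + length(y) - sum(y)) - lbeta(1, 1)
  expect_equal(unname(fit$evidence), true_evidence, tolerance = 0.02)
})

test_that("exchangeable subjects get identical estimates and evidence", {
  p <- quick_params()
  log <- simulate_twostep_agent(p, "istl", n_trials = 40, seed = 36)
  m <- twostep_model("istl")
  cfg <- iis_config(K = 600, max_iter = 4, min_iter = 4, ess_min = 0,
                    seed = 37)
  fit <- suppressMessages(iis_fit(m, list(a = log, b = log), cfg))
  expect_equal(fit$evidence[["a"]], fit$evidence[["b"]])
  expect_equal(unlist(fit$estimates[1, m$par_names]),
               unlist(fit$estimates[2, m$par_names]))
})

test_that("evidence is invariant to subject ordering", {
  set.seed(38)
  logs <- lapply(1:3, function(i)
    simulate_twostep_agent(quick_params(), "istl", n_trials = 30))
  names(logs) <- c("s1", "s2", "s3")
  m <- twostep_model("istl")
  cfg <- iis_config(K = 500, max_iter = 3, min_iter = 3, ess_min = 0,
                    seed = 39)
  f1 <- suppressMessages(iis_fit(m, logs, cfg))
  f2 <- suppressMessages(iis_fit(m, logs[c(3, 1, 2)], cfg))
  expect_equal(f1$evidence[names(f2$evidence)], f2$evidence)
  expect_equal(f1$total_evidence, f2$total_evidence)
})

test_that("a model compared with itself gives a log Bayes factor of zero", {
  set.seed(40)
  logs <- list(s1 = simulate_twostep_agent(quick_params(), "istl", 30))
  m <- twostep_model("istl")
  cfg <- iis_config(K = 400, max_iter = 3, min_iter = 3, ess_min = 0,
                    seed = 41)
  fit <- suppressMessages(iis_fit(m, logs, cfg))
  expect_equal(compare_models(fit, fit), 0)
  fit2 <- fit
  names(fit2$evidence) <- "other"
  expect_error(compare_models(fit, fit2), "different subject sets")
})

test_that("recovery studies are reproducible under a fixed seed", {
  m <- twostep_model("istl")
  cfg <- iis_config(K = 800, max_iter = 5, min_iter = 3, ess_min = 0,
                    seed = 42)
  r1 <- suppressMessages(recover_parameters(m, 12, 60, cfg, seed = 43))
  r2 <- suppressMessages(recover_parameters(m, 12, 60, cfg, seed = 43))
  expect_equal(r1$correlations, r2$correlations)
  expect_equal(r1$fit$total_evidence, r2$fit$total_evidence)
})

test_that("group priors refit toward the weighted sample moments", {
  prior <- group_prior(c(rate = "beta", wt = "gamma", signed = "normal"))
  newp <- stlearn:::refit_prior(prior, c(rate = 0.3, wt = 4, signed = -1),
                                c(rate = 0.02, wt = 2, signed = 0.25))
  draws <- draw_prior(newp, 50000)
  expect_equal(mean(draws[, "rate"]), 0.3, tolerance = 0.02)
  expect_equal(mean(draws[, "wt"]), 4, tolerance = 0.05)
  expect_equal(mean(draws[, "signed"]), -1, tolerance = 0.02)
  expect_equal(var(draws[, "signed"]), 0.25, tolerance = 0.02)
})

test_that("weight degeneracy escalates the sample size with a warning", {
  p <- quick_params()
  log <- simulate_twostep_agent(p, "istl", n_trials = 150, seed = 44)
  m <- twostep_model("istl")
  cfg <- iis_config(K = 200, max_iter = 3, min_iter = 3, ess_min = 150,
                    K_max = 400, seed = 45)
  expect_warning(fit <- suppressMessages(iis_fit(m, list(s = log), cfg)),
                 "escalating")
  expect_equal(max(fit$trace$K), 400)
})
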