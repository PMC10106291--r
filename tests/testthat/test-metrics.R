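test_that("model-basedness counts compliant post-rare behavior", {
  # hand-built log: trials alternate; rare transitions on trials 1-4
  log <- tibble::tibble(
    action1 = c(1, 2, 2, 1, 1, 1),
    common = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    reward = c(1, 0, 1, 0, 1, 0)
  )
  # after t1 (rare, rew): switch (2) -> compliant
  # after t2 (rare, unrew): stay (2) -> compliant
  # after t3 (rare, rew): switch (1) -> compliant
  # after t4 (rare, unrew): stay (1) -> compliant
  expect_equal(model_basedness(log), 1.0)
  log2 <- log
  log2$action1 <- c(1, 1, 1, 1, 1, 1)  # always stay
  # rare-rew trials now non-compliant (2 of 4 compliant)
  expect_equal(model_basedness(log2), 0.5)
})

test_that("model-basedness is invariant to action relabeling and flags empty denominators", {
  set.seed(51)
  log <- simulate_twostep_agent(quick_params(), "istl", 200)
  mb <- model_basedness(log)
  expect_true(mb >= 0 && mb <= 1)
  flipped <- log
  flipped$action1 <- 3 - log$action1
  flipped$state2 <- 3 - log$state2
  expect_equal(model_basedness(flipped), mb)
  all_common <- log
  all_common$common <- TRUE
  expect_true(is.na(model_basedness(all_common)))
})

test_that("stay-probability tables tabulate the four cells", {
  log <- tibble::tibble(action1 = rep(1, 50),
                        common = rep(c(TRUE, FALSE), 25),
                        reward = rep(c(1, 1, 0, 0), length.out = 50))
  tab <- stay_probability_table(log)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$stay_prob == 1))  # always-stay agent
  expect_equal(sum(tab$n), 49)
})

test_that("trait regressions recover planted slopes and reject collinear designs", {
  set.seed(52)
  n <- 1000
  gamma <- rnorm(n)
  trait <- 0.15 * gamma + rnorm(n, 0, sqrt(1 - 0.15^2))
  res <- trait_parameter_regression(data.frame(gamma = gamma), trait)
  row <- res[res$term == "gamma", ]
  expect_lt(abs(row$estimate - 0.15), 2 * row$se)
  expect_error(
    trait_parameter_regression(
      data.frame(a = gamma, b = 2 * gamma), trait),
    "singular|collinear")
})

test_that("null trait effects are rejected at the nominal rate", {
  set.seed(53)
  hits <- vapply(1:60, function(i) {
    x <- rnorm(400)
    y <- rnorm(400)
    res <- trait_parameter_regression(data.frame(x = x), y)
    abs(res$t[res$term == "x"]) > 2
  }, logical(1))
  expect_lte(mean(hits), 0.12)
})

test_that("mediation verdicts follow the three-regression logic", {
  set.seed(54)
  n <- 800
  # planted chain: gamma -> beta_mb -> trait (full mediation)
  g <- exp(rnorm(n, -1, 0.4))
  bmb <- exp(-0.9 * log(g) + rnorm(n, 0, 0.3))
  trait <- -0.5 * log(bmb) + rnorm(n, 0, 0.5)
  med <- mediation_analysis(g, bmb, trait)
  expect_s3_class(med, "mediation_result")
  expect_equal(med$verdict, "full mediation")

  # direct gamma effect, independent beta_mb
  bmb2 <- exp(rnorm(n, 0.5, 0.4))
  trait2 <- 0.5 * log(g) + rnorm(n, 0, 0.5)
  expect_equal(mediation_analysis(g, bmb2, trait2)$verdict, "no mediation")

  # pure noise
  expect_equal(mediation_analysis(g, bmb2, rnorm(n))$verdict, "none")
  expect_error(mediation_analysis(c(-1, g[-1]), bmb, trait),
               "positive")
})

test_that("sweep curves are min-max normalized with a refined grid", {
  sw <- optimality_sweep("multigoal", gamma_grid = c(0.1, 0.4, 0.8),
                         n_reps = 300, n_trials = 60, seed = 55)
  expect_equal(max(sw$curve$normalized), 1)
  expect_equal(min(sw$curve$normalized), 0)
  expect_true(all(sw$refined$gamma >= 0 & sw$refined$gamma <= 1))
  expect_true(sw$gamma_opt %in% sw$curve$gamma)
})

test_that("expected model-basedness decreases in the learning rate over [0.2, 1]", {
  set.seed(57)
  n <- 300
  gamma <- runif(n, 0.2, 1)
  mb <- vapply(seq_len(n), function(i) {
    p <- quick_params(gamma = gamma[i], beta_mb = 5, beta_mf = 1)
    model_basedness(simulate_twostep_agent(p, "istl", 150))
  }, numeric(1))
  fit <- trait_parameter_regression(data.frame(gamma = gamma), mb)
  row <- fit[fit$term == "gamma", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.01)
})

test_that("skewness z-scores separate symmetric from skewed samples", {
  set.seed(56)
  expect_lt(abs(skewed_z(rnorm(2000))), 4)
  expect_gt(skewed_z(rgamma(2000, shape = 0.5)), 4)
})
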