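test_that("sum-to-zero rescaling centers families and preserves the linear predictor", {
  draws <- cbind(b0 = c(0, 1), g1 = c(1, 2), g2 = c(2, -1), g3 = c(3, 5))
  out <- sum_to_zero_rescale(draws, list(g = c("g1", "g2", "g3")))
  expect_equal(unname(out[1, c("g1", "g2", "g3")]), c(-1, 0, 1))
  expect_equal(unname(out[1, "b0"]), 2)
  # linear predictor unchanged for every level and draw
  for (g in c("g1", "g2", "g3"))
    expect_equal(out[, "b0"] + out[, g], draws[, "b0"] + draws[, g],
                 tolerance = 1e-12)
  # idempotent on centered coefficients
  expect_equal(sum_to_zero_rescale(out, list(g = c("g1", "g2", "g3"))), out)
})

test_that("ROPE decisions classify HDIs correctly and are monotone in width", {
  set.seed(61)
  sig <- runif(4000, -0.58, -0.05)  # HDI well below -0.01
  expect_equal(rope_decision(sig, 0.01), "significant")
  ns <- runif(4000, -0.005, 0.008)
  expect_equal(rope_decision(ns, 0.01), "not-significant")
  und <- runif(4000, -0.02, 0.02)
  expect_equal(rope_decision(und, 0.01), "undecided")
  # widening the ROPE can only move decisions away from "significant"
  rank_of <- c(significant = 2, undecided = 1, `not-significant` = 0)
  for (i in 1:20) {
    x <- rnorm(800, rnorm(1, 0, 0.3), runif(1, 0.05, 0.5))
    d <- vapply(c(0.01, 0.1, 0.5), function(w) rope_decision(x, w), "")
    expect_true(all(diff(rank_of[d]) <= 0))
  }
})

test_that("the HDI of a symmetric unimodal sample matches the central interval", {
  set.seed(62)
  x <- rnorm(50000)
  h <- hdi(x, 0.95)
  expect_lt(abs(h[1] - qnorm(0.025)), 0.15)
  expect_lt(abs(h[2] - qnorm(0.975)), 0.15)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.95, tolerance = 0.001)
  expect_true(h[1] < posterior_mode(x) && posterior_mode(x) < h[2])
})

test_that("revaluation blocks are scored by the both-queries rule", {
  sched <- one_step_schedule()
  perfect <- expand.grid(participant_id = "P1", block = 1:5, state = 1:2)
  perfect$response <- ifelse(perfect$state == 1, 1L, 2L)
  sc <- score_revaluation_blocks(perfect, sched)
  expect_equal(sc$scores$n_correct, 5)
  expect_equal(sc$chance, 1.25)

  one_right <- perfect
  one_right$response[one_right$state == 2] <- 1L  # second query always wrong
  expect_equal(score_revaluation_blocks(one_right, sched)$scores$n_correct,
               0)

  with_na <- perfect
  with_na$response[1] <- NA
  expect_warning(sc_na <- score_revaluation_blocks(with_na, sched),
                 "missing")
  expect_equal(sc_na$scores$n_correct, 4)
})

test_that("the hierarchical logistic model recovers an intercept-only baseline", {
  set.seed(63)
  n <- 120
  dat <- expand.grid(participant = sprintf("P%03d", 1:n), condition = 1:5)
  dat$correct <- rbinom(nrow(dat), 1, 0.6)
  dat$F1 <- rnorm(nrow(dat))
  fit <- fit_hierarchical_logistic(
    dat, traits = "F1",
    sampler = sampler_config(n_chains = 2, n_adapt = 200, n_burnin = 200,
                             n_iter = 400, seed = 64),
    diagnostics_thresholds = c(rhat = 1.2, ess = 50))
  b0 <- fit$samples[, "intercept"]
  expect_equal(mean(b0), qlogis(0.6), tolerance = 0.15)
  f1 <- fit$summary[fit$summary$parameter == "F1", ]
  expect_true(f1$decision %in% c("not-significant", "undecided"))
  expect_true(all(c("rhat", "ess") %in% names(fit$summary)))
})

test_that("EFA recovers planted loading structure", {
  set.seed(65)
  n <- 800
  f <- matrix(rnorm(n * 3), n)
  lam <- 0.65
  items <- matrix(NA_real_, n, 18)
  for (k in 1:3) for (j in 1:6) {
    items[, (k - 1) * 6 + j] <- lam * f[, k] + sqrt(1 - lam^2) * rnorm(n)
  }
  efa <- fit_efa(items, 3)
  planted <- matrix(0, 18, 3)
  for (k in 1:3) planted[(k - 1) * 6 + 1:6, k] <- lam
  expect_true(all(factor_congruence(planted, efa$loadings) >= 0.9))
  # orthogonal planted factors: promax correlations near zero
  off <- efa$factor_cor[upper.tri(efa$factor_cor)]
  expect_true(all(abs(off) < 0.15))
  expect_lt(efa$bartlett$p, 0.001)
  expect_gt(efa$kmo, 0.5)
})

test_that("single-factor EFA aligns with the planted loadings", {
  set.seed(66)
  n <- 600
  f <- rnorm(n)
  lam <- seq(0.4, 0.8, length.out = 8)
  items <- vapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n),
                  numeric(n))
  efa <- fit_efa(items, 1)
  l <- as.numeric(efa$loadings)
  if (cor(l, lam) < 0) l <- -l
  expect_gt(cor(l, lam), 0.95)
})

test_that("parallel analysis counts planted factors and is seed-deterministic", {
  set.seed(67)
  n <- 500
  f <- matrix(rnorm(n * 3), n)
  items <- matrix(NA_real_, n, 18)
  for (k in 1:3) for (j in 1:6)
    items[, (k - 1) * 6 + j] <- 0.65 * f[, k] + sqrt(1 - 0.65^2) * rnorm(n)
  expect_equal(parallel_analysis(items, n_sims = 100, seed = 68), 3L)
  noise <- matrix(rnorm(n * 18), n)
  expect_lte(parallel_analysis(noise, n_sims = 100, seed = 69), 1L)
  expect_equal(parallel_analysis(items, n_sims = 50, seed = 70),
               parallel_analysis(items, n_sims = 50, seed = 70))
})
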