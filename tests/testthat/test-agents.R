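test_that("ISTL updates follow the state-prediction-error rule", {
  b <- transition_belief("twostep")
  b1 <- istl_update(b, 1, 2, gamma = 0.5)
  expect_equal(unname(b1[1, ]), c(0.25, 0.75))
  expect_equal(unname(b1[2, ]), c(0.5, 0.5))  # 0.5 is the decay fixed point

  expect_equal(unclass(istl_update(b, 1, 2, gamma = 0)), unclass(b),
               ignore_attr = TRUE)

  bfast <- b
  for (i in 1:3) bfast <- istl_update(bfast, 1, 2, gamma = 1)
  expect_equal(unname(bfast[1, 2]), 1)
  expect_equal(unname(bfast[2, ]), c(0.5, 0.5))
  # one gamma = 1 decay step returns a perturbed untaken row to 0.5
  boff <- b
  boff[2, ] <- c(0.9, 0.1)
  expect_equal(unname(istl_update(boff, 1, 1, gamma = 1)[2, ]), c(0.5, 0.5))

  expect_error(istl_update(b, 1, 2, gamma = 1.5), "\\[0, 1\\]")
})

test_that("belief invariants survive random update sequences", {
  set.seed(11)
  b <- transition_belief("twostep")
  m <- transition_belief("multigoal")
  for (i in 1:200) {
    b <- istl_update(b, sample(1:2, 1), sample(1:2, 1), runif(1))
    m <- istl_update(m, sample(1:2, 1), sample(0:1, 2, replace = TRUE),
                     runif(1))
    expect_true(all(b >= 0 & b <= 1))
    expect_equal(unname(rowSums(b)), c(1, 1), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("the counting model infers T1, T2 or their average", {
  tc <- typical_counts()
  expect_equal(unname(typical_infer(tc)), matrix(0.5, 2, 2))
  tc1 <- typical_observe(tc, 1, 1)
  expect_equal(unname(typical_infer(tc1)[1, ]), c(0.7, 0.3))
  tc2 <- typical_counts()
  tc2$counts[1, 2] <- 3
  tc2$counts[2, 1] <- 2
  expect_equal(unname(typical_infer(tc2)[1, ]), c(0.3, 0.7))
})

test_that("the counting model is permutation-covariant", {
  set.seed(12)
  tc <- typical_counts()
  obs <- data.frame(a = sample(1:2, 30, TRUE), s = sample(1:2, 30, TRUE))
  for (i in seq_len(nrow(obs))) tc <- typical_observe(tc, obs$a[i], obs$s[i])
  # relabel both actions and states (1 <-> 2)
  tc_rel <- typical_counts()
  for (i in seq_len(nrow(obs)))
    tc_rel <- typical_observe(tc_rel, 3 - obs$a[i], 3 - obs$s[i])
  expect_equal(unname(typical_infer(tc_rel)),
               unname(typical_infer(tc)[2:1, 2:1]))
})

test_that("hybrid chooser policies behave at the symmetric and greedy limits", {
  p <- quick_params()
  b <- transition_belief("twostep")
  Q2 <- matrix(c(0.6, 0.2, 0.1, 0.5), 2, 2)
  out <- two_step_choice_values(b, Q2, Q_mf = c(0.3, 0.1), p,
                                prev_action = 1)
  expect_equal(out$Q_mb[1], out$Q_mb[2])  # uniform belief: symmetric MB
  expect_equal(sum(out$policy1), 1)
  expect_equal(unname(rowSums(out$policy2)), c(1, 1))
  # with symmetric MB the policy reduces to MF + stickiness
  p0 <- quick_params(); p0[["beta_mb"]] <- 0
  out0 <- two_step_choice_values(b, Q2, Q_mf = c(0.3, 0.1), p0,
                                 prev_action = 1)
  expect_equal(out$policy1, out0$policy1)

  greedy <- quick_params(beta_mb = 500, beta_mf = 0, stickiness = 0)
  bsure <- transition_belief("twostep")
  bsure[1, ] <- c(1, 0); bsure[2, ] <- c(0, 1)
  outg <- two_step_choice_values(bsure, Q2, Q_mf = c(0, 0), greedy,
                                 prev_action = NA)
  expect_gt(outg$policy1[1], 0.999)  # state 1 holds the best value
  expect_error(two_step_choice_values(b, Q2 * NA, c(0, 0), p, NA),
               "non-finite")
})

test_that("model-free updates learn the chosen and forget the unchosen", {
  expect_equal(mf_value_update(c(0, 0), 1, reward = 1, alpha = 1, D = 0),
               c(1, 0))
  expect_equal(mf_value_update(c(0.4, 0.8), 1, 1, alpha = 0.5, D = 0),
               c(0.7, 0.8))
  expect_equal(mf_value_update(c(0.4, 0.8), 1, 1, alpha = 0.5, D = 1),
               c(0.7, 0))
  expect_error(mf_value_update(c(0, 0), 1, 1, alpha = 2, D = 0),
               "\\[0, 1\\]")
})

test_that("goal vectors gate the multi-goal strategy values", {
  b <- transition_belief("multigoal")
  b[1, ] <- c(0.8, 0.3)  # action 1: P(reward) = 0.8, P(punish) = 0.3
  p <- multigoal_params()
  out <- multigoal_action_values(b, "avoid_punish", c(0, 0), NA, p)
  expect_equal(out$Q_mb_punish[[1]], -0.3)
  expect_equal(out$Q_mb_reward[[1]], 0)   # zero in the instructed-goal vector
  expect_equal(out$Q_gp_reward[[1]], 0.8) # GP always values both states
  expect_equal(out$Q_gp_punish[[1]], -0.3)

  pz <- multigoal_params(beta_mb_reward = 0, beta_mb_punish = 0,
                         beta_gp_reward = 0, beta_gp_punish = 0,
                         beta_mf = 0, beta_ap = 0)
  outz <- multigoal_action_values(b, "seek_reward", c(0.4, -0.2), 2, pz)
  expect_equal(unname(outz$policy), c(0.5, 0.5))

  pap <- multigoal_params(beta_mb_reward = 0, beta_mb_punish = 0,
                          beta_gp_reward = 0, beta_gp_punish = 0,
                          beta_mf = 0, beta_ap = 1.2)
  outap <- multigoal_action_values(b, "seek_reward", c(0.4, -0.2), 1, pap)
  expect_equal(unname(outap$policy), softmax(c(1.2, 0)))
  expect_error(multigoal_action_values(b, "both", c(0, 0), NA, p),
               "unknown goal")
})

test_that("simulated choices are most likely under their generating learning rate", {
  p <- quick_params(gamma = 0.5)
  log <- simulate_twostep_agent(p, "istl", n_trials = 2000, seed = 21)
  ll_true <- loglik_twostep(p, log)
  ll_lo <- loglik_twostep(replace(p, 1, 0.2), log)
  ll_hi <- loglik_twostep(replace(p, 1, 0.8), log)
  expect_gt(ll_true, ll_lo)
  expect_gt(ll_true, ll_hi)
})

test_that("per-trial likelihoods are valid probabilities for any box-constrained parameters", {
  set.seed(22)
  log <- simulate_twostep_agent(quick_params(), "istl", n_trials = 50)
  mlog <- simulate_multigoal_agent(multigoal_params(), n_trials = 50)
  for (i in 1:20) {
    p <- two_step_params(gamma = runif(1), alpha = runif(1),
                         decay = runif(1), beta_mb = rgamma(1, 2, 1),
                         beta_mf = rnorm(1), beta_2 = rgamma(1, 2, 1),
                         stickiness = rnorm(1))
    ll <- loglik_twostep(p, log)
    expect_true(is.finite(ll))
    expect_lte(ll, 0)
    mp <- multigoal_params(gamma = runif(1), beta_mb_reward = rgamma(1, 2),
                           beta_mb_punish = rgamma(1, 2),
                           beta_gp_reward = rgamma(1, 2),
                           beta_gp_punish = rgamma(1, 2),
                           beta_mf = rnorm(1), beta_ap = rnorm(1),
                           alpha_mf = runif(1))
    mll <- loglik_multigoal(mp, mlog)
    expect_true(is.finite(mll))
    expect_lte(mll, 0)
  }
})
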