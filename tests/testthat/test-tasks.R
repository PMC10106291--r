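test_that("one-step blocks realize the scheduled outcome counts exactly", {
  sched <- one_step_schedule()
  for (seed in c(1, 7, 99)) {
    blk <- simulate_one_step_block(sched, seed = seed)
    expect_equal(nrow(blk$learning), 20)
    for (a in 1:2) {
      states <- blk$learning$state[blk$learning$action == a]
      expect_length(states, 10)
      expect_equal(unname(table(factor(states, levels = 1:3))[a]), 5)
      expect_equal(sum(states == 3), 2)
    }
  }
  prac <- simulate_one_step_block(one_step_schedule(practice = TRUE),
                                  seed = 3)
  for (a in 1:2) {
    states <- prac$learning$state[prac$learning$action == a]
    expect_length(states, 20)
    expect_equal(sum(states == a), 16)
  }
})

test_that("different seeds permute but never change the outcome multiset", {
  sched <- one_step_schedule()
  b1 <- simulate_one_step_block(sched, seed = 1)
  b2 <- simulate_one_step_block(sched, seed = 2)
  for (a in 1:2) {
    s1 <- b1$learning$state[b1$learning$action == a]
    s2 <- b2$learning$state[b2$learning$action == a]
    expect_equal(sort(s1), sort(s2))
  }
  expect_false(identical(b1$learning$state, b2$learning$state))
  # identical seed reproduces the block exactly
  expect_identical(simulate_one_step_block(sched, seed = 5)$learning,
                   simulate_one_step_block(sched, seed = 5)$learning)
})

test_that("one-step schedule structure is validated", {
  sched <- one_step_schedule()
  expect_true(all(rowSums(sched$counts) == 10))
  expect_equal(sum(sched$queries$scored), 2)
  expect_true(is.na(sched$queries$optimal_action[3]))
  expect_equal(sched$queries$optimal_action[1:2], c(1L, 2L))
  bad <- sched
  bad$counts[1, ] <- c(6L, 2L, 2L)
  expect_error(simulate_one_step_block(bad), "counts|actions|\\{5, 3, 2\\}")
})

test_that("two-step transitions occur at the configured common rate", {
  env <- two_step_env(drift_sd = 0, seed = 1)
  set.seed(2)
  common <- logical(10000)
  for (i in seq_len(10000)) {
    out <- step_two_step(env, 1, 1)
    common[i] <- out$common
    env <- out$env
  }
  expect_equal(mean(common), 0.7, tolerance = 0.02 / 0.7)
})

test_that("two-step reward probabilities stay within bounds and freeze at zero drift", {
  env <- two_step_env(drift_sd = 0.05, bounds = c(0.25, 0.75), seed = 3)
  set.seed(4)
  for (i in 1:200) {
    env <- step_two_step(env, sample(1:2, 1), sample(1:2, 1))$env
    expect_true(all(env$reward_probs >= 0.25 & env$reward_probs <= 0.75))
  }
  frozen <- two_step_env(drift_sd = 0, seed = 5)
  p0 <- frozen$reward_probs
  for (i in 1:50) frozen <- step_two_step(frozen, 1, 2)$env
  expect_identical(frozen$reward_probs, p0)
})

test_that("multi-goal points follow the instructed goal only", {
  env <- multi_goal_env(goals = rep("seek_reward", 5), seed = 1)
  env$probs[] <- c(1, 1, 1, 1)  # both states always reached
  out <- step_multigoal(env, 1)
  expect_true(all(out$reached))
  expect_equal(out$points, 1)   # punishment state reached, no consequence

  env2 <- multi_goal_env(goals = rep("avoid_punish", 5), seed = 2)
  env2$probs[1, ] <- c(0, 1)    # only the punishment state
  out2 <- step_multigoal(env2, 1)
  expect_equal(unname(out2$reached), c(FALSE, TRUE))
  expect_equal(out2$points, -1)

  env3 <- multi_goal_env(goals = rep("seek_reward", 5), seed = 3)
  env3$probs[1, ] <- c(1, 0)
  for (i in 1:3) {
    out3 <- step_multigoal(env3, 1)
    expect_equal(unname(out3$reached), c(TRUE, FALSE))
  }
})

test_that("multi-goal states are reached independently", {
  env <- multi_goal_env(n_trials = 6000, drift_sd = 0,
                        goals = rep("seek_reward", 6000), seed = 6)
  env$probs[1, ] <- c(0.6, 0.3)
  set.seed(7)
  both <- logical(6000)
  for (i in seq_len(6000)) {
    out <- step_multigoal(env, 1)
    both[i] <- all(out$reached)
    env <- out$env
  }
  expect_equal(mean(both), 0.6 * 0.3, tolerance = 0.1)
})

test_that("multi-goal probabilities respect bounds and goal labels are validated", {
  env <- multi_goal_env(n_trials = 300, drift_sd = 0.1, seed = 8)
  set.seed(9)
  for (i in 1:300) {
    env <- step_multigoal(env, sample(1:2, 1))$env
    expect_true(all(env$probs >= 0.1 & env$probs <= 0.9))
  }
  expect_error(multi_goal_env(goals = c("seek_reward", "win")), "goal label")
  # balanced default goal sequence
  env2 <- multi_goal_env(n_trials = 180, seed = 10)
  expect_equal(sum(env2$goals == "seek_reward"), 90)
})
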