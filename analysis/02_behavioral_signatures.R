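#!/usr/bin/env Rscript
# Model-agnostic signatures: stay-probability tables for slow vs fast
# transition learners, and the regression of model-basedness on the
# learning rate and model-based weight across a simulated cohort.

suppressPackageStartupMessages(library(stlearn))
dir.create("results", showWarnings = FALSE)
seed <- 2
set.seed(seed)

sim_cohort <- function(params, n_agents = 300, n_trials = 150) {
  do.call(rbind, lapply(seq_len(n_agents), function(i) {
    l <- simulate_twostep_agent(params, "istl", n_trials)
    l$participant_id <- i
    l
  }))
}

slow <- two_step_params(gamma = 0.15, alpha = 0.5, decay = 0.3,
                        beta_mb = 8, beta_mf = 0, beta_2 = 3,
                        stickiness = 0.1)
fast <- replace(slow, 1, 0.9)

tab_slow <- stay_probability_table(sim_cohort(slow))
tab_fast <- stay_probability_table(sim_cohort(fast))
tab_slow$agent <- "slow_learner_mb"
tab_fast$agent <- "fast_learner_mb"
stay <- rbind(tab_slow, tab_fast)
write.csv(stay, "results/stay_probabilities.csv", row.names = FALSE)
message("stay-probability cells (see results/stay_probabilities.csv):")
message(paste(capture.output(print(as.data.frame(stay))), collapse = "\n"))
message("slow learner shows the transition x reward interaction; ",
        "the fast learner shows a reward main effect.")

# model-basedness ~ gamma + beta_mb across an empirical-like cohort
res <- model_basedness_parameter_regression(n_agents = 400, n_trials = 200,
                                            seed = seed)
reg <- res$coefficients
write.csv(reg, "results/model_basedness_regression.csv", row.names = FALSE)
message("model-basedness regression (standardized):")
message(paste(capture.output(print(as.data.frame(reg), digits = 3)),
              collapse = "\n"))
write_manifest("results/model_basedness_regression.csv",
               list(n_agents = 400, n_trials = 200), seed)
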