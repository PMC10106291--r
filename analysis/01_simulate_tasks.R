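#!/usr/bin/env Rscript
# Simulate small synthetic sessions of the three paradigms and write the
# trial logs that later steps consume.

suppressPackageStartupMessages(library(stlearn))
dir.create("results", showWarnings = FALSE)
seed <- 1

# one-step revaluation: one practice and five experimental blocks
sched <- one_step_schedule()
blocks <- lapply(1:5, function(b) {
  blk <- simulate_one_step_block(sched, seed = seed + b)
  cbind(block = b, blk$learning)
})
onestep <- do.call(rbind, blocks)
onestep$participant_id <- "demo"
write_trial_log(onestep[, c("participant_id", "block", "trial", "action",
                            "state", "condition")],
                "results/onestep_demo.csv", "onestep")
write_manifest("results/onestep_demo.csv", list(n_blocks = 5), seed)

# two-step task: 20 incremental-learner agents
parts <- generate_cohort(cohort_spec(n = 20, seed = seed))$participants
twostep <- generate_study_behavior(parts, "twostep", n_trials = 200,
                                   seed = seed)
write_trial_log(twostep, "results/twostep_demo.csv", "twostep")
write_manifest("results/twostep_demo.csv",
               list(n = 20, n_trials = 200, model = "istl"), seed)
message("two-step: ", length(unique(twostep$participant_id)),
        " agents, mean reward rate ", round(mean(twostep$reward), 3),
        ", common-transition share ", round(mean(twostep$common), 3))

# multi-goal pursuit: 20 integrated-model agents
mg_parts <- generate_cohort(
  cohort_spec(n = 20, model = multigoal_model(), seed = seed))$participants
multigoal <- generate_study_behavior(mg_parts, "multigoal",
                                     model = multigoal_model(),
                                     n_trials = 180, seed = seed)
write_trial_log(multigoal, "results/multigoal_demo.csv", "multigoal")
write_manifest("results/multigoal_demo.csv",
               list(n = 20, n_trials = 180), seed)
message("multi-goal: mean points per session ",
        round(sum(multigoal$points) / 20, 2))
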