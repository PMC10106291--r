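#!/usr/bin/env Rscript
# Hierarchical fitting by iterative importance sampling: a desk-scale
# parameter-recovery study plus the model-based-weight threshold search
# for learning-rate recoverability.

suppressPackageStartupMessages(library(stlearn))
dir.create("results", showWarnings = FALSE)
seed <- 3

model <- twostep_model("istl")
rec <- suppressWarnings(recover_parameters(
  model, n_subjects = 100, n_trials = 200,
  config = iis_config(K = 6000, max_iter = 25, seed = seed),
  seed = seed + 1))

write.csv(rec$correlations, "results/parameter_recovery.csv",
          row.names = FALSE)
write.csv(rec$estimates, "results/recovered_estimates.csv",
          row.names = FALSE)
write_manifest("results/parameter_recovery.csv",
               list(n_subjects = 100, n_trials = 200, K = 6000), seed)
message("recovery correlations:")
message(paste(capture.output(print(rec$correlations)), collapse = "\n"))

search <- beta_mb_threshold_search(rec$true, rec$estimates)
write.csv(search, "results/beta_mb_threshold_search.csv",
          row.names = FALSE)
message("learning-rate recoverability by model-based-weight threshold ",
        "(best at ", attr(search, "best"), "):")
message(paste(capture.output(print(as.data.frame(search))),
              collapse = "\n"))
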