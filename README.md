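# stlearn

Computational machinery for studying **state-transition learning**: how
people learn the probabilistic map P(state | action) of their
environment, how fast they should learn it, and how the rate of learning
relates to traits such as compulsivity. The package is aimed at
computational-psychiatry and decision-neuroscience researchers who work
with sequential decision tasks (two-step-style paradigms) and
transdiagnostic questionnaire batteries.

## What it implements

**Tasks** (generative simulators with exposed schedules):

- a one-step revaluation task — forced-choice learning of action→state
  frequencies (common 5/10, uncommon 3/10, shared rare 2/10 per block;
  practice 16/20) followed by a no-feedback test phase, scored by the
  both-queries rule with chance level 5 × (1/2)² = 1.25 blocks;
- the two-step task — stable 0.7/0.3 first-stage transitions, drifting
  second-stage reward probabilities;
- a multi-goal pursuit task — independently drifting P(state | action)
  for a reward and a punishment state, with per-trial instructed goals.

**Agents.** An incremental state-transition learner (ISTL) that updates
P(s | a) by a state prediction error with learning rate γ (untaken
actions decay toward the 0.5 prior), and a counting ("Typical") learner
that infers one of two candidate transition matrices from a transition
tally — both embedded in the hybrid chooser

> P(a) ∝ exp( β_MB · Q_MB(a) + β_MF · Q_MF(a) + π_stick · 1[a = a_prev] ),
> Q_MB(a) = Σ_s P(s | a) · max_a′ Q2(s, a′),

with value learning rate α (chosen-value decay 1 − α) and unchosen-value
decay D. For multi-goal pursuit, a four-strategy integrated model
(goal-conditioned model-based values, goal perseveration, model-free
values, action perseveration) in one weighted softmax.

**Fitting.** Hierarchical fitting by iterative importance sampling:
draw parameters from a group prior, weight by session likelihood, refit
the prior by weighted moment matching, iterate to maximize total model
evidence; model comparison by log Bayes factor; parameter- and
model-recovery studies. Likelihoods are compiled (Rcpp).

**Metrics and inference.** The model-agnostic model-basedness score
(compliance with switch-after-rare-reward / stay-after-rare-no-reward),
stay-probability tables, standardized trait regressions, the
three-regression mediation test, and reward-optimality sweeps over γ.
For questionnaire inference: hierarchical Bayesian logistic regression
(JAGS) with sum-to-zero rescaling and ROPE/HDI decisions, plus EFA with
promax rotation, parallel analysis, Bartlett and KMO statistics.

**Synthetic cohorts.** `generate_cohort()` plants a known 3-factor
structure in Likert items and couples traits to model parameters on
logit/log scales, so every pipeline stage can be validated against
ground truth.

## Worked example

A fast transition learner looks less "model-based" even with fully
intact model-based control:

```r
library(stlearn)

base <- two_step_params(gamma = 0.15, alpha = 0.5, decay = 0.3,
                        beta_mb = 5, beta_mf = 1, beta_2 = 3,
                        stickiness = 0.2)
sim_mb <- function(params, seed) {
  set.seed(seed)
  mean(vapply(1:50, function(i)
    model_basedness(simulate_twostep_agent(params, "istl", 200)),
    numeric(1)))
}
sim_mb(base, 1)                    # slow learner:  0.462
sim_mb(replace(base, 1, 0.9), 1)   # fast learner:  0.337
```

Both agents have β_MB = 5; only γ differs. Across a 400-agent cohort
varying γ and β_MB (other parameters fixed),
`model_basedness_parameter_regression()` gives standardized
coefficients γ = −0.30 (p = 4.7e−10) and β_MB = +0.22 (p = 2.6e−06):
the compliance metric falls with the learning rate and rises with the
model-based weight, so fast transition learning mimics reduced
model-based control.

The stay-probability pattern behind this (300 agents, β_MF = 0): the
slow learner shows the transition × reward interaction
(stay 0.73 / 0.54 / 0.47 / 0.56 for common-rewarded / common-unrewarded
/ rare-rewarded / rare-unrewarded), while the fast learner shows a
reward main effect (0.85 / 0.55 / 0.76 / 0.43) — the canonical
"reduced model-basedness" signature.

## Analysis workflow

The numbered scripts under `analysis/` run the full set of analyses at
desk scale and write tables under `results/` (each with a JSON
manifest):

1. `01_simulate_tasks.R` — synthetic sessions of all three tasks;
2. `02_behavioral_signatures.R` — stay tables and the model-basedness
   regression;
3. `03_fit_and_recover.R` — hierarchical fitting and parameter
   recovery, with the model-based-weight threshold search;
4. `04_model_comparison.R` — model recovery (log Bayes factors in both
   directions);
5. `05_optimality_sweeps.R` — reward curves over γ for the stable and
   changing tasks;
6. `06_study1_pipeline.R` — items → EFA → parallel analysis →
   hierarchical logistic regression with ROPE decisions → mediation.

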