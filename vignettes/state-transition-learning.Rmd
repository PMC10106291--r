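---
title: "Modeling state-transition learning: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling state-transition learning: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

People build probabilistic maps of how their actions move them between
states of the world. This package implements the computational machinery
for studying *how fast* such state-transition maps are learned, and how
that rate relates to traits such as compulsivity: three task simulators,
the decision models that play them, hierarchical fitting and model
comparison, model-agnostic behavioral signatures, Bayesian trait
inference, and a synthetic-cohort generator that plants known ground
truth under every analysis.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers that call the package
functions and write tables under `results/`; all computation lives in
the package so that tests and the acceptance script exercise exactly the
same code.

## Tasks

**One-step revaluation.** Two actions each lead to one of three states
with fixed frequencies per block of 10 forced choices per action: common
5/10, uncommon 3/10, and a rare state 2/10 shared by both actions (the
practice block uses 16/20 and 2/20). Because the frequencies are task
facts rather than sampling probabilities, `simulate_one_step_block()`
realizes them as exact count permutations: every seed produces the same
outcome multiset per action, differing only in order. The test phase
asks, for each outcome state, which action produced it most often; the
rare-state query has no correct answer and is unscored, so a block is
learned iff both scored queries are answered optimally. Under random
responding the expected number of fully-correct blocks is 5 × (1/2)² =
1.25.

**Two-step task.** Stable first-stage transitions (common probability
0.7) and second-stage reward probabilities drifting by Gaussian random
walks (s.d. 0.025) reflected at [0.25, 0.75], 200 trials — the
paradigm's standard configuration, which we adopt as defaults because
the rate-of-learning question is about this exact environment.

**Multi-goal pursuit.** Two actions, a reward state and a punishment
state reached *independently* — both, one, or neither can occur — with
all four P(state | action) drifting by independent reflected random
walks. Each trial instructs a goal: seek reward (+1 if the reward state
is reached) or avoid punishment (−1 if the punishment state is reached);
reaching an uninstructed state has no consequence. The source study
defers the walk parameters to a companion paper, so the defaults here —
step s.d. 0.04, bounds [0.1, 0.9], 180 trials, balanced randomized goal
order — are this package's own choices, sized so transitions change
appreciably within a session while staying learnable. They are flagged
as assumptions and fully configurable.

## Decision models

**Incremental state-transition learner (ISTL).** The belief P(s | a)
starts at 0.5 and moves toward each observed outcome by a state
prediction error scaled by the learning rate γ; on the two-step task the
complement is set so each action's row sums to 1, and the untaken
action's belief decays toward the 0.5 prior. The decay rate toward 0.5
is taken to equal γ (the source describes the decay but not its rate;
this is configurable). In the multi-goal variant the reward- and
punishment-state probabilities are free in [0, 1] and update
independently; whether the untaken action also decays toward 0.5 is
configurable and on by default.

**Typical (counting) learner.** A running tally of observed transitions;
whichever of the two candidate 0.7/0.3 matrices is supported by the
diagonal-vs-off-diagonal count comparison is adopted wholesale, with the
element-wise average (all 0.5) on ties.

**Hybrid two-step chooser.** Q_MB(a) = Σ_s P(s|a) max_a′ Q2(s, a′);
the first-stage policy is softmax over β_MB·Q_MB + β_MF·Q_MF +
π_stick·1[a = previous action], the second-stage policy softmax over
β_2·Q2. Model-free values decay by 1 − α when chosen (the learning-rate
complement) and by a separate rate D when unchosen, toward 0. Credit
assignment gives the second-stage reward directly to the first-stage
chosen value (eligibility λ = 1, not exposed as a parameter). Q2 starts
at 0; beliefs at 0.5. Stickiness is the paradigm's standard nuisance
parameter and can be disabled.

**Four-strategy multi-goal model.** Model-based values multiply the
transition estimate by the instructed-goal vector — (1, 0) on
seek-reward trials, (0, −1) on avoid-punishment trials — so only the
goal-relevant state is valued. Goal perseveration uses the fixed vector
(1, −1) regardless of instruction; a model-free value tracks points per
action (learning rate α_MF, a free parameter); action perseveration is a
stay bias. The weighted sum of the four strategies feeds one softmax;
softmax temperature is absorbed into the β weights (the source renders
its policy equations as images, so the temperature convention is our
choice and is flagged).

All softmaxes subtract the maximum before exponentiating; ties are
resolved by the resulting equal probabilities, never by an argmax.

## Hierarchical fitting by iterative importance sampling

`iis_fit()` alternates: draw K parameter vectors from the group prior;
weight each subject's draws by the session likelihood; score subject
evidence as the log mean likelihood; estimate subjects by
importance-weighted posterior means; refit the group prior by weighted
moment matching (Beta via mean/variance, Gamma via shape/scale, Normal
directly). Iteration stops when total log evidence improves by less
than the tolerance. Model comparison is the difference in total log
evidence (a log Bayes factor).

Numerical choices: starting priors are naive — Beta(1, 1) for rates,
Normal(0, 10) for signed weights, and Gamma(shape 1, scale 5) for
non-negative weights (an exponential with mean 5, so the first iteration
already covers the range where softmax weights plausibly live); the
iterative refit makes the converged result largely insensitive to them.
Weights are exponentiated after subtracting the per-subject maximum;
Beta-variance refits are capped below the mean(1−mean) bound; variances
are floored at 10⁻⁶. When the median per-subject effective sample size
falls below a threshold (default 25) the sample size is doubled, up to a
cap, with a warning. Defaults (K = 5,000, ≤ 30 iterations, 0.5-nat
tolerance) are sized for desk-scale runs; the source does not state its
fitter's internal settings, so these are package choices. Subject point
estimates are posterior means (the source says only "best-fitting
parameters"; the mean is the stabler choice under importance sampling).

Likelihoods are implemented in C++ (vectorized over parameter draws), as
is usual for per-trial reinforcement-learning likelihoods; all random
number generation goes through R's generator, so a single `set.seed`
governs every result.

## Recovery studies and their limits

`recover_parameters()` draws agents from a *moderate* generating prior —
Beta(2, 2) for the three rates, Gamma(2, scale 2) for the model-based
weight, Gamma(3, 1) for the second-stage temperature, Normal(1.5, 0.75)
and Normal(0.2, 0.5) for the model-free weight and stickiness — chosen
once as representative of the two-step literature. At 200 agents × 200
trials, six of the seven parameters recover with r ≈ 0.7–0.9. The
transition learning rate is different in kind: when an agent's
model-based weight is small, its choices carry almost no information
about γ. A profile-likelihood experiment (all other parameters fixed at
truth) puts the full-sample ceiling near r ≈ 0.35 under these
conditions, rising to ≈ 0.6 among agents with β_MB > 2.5; the
hierarchical posterior mean reaches ≈ 0.46 full-sample by pooling. This
is why `beta_mb_threshold_search()` exists: γ-recovery is meaningfully
assessed only on the high-β_MB subsample, and analyses that regress
traits on γ should do likewise. We report the full-sample minimum
correlation honestly rather than restricting the sample to flatter it.

## Behavioral signatures

`model_basedness()` is the compliance proportion after rare transitions
(switch after reward, stay after no reward); `stay_probability_table()`
gives the four-cell stay pattern. Two facts worth noting. First, a pure
model-free agent is not at chance on the compliance metric — the reward
main effect drives it *below* 0.5. Second, a fast transition learner
with *no* model-free system reproduces the reduced-model-basedness
pattern (reward main effect): after a rare transition a high-γ belief
flips to treat the rare state as common, so a rewarded rare outcome
makes the agent stay. The package's simulations reproduce both, and the
cohort-level regression of model-basedness on (γ, β_MB) gives a negative
γ and positive β_MB coefficient.

`optimality_sweep()` plays the task across a γ grid with other
parameters fixed — the model-based weight at the 97.5th percentile of
its generating distribution (approximating an extreme-but-plausible
value from a skewed distribution; the |z-skewness| > 4 rule decides
median-vs-mean fixing for the rest) — and min-max normalizes mean
reward. Stable transitions put the optimum at low γ with γ = 1 clearly
suboptimal; drifting multi-goal transitions put it near γ ≈ 0.2 with
γ = 0.05 clearly suboptimal. Reward differences in the stable task are
intrinsically tiny (fractions of a reward over 200 trials), which is why
sweeps default to 20,000 plays per grid point and a refined grid around
the argmax.

## Trait inference

The hierarchical logistic model predicts per-(participant, block)
revaluation correctness from a grand-mean intercept (Normal(0.6, 1)
prior), participant and condition random effects (s.d. hyperpriors
Uniform(0, 3) each — the source is partly ambiguous on whether both
families share this bound, and we give it to both), and fixed trait
effects (Normal(0, 3)). Sampling uses JAGS with 4 chains × 1,000
post-warmup draws by default; target-acceptance 0.9 and tree depth 18
are recorded for samplers that expose them. Convergence is checked
against r-hat < 1.1 and ESS > 1,000 and *flagged*, never silently
accepted. Categorical coefficient draws are rescaled to sum to zero
(means moved into the intercept, leaving all linear predictors
unchanged) before summarization. Decisions compare the 95% highest
density interval (narrowest interval on sorted draws) against a region
of practical equivalence of ±0.01 — 10% of the baseline-effect posterior
s.d. in the task this model was built for, recomputable from the fit.

EFA uses maximum-likelihood extraction with promax rotation and
regression-method scores (the source is silent on the scoring method);
items are standardized first. Parallel analysis compares observed
eigenvalues against the 95th percentile of column-permuted nulls.
Bartlett sphericity, KMO and Tucker congruence are computed from their
closed forms.

## The synthetic-data generator

`generate_cohort()` draws correlated latent factors, Likert items with a
planted loading structure (Gaussian items cut at equal-mass thresholds),
covariates, and model parameters coupled to traits *on transformed
scales* — logit for rates, log for non-negative weights — so that
native-scale constraints can never be violated by a coupling. Planted
slopes use the source's reported effect sizes as plausible templates
(e.g. +0.15 standardized for compulsivity→γ in the stable task). The
one-step behavior generator plants log-odds effects directly in a
logistic ground-truth model, which is what the inference recovery tests
exercise; end-to-end tests that first estimate factor scores from items
necessarily see attenuated effects, which is a property of measurement,
not of the sampler.

What the generator does *not* emulate: real questionnaire psychometrics
beyond the planted factor structure, attention lapses and response
biases, within-session non-stationarity of parameters, and any
relationship between covariates and traits. Passing tests therefore
demonstrate that the pipeline recovers what it assumes, not that the
assumptions hold of real participants.

## Problem sizes

Tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is stable: recovery at 200 agents
× 200 trials (importance samples K = 8,000, escalating on degeneracy),
model recovery at 100 agents per direction (K = 3,000), signature
cohorts of 300–400 agents, sweeps at 20,000 plays per grid point, the
hierarchical logistic at n = 174 × 5 blocks with 20 replicates per
calibration arm, and EFA at n = 1,000.

## Known limitations

- γ recovery at moderate model-based weights is information-limited (see
  above); the full-sample minimum recovery correlation can fall below
  0.5 even when the fitter is working exactly as intended.
- Subject evidence is the marginal likelihood under the *converged group
  prior*, as in the empirical-Bayes tradition; it is not a fully
  Bayesian marginal over hyperparameters.
- The JAGS sampler mixes the intercept/random-effect trade-off slowly at
  small chain lengths; the intercept's r-hat is the usual flag, and the
  trait effects of interest mix well before it does.
- The multi-goal walk parameters and the Study-3 model-free learning
  rate are package choices where the source defers to companion work.
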