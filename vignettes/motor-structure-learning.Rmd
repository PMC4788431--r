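---
title: "Motor constraints on hierarchical rule creation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor constraints on hierarchical rule creation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorstruct)
```

## The problem

In a two-dimensional stimulus-action task, every trial shows a stimulus
with a color feature and a shape feature (two levels each, four stimuli),
and one of four fingers (F1--F4, ordered left to right) is the correct
response. Learners tend to impose a *hierarchical* reading on such tasks:
one dimension is treated as a context that cues an abstract task-set, and
the other as the stimulus acted on within that task-set. Nothing in the
contingencies forces either reading -- color-as-context and
shape-as-context fit the data equally well -- yet which one a learner
creates has measurable consequences (switch costs, transfer).

This package implements the computational machinery for studying one
specific hypothesis about what breaks the tie: *motor adjacency*. If a
task-set's two required key presses sit on physically adjacent fingers,
preparing that task-set can facilitate both presses at once. A structure
whose task-sets cluster motor actions is then favored, not because it pays
off behaviorally, but because outcome predictions that spread to
neighboring fingers happen to be more accurate under it.

## Task combinatorics

A contingency assignment is a bijection from the four stimuli to the four
fingers. Each assignment admits two *structure views* (color or shape as
context), each inducing two task-sets of two stimuli each. Per view we
score:

* the **adjacency bonus** `a`: the number of task-sets whose two fingers
  are adjacent (positions differing by exactly 1), so `a` is 0, 1 or 2;
* the **symmetry bonus** `s`: 1 if both task-sets order the two
  stimulus-dimension features the same way left-to-right, else 0.

The two views of one assignment never induce the same finger partition,
and their adjacency bonuses always form one of the unordered pairs
\{2,0\}, \{1,0\} or \{2,1\}. Counting assignment-plus-view patterns up to
permuting the two colors, permuting the two shapes, and exchanging the
roles of the dimensions (a group of order 8 acting freely on the 48
views), exactly six classes remain, in sibling pairs:

```{r classes}
enumerate_pattern_classes()$classes[, c("class", "a", "a_sibling", "s")]
```

P1/P3 are the higher-adjacency views of their pairs. Note the P5/P6 pair:
P5 has the higher adjacency bonus (2 vs 1) but P6 is the symmetric view,
so the two natural-bias scores `a + s` tie at 2. This is why that pair is
excluded from the headline contrasts -- adjacency and symmetry pull in
opposite directions there, and predictions depend on how the two biases
are weighted.

Trial sequences are pseudo-randomized with exact stimulus balance and
first-order transition counts equal within one occurrence. The generator
builds a directed multigraph over the four stimuli with near-equal edge
multiplicities consistent with the required visit counts, then draws a
randomized Eulerian path. This guarantees the balance property by
construction rather than by rejection sampling on full sequences;
unsatisfiable settings (blocks shorter than 16 trials or not divisible by
4) are rejected with an error. With `no_repeats = TRUE` the diagonal is
removed and the 12 non-repeat transitions are balanced, as in instructed
task-switching blocks.

## The structure-learning agent

The agent holds two *experts*, one per candidate structure. Each expert:

* clusters its context features into latent task-sets `Z` with a Chinese
  Restaurant Process prior: a novel context joins an existing task-set
  with probability proportional to that task-set's popularity (its summed
  posterior probability across known contexts) or opens a new one with
  probability proportional to the concentration `alpha`;
* infers `Z` for the current context by maximum a posteriori (ties to the
  lowest id), and learns `p(r = 1 | S, a, Z)` by beta counting with a
  `Beta(1, 1)` prior, so the neutral prediction before data is 0.5;
* acts through a noisy softmax on expected outcome,
  `pi = (1 - epsilon) * softmax(beta * q) + epsilon / 4`.

The agent's choice is sampled from the reliability-weighted mixture
`w_C * pi_color + (1 - w_C) * pi_shape`, with `w_C` initialized at 0.5 and
updated by Bayes rule from each expert's probability of the realized
outcome. By default that likelihood marginalizes over the expert's task-set
posterior for the current context rather than conditioning on the MAP
task-set: expert reliability is a structure-level quantity, and the
marginal likelihood is what Bayes rule actually prescribes for comparing
structures. The MAP-conditioned variant is available as
`agent_params(map_likelihood = TRUE)`. Likelihoods are floored at `1e-6`
so a single zero-probability outcome cannot create an absorbing state.

Default parameters are `beta = 30`, `alpha = 2`, `epsilon = 0.1`,
`f = 0.1`. With four actions the lapse bounds asymptotic accuracy at
`1 - 0.75 * epsilon = 0.925` once contingencies are learned.

### Motor biases

The **adjacency bias** spreads the expert's policy for the task-set's
*other* stimulus onto neighboring fingers through the kernel
F1→\{F2\}, F2→\{F1, F3\}, F3→\{F2, F4\}, F4→\{F3\}, each row normalized
by its neighbor count. The **symmetry bias** distributes mass over finger
positions in proportion to how many fully symmetric assignment
completions are consistent with what the expert has learned so far (cells
with at least one recorded success count as known; the other task-set is
the MAP task-set of the expert's other context); it is uniform when
nothing constrains the completion. Whenever exactly one cell of the other
task-set is known, three completions survive and the bias mass lands in
thirds -- the characteristic 1/3 vs 2/3 split between candidate positions.

Enabled biases are mixed evenly, then folded into predictions with weight
`f`: `p_hat = (1 - f) * p_beta + f * bias`. The `routing` parameter
decides where `p_hat` acts:

* `"policy_only"`: biased values drive choice, but the predictions used
  for posterior and reliability updates stay unbiased;
* `"prediction_and_policy"`: biased predictions also enter the Bayes
  updates -- this is the full model;
* `"none"`: no biases anywhere.

The biases apply on every trial by default (`bias_scope = "always"`); the
reading under which they act only on stimulus cells without observed
outcomes is available as `"unseen_only"`. A `credit_spread` variant
instead deposits fractional beta counts on neighboring actions of the
task-set's other stimulus at learning time (weight `g = f` by default,
split equally among neighbors, a value chosen here since none is
prescribed); it implements the alternative mechanism in which motor
overlap corrupts credit assignment rather than prediction.

### Why the routing matters

Under `policy_only` the biases change which fingers are pressed but not
how well either expert predicts outcomes, so `w_C` stays at 0.5 on
average for every configuration -- the null result. Under
`prediction_and_policy` the expert whose task-sets cluster adjacent
fingers genuinely predicts outcomes better (its spread-out predictions
are right more often), so `w_C` moves toward the higher-adjacency view:

```{r sweep, eval = FALSE}
sw <- run_sweep(n_runs = 1000, n_trials = 80, base_seed = 1)
sw$summary
```

At full scale (1000 simulated 80-trial blocks per configuration, the
scale used by the test suite) the policy-only grand mean of `w_C` is 0.5
within Monte-Carlo error, while prediction routing yields mean `w_C`
around 0.94 for P1, 0.06 for P2, 0.73 for P3 and 0.27 for P4 -- the
mirror-symmetric preference for the higher-adjacency view. Sweeps
counterbalance by cycling the four color-as-context representatives of
each class across runs, and `summarize_preferences()` converts run-level
weights into the fraction of blocks favoring the higher-adjacency
structure (ties at exactly 0.5 broken by a fair coin).

## Switch-cost analysis

Behaviorally, the created structure is identified from reaction times:
switching the context feature of the *created* structure costs more time
than switching its stimulus feature. The pipeline is:

1. **Transition labelling** of consecutive trials within a block (color
   switch, shape switch, full repeat, finger repetition, finger
   distance).
2. **Asymptotic filtering**: keep correct trials in the second half of
   the block, at or after the start of the first run of at least 8
   consecutive correct trials. The streak criterion marks learning
   attained; taking the *first* qualifying run means sporadic
   post-asymptotic lapses do not shrink the analysis window (taking the
   last run instead is available via
   `asymptote_policy(criterion = "last")`, but with realistic ~0.95
   asymptotic accuracy it often leaves fewer than 15 usable trials and
   renders half the blocks indeterminate). Blocks that never reach the
   criterion contribute no trials and end up labeled indeterminate.
3. **Corrected switch costs**: an additive model of log RT on both
   dimensions' switch flags, a finger-repetition flag and the absolute
   finger distance, with the queried effect back-transformed to ms at the
   sample mean of the covariates. Log RT reflects the multiplicative
   character of RT noise; the motor covariates absorb sequential
   finger-repetition effects that would otherwise masquerade as switch
   costs. Full-repeat trials are excluded, constant covariates are
   dropped, and if a switch flag is itself collinear the estimator falls
   back to the raw mean RT difference (which is exactly shift- and
   scale-equivariant). Fewer than 5 trials in either cell yields `NA`.
4. **Contrasts**: the *motor-clustering switch cost* is the switch cost
   of the higher-adjacency view's dimension minus the lower-adjacency
   view's; its sign labels the block. The *instructed switch cost*
   (instructed minus other dimension) is negative when a subject
   restructured an instructed task toward the motor-clustering view.
   P5/P6 blocks are rejected, mirroring their exclusion from the
   contrasts.
5. **Group statistics**: block values are averaged within subject and
   configuration type before a one-sample t test, and block labels are
   counted against a fair coin with an exact two-sided binomial test
   (both delegated to the standard stats implementations). Whether group
   tests run on ms or log-RT differences is not settled; ms is used so
   the values stay in the units in which effects are reported.

## Synthetic behavior

Because no trial-level human data ship with the package, a generator
produces cohorts with exactly the statistical structure the analysis
assumes: a logistic learning curve rising from chance (0.25) to an
asymptote of 0.95 around trial 10 (rate 0.2/trial); log-normal baseline
RTs (median 600 ms, sdlog 0.2, ~120 ms spread); an additive context-switch
cost (default 80 ms) on the *created* view's dimension plus a smaller
stimulus-switch cost (30 ms); a 20 ms finger-repetition speed-up; RTs
truncated at 150 ms. Each block's created view is the higher-adjacency
one with probability `q` (default 2/3, the empirical rate motivating the
binomial analyses). Choices can alternatively come from the structure
agent itself, so the analysis tests do not depend on the parametric
learning curve.

Block length defaults to 400 trials. This is a power choice for pipeline
validation, not an emulation of any experiment: the identifying signal
per block is the 50 ms difference between the context and stimulus switch
costs against ~120 ms noise, and 400 trials leave roughly 120 filtered
regression trials -- the regime in which the planted label is comfortably
recoverable (~97% of blocks). At the 80-trial scale of real learning
blocks the same pipeline labels blocks at only ~80% accuracy; that is a
statement about single-block identifiability at that length, and real
analyses compensate by aggregating across blocks and subjects.

What passing these tests shows -- and what it does not: the generator
draws i.i.d. log-normal RTs with purely additive effects and no drift,
fatigue, post-error slowing, or subject-level heterogeneity beyond the
planted structure. Recovery on this synthetic cohort validates the
estimator's logic (labelling, windowing, covariate correction,
aggregation), not its robustness to every real-data pathology.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; all distribution outputs are
  validated to sum to 1 within `1e-12` in the test suite.
* MAP ties break toward the lowest task-set id; preference ties at
  `w = 0.5` break by a seeded fair coin.
* Mixture likelihoods are floored at `1e-6`; beta counts may be
  fractional under credit spreading.
* Sequence generation requires `n >= 16` divisible by 4 and errors
  otherwise; all-error blocks filter to an empty set with a warning and
  an indeterminate downstream label.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state, so identical configurations give byte-identical outputs.

## Known limitations

* The symmetry bias is specified only loosely by its source; the
  completion-counting rule implemented here reproduces the characteristic
  1/3 vs 2/3 priors, but other rules could too. It is off the headline
  path (P1--P4 results are unchanged without it).
* Model parameters are fixed, not fit; the package simulates and analyzes
  but does not estimate the agent's parameters from data.
* The formulas are written for 2 features per dimension and 4 actions
  (the studied task family); the expert container generalizes the CRP
  machinery to more contexts, but the bias kernels assume 4 ordered
  fingers.
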