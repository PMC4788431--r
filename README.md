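# motorstruct

Tools for studying how low-level motor constraints bias which hierarchical
rule structure a learner creates.

## The problem

In two-dimensional stimulus–action tasks (four colored shapes, four
response fingers F1–F4 ordered left to right), people spontaneously impose
a hierarchy: one feature dimension becomes a *context* cueing an abstract
task-set, the other a *stimulus* acted on within it. Color-as-context and
shape-as-context explain the contingencies equally well — so what breaks
the tie? One candidate is motor adjacency: a task-set whose two required
key presses sit on adjacent fingers can be prepared as a unit. The package
implements

* the **task combinatorics**: finger assignments scored by the adjacency
  bonus *a* (number of task-sets on adjacent finger pairs, 0–2) and the
  left-right symmetry bonus *s* (0/1); the six pattern classes
  P1–P6 that remain after counterbalancing (sibling pairs (P1,P2), (P3,P4),
  (P5,P6), where P1/P3/P5 are the higher-adjacency views); and balanced
  trial sequences with equal first-order transition frequencies;
* the **structure-learning agent**: two experts (one per candidate
  structure), each with Chinese Restaurant Process context clustering
  (concentration α), beta-count outcome learning p(r = 1 | S, a, Z), and a
  noisy softmax policy π = (1 − ε)·softmax(β·q) + ε/4; actions sampled
  from the reliability-weighted mixture w_C·π_C + (1 − w_C)·π_S with a
  Bayesian update of w_C from each expert's outcome likelihood; motor
  adjacency and symmetry biases mixed into predictions with weight *f*
  and routed either to the policy only or to policy and prediction;
* the **simulation sweeps** contrasting bias routings over P1–P4
  (defaults β = 30, α = 2, ε = 0.1, f = 0.1, 1000 runs × 80 trials);
* the **switch-cost pipeline** for trial-level data: transition labelling,
  asymptotic filtering, log-RT switch costs corrected for sequential motor
  effects, the motor-clustering contrast SwC(high-adjacency dim) −
  SwC(low-adjacency dim) whose sign labels the created structure, the
  instructed contrast, and the two-level group statistics (one-sample t,
  exact binomial);
* a **synthetic-behavior generator** planting known structure labels,
  learning curves, and RT effects so the whole pipeline is testable
  without human data.

## Worked example

```r
library(motorstruct)

# 1. the combinatorics: six pattern classes
enumerate_pattern_classes()
#> <motor pattern classes> 6 classes over 48 views
#> # A tibble: 6 × 4
#>   class     a a_sibling n_views
#>   <chr> <int>     <int>   <int>
#> 1 P1        2         0       8
#> 2 P2        0         2       8
#> 3 P3        1         0       8
#> 4 P4        0         1       8
#> 5 P5        2         1       8
#> 6 P6        1         2       8

# 2. one simulated learning block of the full model on a P1 assignment
view <- class_representatives("P1")[[1]]
sq <- generate_trial_sequence(80, seed = 1)
run_block(agent_params(), view, sq, seed = 4)
#> <block run> 80 trials, accuracy 0.89, final w_C = 0.959

# 3. printed-count group statistics
exact_binomial_test(66, 99)   # 0.001185 -> 0.0012
exact_binomial_test(61, 92)   # 0.002315 -> 0.0023

# 4. a synthetic cohort through the full analysis pipeline
co <- generate_cohort(seed = 5)
cohort_report(co$trials, co$metadata)
#> <cohort report> 99 blocks, 99 labeled
#>   mean motor-clustering switch cost: 18.3 ms
#>   group t(39) = 3.32, p = 0.001954
#>   high-adjacency labels: 62 / 99 (binomial p = 0.01543)
```

The block run shows the agent learning the contingencies (accuracy
approaches the lapse-limited ceiling of 0.925) while its mixture weight
moves toward the color structure — the higher-adjacency view of a P1
assignment. The cohort report recovers the planted 2/3 population bias:
62 of 99 blocks labeled high-adjacency, significant against a fair coin.

A mean final w_C above 0.5 in `run_sweep()` output means the model prefers
the color structure; under prediction routing the preference lands on
whichever view has the higher adjacency bonus, while the policy-only model
stays at 0.5 (see the vignette for the mechanism).

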