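---
title: "Active-inference models of anticipation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-inference models of anticipation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(anticipatr)
```

## The modelling problem

In striking sports a performer must commit to an interceptive action before
the ball's trajectory is fully resolved: a batter facing a pitcher who throws
either a *normal* delivery or a *change-up* has to weigh what they know about
this opponent (contextual priors: "80% of deliveries are normal") against
early kinematic cues (sensory evidence of limited reliability), and decide
*when* to commit — early, for a well-prepared but riskier action, or late,
after more information has arrived but with less time to execute.

`anticipatr` implements this situation as a family of discrete-state partially
observable Markov decision processes solved by active inference. Perception
and action both minimise free energy: state inference minimises variational
free energy given the observations so far, and action selection minimises the
*expected* free energy G of each candidate policy, which trades pragmatic
value (reaching preferred, rewarded outcomes) against epistemic value
(observations that resolve uncertainty).

## The generative models

Both within-trial scenarios factor the hidden state into a **context** factor
(`normal` / `changeup`, the ball type; identity dynamics, so the ball is fixed
within a trial) and a controllable **behavioural stage** factor. Three
timepooints structure every trial: the start state, the cue, and the outcome.

* **Simple scenario** (`build_simple_model()`): stages `start`, `observing`,
  `committed_normal`, `committed_changeup`; two policies, *wait then commit
  normal* and *wait then commit change-up*. The cue modality
  (`null`/`cue_normal`/`cue_changeup`) is informative only in the `observing`
  stage, with the believed reliability encoded in Dirichlet counts; the
  feedback modality (`null`/`correct`/`incorrect`) is emitted only in
  committed stages.
* **Trade-off scenario** (`build_tradeoff_model()`): the stage factor also
  distinguishes early commitments (made before the cue, rewarded `r_early`)
  from late ones (made after the cue, rewarded `r_late < r_early`). Pending
  early commitments pass through an explicit outcome stage so that feedback
  is emitted exactly once per trial through a time-invariant likelihood
  mapping, and the cue is observable only on the wait branch. Four policies:
  early-normal, early-changeup, wait-late-normal, wait-late-changeup.

The model containers follow the standard discrete-state active-inference
notation: `A` (likelihood mappings per modality), `B` (per-action transition
tables), `C` (log-preferences over outcomes; only differences within a
timepoint matter, which the test suite verifies as a shift-invariance
property), `D` (initial-state priors), a policy set with uniform habit
weights by default, and a policy precision `gamma`.

## Inference

Given a policy, the within-trial model is a short chain over the joint
(context x stage) state, so `infer_states()` runs iterated sum-product
(forward/backward) message passing until beliefs change by less than `1e-6`
(cap 64 sweeps). On tree-structured models this fixed point *is* the exact
Bayes posterior, and the suite pins it against a brute-force enumeration of
all joint trajectories across 1000 random parameterisations. We chose this
scheme over mean-field coordinate ascent deliberately: with the identity
context dynamics used here, product-of-marginals updates double-count
near-deterministic transition messages and collapse smoothed marginals toward
deltas, which breaks exactness.

`variational_free_energy()` evaluates the usual accuracy-plus-complexity
functional against one-step-ahead empirical priors; at the converged
posteriors it equals the surprisal bound, and it is zero when every
observation is predicted with certainty.

`expected_free_energy()` accumulates, over the timepoints that still lie in
the future,

* **risk**: KL divergence from the predicted outcome distribution to the
  preference distribution `softmax(C)`,
* **ambiguity**: expected conditional entropy of the likelihood mapping, and
* **novelty** (only when cue learning is enabled): the expected information
  gain about the cue-likelihood Dirichlet counts,

with `G = risk + ambiguity - novelty`. Policies map to actions through
`softmax(ln habits - gamma * G)` followed by marginalisation onto the next
action, which is sampled by default (argmax is available and breaks ties
toward the lowest action index).

### Precision through count magnitude, not expected logs

Beliefs that can be learned are carried as Dirichlet concentration counts
(`dirichlet_beliefs()`): `d_counts` over the context prior and `a_counts`
over the cue likelihood. Within-trial inference uses the *normalized means*
of these counts rather than exponentiated digamma expectations. The digamma
form systematically over-weights low-count sources — `digamma(4) - digamma(1)
= 1.83` exceeds `digamma(40) - digamma(10) = 1.42` even though the ratios are
identical — which would make the *less* precise source dominate a conflict.
With normalized means, equal ratios integrate to an exact tie within a trial,
and precision instead expresses itself across trials through learning speed:
a source with total count mass 5 is revised by a handful of outcomes while a
source with mass 50 is nearly immovable. This is what flips the dominant
action between the two precision-conflict conditions. The digamma expectation
is still exported (`dirichlet_expected_log()`) and drives the novelty term.

Learning itself is a count update after each trial
(`update_dirichlet()`): with context learning on, the trial-start context
posterior (which, after veridical feedback, is concentrated on the true ball)
is added to `d_counts` scaled by `eta`; with cue learning on, the row of
`a_counts` for the observed cue receives the cue-time context posterior. Both
toggles off reproduce a non-learning control observer. Transition (`B`)
learning is not exposed; the scenarios hold their dynamics fixed.

## Environments and study conditions

The generative process (`environment_spec()`) mirrors the model structure
with *true* parameters: per-trial change-up probability (optionally a
block-wise volatility schedule), true cue reliability `rho_true`, congruency
flags (an incongruent cue points at the opposite ball; an incongruent context
gives the agent initial counts favouring the minority ball), and a
deterministic feedback rule. All randomness flows through R's RNG, seeded
once per observer (`base_seed + observer - 1`), so batches are
bit-reproducible.

The condition registry (`make_condition()`, `list_conditions()`) fixes the
study conditions. The notable numerical choices, made once and documented
here:

* **Learning-curve conditions**: true context 80/20 (majority normal), true
  cue reliability 0.8, flat initial beliefs (`d = (1, 1)`, uninformative cue
  counts), 50 observers x 50 trials; the reversal variants flip the context
  to 20/80 at trial 26 of 50.
* **Congruency grid** (50 x 100, both learning channels on): the four cells
  follow the scenario descriptions they simulate. In the cue-incongruent cell
  the observer initially trusts the cue more than the context (believed
  reliability 0.9 against a 4:1 prior), so behaviour starts biased by the
  deceptive cue; in the context-incongruent cell the context is the more
  precise source (prior ratio 4:1 against believed reliability 0.7). A fully
  symmetric design would place prior and likelihood log-odds in an exact tie
  that a single count update breaks, leaving no visible early deficit.
* **Precision conflict** (50 x 50, true context 50/50, cue clamped to
  `cue_changeup`): both conditions share the 4:1 belief ratios; only the
  count magnitudes swap (context mass 40+10 vs 4+1 against cue column mass 50
  vs 5). "Weak" and "strong" mass follow the 5-vs-50 convention used
  throughout.
* **Policy-precision sweep** (trade-off scenario): `gamma` in {16, 4, 2, 1}
  with a confident 4:1 context prior; only the determinism of policy
  selection varies.
* **Reward sweep** (trade-off, true context 80/20, perfectly reliable cue,
  context learning from a `(5, 5)` prior): early rewards {1, 4, 8} with
  `r_late = 0.75 * r_early` and loss 4. The commit-early-versus-wait boundary
  at the first timepoint is analytic here: committing early is preferred when
  `p * (r_early - r_late)` (the pragmatic advantage, `p` the believed
  probability of the majority ball) exceeds the entropy of the predicted cue
  (the epistemic value of waiting, at most `ln 2`). With these values the low
  condition waits at any attainable `p`, the high condition commits early
  from the first trial, and the medium condition starts below the boundary at
  `p = 0.5` and crosses it near `p ~ 0.65`, i.e. around trial 10 of 60 as the
  `(5, 5)` prior absorbs the 80/20 contingencies — the wait-then-switch
  pattern. A weaker `(1, 1)` prior would cross within two trials; a larger
  late reward (e.g. half rather than three quarters of the early reward)
  would push the medium condition past the boundary immediately.
* **Volatility pair**: stable = constant 50/50; volatile = 10-trial blocks
  alternating 80/20 and 20/80, so the scheduled marginals match exactly.

## The hierarchical volatility model

`build_hierarchical_model()` adds an across-trial level: a hidden Markov
model over context *regimes* whose transition table encodes an expectation of
stability (persistence 0.9 by default). Its observations are summaries of
non-overlapping 10-trial windows — the realised change-up fraction,
discretized as `low_changeup` (<= 0.25), `balanced`, or `high_changeup`
(>= 0.75) — while the lower level tracks the marginal change-up probability
with Dirichlet counts trial by trial. Window summarisation is a deliberate
choice: a regime model consuming raw single-trial outcomes assigns blocked
80/20 data a *lower* entropy rate than matched-marginal 50/50 data, so its
total surprisal rewards, rather than penalises, volatility; summarising at
the timescale on which regimes change isolates exactly the structure the
higher level is supposed to explain. The wide thresholds keep ~89% of stable
50/50 windows in the `balanced` category, so the stable order produces little
higher-level surprise while every block switch in the volatile order violates
the stability expectation. Per update the model records its variational free
energy (equal to the surprisal of the summary under the regime-filtered
predictive) and its complexity/accuracy decomposition, which the tests verify
as an identity. Setting `window = 1` recovers a ball-level regime filter,
used in the tests for closed-form convergence checks.

## What the synthetic data does and does not emulate

The generator reproduces the *informational* structure of anticipation
experiments: base-rate context, partially reliable or deceptive cues, reward
asymmetries between early and late commitment, and volatility in trial order.
It does not emulate kinematics, continuous time, motor noise, opponent
adaptation (no agent on the other side of the exchange), fatigue, or
individual differences beyond what the belief parameters express. Passing
simulations therefore show that the *belief and decision dynamics* behave as
the theory predicts under these idealised conditions — not that human
performers implement these computations, and not that effect sizes transfer
to real tasks.

## Numerical choices and degenerate inputs

* Probabilities are floored at `1e-16` inside logarithms; distributions are
  validated to a normalisation tolerance of `1e-10`.
* Belief updating iterates to `1e-6` with a 64-sweep cap; non-convergence
  returns the best iterate with a warning flag (unreachable on these chain
  models, but the contract is kept for safety).
* Argmax ties break toward the lowest policy/action index; sampled selection
  is the default because the simulated observers are meant to show graded
  action probabilities.
* Zero-probability observations raise an error rather than silently flooring.
* Degenerate trade-offs (`r_late >= r_early`) and out-of-range reliabilities
  or persistence values are rejected at construction.
* A single-observer batch reports zero-width confidence intervals and flags
  the result (`ci_degenerate`).

## Problem sizes

The registered conditions use 50 seeded observers with 50–100 trials
(200 for the parameter-recovery check), matching the batch sizes of the
experiments they simulate; the figure-style single-observer traces are
exposed through the `single_trial` battery and the trade-off runners. The
full battery suite plus the exact-inference oracle (1000 randomized models
against brute-force enumeration) completes in a few minutes on one CPU.

## Known limitations

* Policies span a single trial (horizon 3); there is no deep planning across
  trials, and the across-trial hierarchy is a filter, not a planner.
* Only the context prior and cue likelihood are learnable; transition
  learning and habit learning are out of scope.
* The policy posterior omits the per-policy variational free energy term:
  within a trial all still-viable policies share the same past actions and
  observations, so the term is constant and cannot change the posterior; it
  would matter only for policy sets with divergent pasts.
* The hierarchical level is an equivalent-by-behaviour construction
  (regime filter over window summaries), not a full two-level POMDP with
  top-down empirical priors.
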