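---
title: "A reduced successor representation model of procrastination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced successor representation model of procrastination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procrasim)
```

## The model

`procrasim` simulates a value-learning account of procrastination. The task
is a chain of `n` states; state `n` is the goal, delivering reward `R`. At
every non-goal state the agent chooses **GO** (advance, cost `c`) or
**STAY** (self-loop, free). An episode — one "assignment" — runs from state
1 to the goal. The agent first experiences a *school term* of forced-GO
episodes, then a *vacation* of free-choice episodes.

The agent's state representation is deliberately impoverished: each state is
summarised by one number, its discounted future occupancy of the goal under
the non-procrastinating policy (`x(S_k) = gamma^(n-k)`), the goal-based
reduced successor representation. State values are approximated linearly,
`v~(S_k) = w x(S_k)`, with the single weight `w` learned by TD(0):
`delta = r + gamma v~(S') - v~(S)` and `w <- w + a delta x(S)`, on every
time-step, STAY steps included. Action values are a one-step lookahead
(`q~(GO) = gamma v~(S_{k+1}) - c`, `q~(STAY) = gamma v~(S_k)`), and choices
are Boltzmann with inverse temperature `b`.

Why this produces procrastination: under the exact features,
`x_k = gamma x_{k+1}`, so *every* non-terminal GO step has
`delta = -c` regardless of `w` — the representation can express the
discounted-reward gradient along the chain but not the step-by-step
decrement of remaining future cost that a GO buys. The learned fixed point,
`w* = R - c * sum_{j=1}^{n-1} gamma^j`, therefore makes
`q~(GO) - q~(STAY) = gamma w* x_{k+1} (1 - gamma) - c`, which is negative at
every state for the default parameters, while the true values (computable in
closed form for the always-GO policy, `v(S_k) = gamma^(n-k) R - C_k` with
`C_k` the discounted remaining cost) favour GO everywhere. A tabular TD
tracker, initialised at the closed form when the vacation starts, estimates
the true values of the policy the agent actually follows, so both verdicts
are available throughout.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `n` | states per episode (unitless) | 5 |
| `R` | goal reward | 1 |
| `c` | cost per GO action | 0.1 |
| `gamma` | discount factor per time-step | 0.85 |
| `b` | softmax inverse temperature | 20 |
| `a` | learning rate, `0.5 / (1 + 0.2 m)` over episodes `m` | scheduled |
| school / vacation episodes | phase lengths | 20 / 20 |
| `n_runs` | independent simulation repetitions | 10,000 |

The learning-rate schedule models habituation; the episode index restarts at
1 when the vacation begins (the rate jumps back up at the context change).
Constant rates of 0.2 or 0.4 are supported as alternatives, as are `b` = 10
or 30 and a cost grid of 0–0.15. The same `a` drives both the weight update
and the tabular tracker on each step.

## Timing conventions

Two conventions deserve explicit statement, since the results are sensitive
to neither in the base model but mildly sensitive in the penalty variant:

* **Reward timing at the goal.** The cost `-c` is charged on the GO update
  out of `S_{n-1}` (using `gamma v~(S_n)` as the successor value), and the
  reward `R` is delivered in a separate terminal update at the goal with the
  successor value taken as 0. This is the only convention consistent with
  both the action-value definition `q~(GO) = gamma v~(S_{k+1}) - c` and the
  observed sharp rise of `w` at the goal-state update.
* **Vacation time-step counter `t_v`.** Counts cumulatively over the whole
  vacation, one tick per time-step — including the terminal goal occupancy,
  which is a time-step like any other (the terminal TD update is indexed by
  `t` with `S(t)` the goal). The penalty ramp `p(t_v)` is evaluated before
  the step's choice and the same value adjusts that step's TD errors when
  STAY is taken.

"First-entry" value gaps are recorded when a state is first entered within
an episode, before any action there, using the weight, tracker state and
`t_v` that will govern the first choice at that state. The weight "just
after leaving" a state means after the GO update out of it (after the
terminal update, for the goal). With a constant learning rate the weight
oscillates within an episode by `a c sum(gamma^j)`; the stationarity
condition pins the value just after leaving `S_{n-1}` at exactly `w*`, which
is where the package measures fixed-point convergence.

## Variants

* **Penalty**: `p(t_v) c_p` (with `p(t_v) = max(0, (t_v - 150)/150)`,
  `c_p = 0.1`) is subtracted from the selection-time STAY value, the
  reported true STAY value, and both TD errors on STAY steps. The ramp is
  linear and unbounded. Deadline-like pressure: procrastination first grows,
  then collapses once the penalty dominates.
* **Regret**: a constant `c_r = 0.02` is subtracted from the same
  quantities *except* the selection-time value — the agent cannot foresee
  the regret, so choice probabilities at fixed weights are unchanged; the
  extra negative TD errors only depress `w` further. Procrastination does
  not improve.
* **SR update**: the feature of the current non-goal state is updated by
  `alpha_SR (gamma x(S') - x(S))` with `alpha_SR = 0.05` on every vacation
  step. STAY self-loops shrink the feature by the factor
  `1 - alpha_SR (1 - gamma)` (0.9925 at defaults), so the representation
  gradually admits that the goal has become temporally more distant, which
  paradoxically restores GO's advantage near the goal.

Variants are mutually exclusive per run, and with `type = "none"` all
adjustments are exactly zero.

## Numerical and design choices

* The softmax is computed in its two-action logistic form with the exponent
  clipped at ±700, so extreme value gaps saturate to 0/1 instead of
  overflowing. No tie-breaking is needed (choice is probabilistic).
* Vacation episodes carry a safety cap (default 10,000 steps). Under all
  shipped conditions the per-step GO probability stays far from 0 and the
  cap is never hit; if hit, the episode is truncated and flagged, never an
  error. First-entry gaps at states never reached are missing values and are
  excluded from the across-run means.
* Per-run seeds are derived from the master seed by an injective affine map
  modulo the Mersenne prime `2^31 - 1` — a counter-based scheme, so run `i`
  is reproducible in isolation and enlarging `n_runs` leaves earlier runs
  unchanged. Identical configuration and seed give bit-identical ensembles.
* The ensemble engine is compiled (Rcpp) but consumes R's own RNG stream;
  a pure-R reference implementation of the identical recursion ships
  alongside it, and the test suite asserts the two are bit-identical across
  variants. All scalar primitives (features, TD error, action values,
  softmax, penalty ramp, feature update) are exported R functions tested
  against hand-derived values.
* Across-run dispersion is reported as the sample standard deviation
  (`n - 1` denominator); the convention is recorded in every run manifest.
* The true-value tracker runs only during vacation, initialised at the
  closed form. The closed form is the tabular TD fixed point of the
  forced-GO policy (the Bellman identity `v_k = gamma v_{k+1} - c` holds to
  machine precision), so school-term tracking would be a no-op.

## Problem sizes

The shipped test suite exercises the behavioral claims on ensembles of
1,000 runs (the package's chosen size for distributional checks; standard
errors of mean STAY counts are then below 0.1) and the full-scale standard
condition at 10,000 runs, which completes in a few seconds. The acceptance
script uses 10,000 runs for the base condition and 1,000 per cell for
sweeps and variants.

## What the simulator does and does not capture

The generator *is* the study design: a fixed short chain, deterministic
transitions, a single binary choice, exponential discounting, and a rigid
(or slowly adapting) one-dimensional state representation. Passing tests
show that the implementation reproduces the model's internal logic — the
sign structure of the approximated versus true value gaps, the growth of
procrastination across vacation episodes, its monotone dependence on cost,
and the variant effects. They do not show anything about real students:
there are no deadlines or alternative rewards, no stochastic task structure,
no hyperbolic discounting, no individual differences, and the mapping from
"time-step" to real time is notional. The model also takes the reduced SR
as given rather than learning it, and the optimal (off-policy) action
values are deliberately out of scope.
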