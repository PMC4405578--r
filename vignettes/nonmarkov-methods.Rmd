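---
title: "Models and methods: learning without the Markov property"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: learning without the Markov property}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonmarkov)
```

## The two task families

Most reinforcement-learning models assume the Markov property: the next
state depends only on the current state and action. This package simulates
two prototypical situations in which that assumption fails, together with
the learning models that can nonetheless solve them.

**Switch-state navigation.** An agent moves through a directed graph of
image states, three actions per state, and is rewarded on reaching a goal.
The goal transition is *gated*: it succeeds only if a designated
switch state was visited earlier in the episode; otherwise the same action
redirects to a decoy state. The environment is non-Markovian through its
state structure — the optimal action at the pre-goal state depends on
episode history. `build_switch_env()` rejection-samples a graph satisfying
the structural constraints (8 states, deterministic transitions, recurrent
and outward connections, a unique pre-goal state, and a shortest successful
episode of exactly 5 actions, verified by breadth-first search over the
(state, switch-visited) product space). The seed-0 graph is used as the
canonical environment throughout; all quantitative claims depend only on
the stated structural constraints, not on a particular arrow layout.

**Classification with intermixed feedback.** The agent classifies images
into "left"/"right". Feedback (+1/−1) for each response is delayed by a
gamma-distributed lag (shape $k = 2$, scale $\theta = 1.5$ s),

$$p(t \mid \theta, k) = \frac{t^{k-1} e^{-t/\theta}}{\Gamma(k)\,\theta^k},$$

so feedback for one response can arrive after feedback for a later
response. The task is non-Markovian through its feedback schedule: the
reward of a response can only be estimated by averaging signals over
several nearby responses. With an inter-trial interval of 1.5 s (the
package default; the delay mean is $k\theta = 3$ s, two intervals) feedback
inversions are frequent, which is the phenomenon of interest.

## The learner families

### Population of spiking neurons

A three-layer network: an input layer with one sub-population of Poisson
neurons per stimulus (fixed encoding), a hidden spiking layer, and a
decision layer read out by spike counts — majority-spiking for binary
choices, largest population count for three actions. Spike sampling is the
only exploration mechanism.

Credit assignment uses a cascade of three eligibility traces per synapse
group, with time constants spanning the three relevant timescales:

| trace | default $\tau$ | timescale |
|---|---|---|
| $e_1$ | 0.02 s | individual spikes |
| $e_2$ | 0.5 s | stimulus duration |
| $e_3$ | 4 s | reward delay |

Each decision event deposits the centered spike-count score (observed
minus expected count, the REINFORCE estimator for Poisson/binomial
readouts) into $e_1$; each trace feeds the next, and all decay
exponentially between events. The weight update uses *only* the third
trace and the reward: $\Delta W = \eta\,(R - \bar R)\,e_3$, with $\bar R$
a running reward average (update rate 0.1). The detailed synaptic
equations of the original model are not available; this reconstruction
keeps every stated architectural constraint (three layers, Poisson
spiking, majority/argmax readout, three-trace cascade, third-trace-only
updates) while remaining simple enough to verify.

Two numerical choices matter in practice:

* **Rate floor** (`min_rate = 0.5` Hz). Readout rates are rectified; at a
  hard zero the Poisson score — and with it both the gradient and
  exploration — vanishes permanently. A small floor keeps learning alive
  however depressed a synapse becomes.
* **Learning rate** ($\eta = 0.3$). The model's single free parameter,
  chosen once by a coarse competence scan: small enough to be stable on
  the navigation task (large $\eta$ saturates weights on noise), large
  enough to reach minimal-length episodes within the 50-episode horizon
  and ceiling accuracy in classification.

### Three sequence/transition Bayesian learners

*Model 1* maintains, for every action sequence $s$, Beta posteriors over
"the sequence continues" $P(C\mid s)$ and "reward given termination"
$P(R\mid \bar C, s)$, uniform Beta(1,1) priors. Planning samples thousands
of outcome trees: each tree grows breadth-first, sampling
continue/terminate and reward at every node, and stops at the first depth
containing a sampled rewarded terminal, crediting that sequence's counter.
The highest counter is the MAP estimate of the best (shortest rewarded)
sequence. Under uniform priors this planner is rationally exploratory:
an unexplored length-1 sequence has probability 0.25 of being an immediate
rewarded terminal, so shallow unknowns dominate the counters until they
have been tried. Model 1 therefore learns this task *slowest* of the three
— consistent with its published ranking — because it keys on action
history alone and must exhaust shallow alternatives before exploiting a
known 5-step solution. Tree depth is capped at 12 (trees that reach the
cap are discarded and counted); when a plan runs out before the episode
ends, the agent continues with uniform random actions.

*Model 2* learns state–action transition dynamics under the Markov
assumption (Dirichlet-categorical posterior; the predictive collapses to
the empirical ratio, so deterministic transitions are learned in one
observation) and plans by value iteration with reward 1 on entering the
goal and discount 0.95. Unvisited pairs carry optimistic value 1, which
drives systematic exploration. The gated pair is where the Markov
assumption bites: its predictive is a success/failure mixture, and the
model cannot represent *why* the goal action sometimes fails.

*Model 3* is Model 2 plus a within-episode constraint: actions whose
predicted successor was already visited this episode are excluded (the
restriction is dropped if it excludes everything). This single heuristic
makes it the strongest of the three on the navigation task, again matching
the published ranking.

One design choice goes beyond the original description: greedy planning on
a deterministic learned model can **livelock** — once every reachable pair
has been tried, the greedy cycle through the pre-goal state need not pass
the switch state, and nothing ever changes. Models 2 and 3 therefore take
a uniformly random action with probability $\varepsilon = 0.1$ per step.
Without it Model 2 truncates indefinitely in a decoy cycle; with it both
models behave like their published counterparts.

### Dirichlet-process delay learner

For intermixed feedback the optimal strategy must infer *which response a
feedback belongs to*. The learner places a Dirichlet-process prior over
the unknown delay distribution, realized as a finite Dirichlet on a delay
grid (0–15 s in 0.25 s bins, concentration $\alpha = 1$, uniform base) —
the standard computable truncation. Decision-relevant quantities use the
posterior mean (exact marginalization, deterministic). Each feedback event
is softly attributed to the last 10 not-yet-attributed responses with
responsibilities proportional to the posterior-predictive density at the
respective lags; those responsibilities update both the delay posterior
(fractional bin counts) and the per-image Beta category beliefs
(fractional evidence toward "chosen action was correct/incorrect").

Category evidence uses *leaky counts*: both sides of an image's belief
decay by $\lambda^w$ (default $\lambda = 0.7$) before evidence $w$ is
added. The forgetting factor exists because the task set includes a
reversal condition (half the images swap categories after training); an
exact conjugate learner would need as many contrary observations as it has
accumulated, which no human in the reversal experiment needed. The value
0.7 balances the two stated conditions and was fixed once: smaller
$\lambda$ flips faster after a reversal but wastes evidence under noisy
attribution; larger $\lambda$ does the opposite (at $\lambda = 0.8$ the
learner no longer reaches ceiling within a 40-trial reversal session, at
$\lambda = 0.6$ it sacrifices delayed-feedback accuracy for no reversal
benefit). In immediate mode exactly one unattributed response exists per
event, so the whole machinery reduces to a plain (leaky) Beta–Bernoulli
learner — the test suite asserts trace-identical behavior.

### Policy-gradient baseline

A tabular softmax policy over the current observation (state id or image
id), temperature 1, updated by episodic REINFORCE with a running-mean
baseline; the learning rate is the single free parameter (default 0.1,
grid-fit against reference curves by `fit_learning_rate()` over 21
log-spaced points in $[10^{-3}, 1]$). In the classification task the
baseline attributes each feedback to the most recent response — under
intermixed feedback this is simply wrong part of the time, which is
precisely the comparison the baseline exists to make.

## Evaluation layer

Correctness sequences are smoothed with a 10-trial flat kernel
(`sliding_proportion_correct()`, "valid" edges: the curve starts at trial
10; a trailing-window mode is available). Episode lengths are reported
per episode with truncation flags (episodes are capped at 100 actions, the
desk analogue of the human 10-minute wall clock). Model fit is residual
sum of squares on the common support, and models are ranked by the
finite-sample corrected Akaike criterion in its least-squares form

$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k = 1$ for the spiking and policy-gradient learners (their learning
rate) and $k = 0$ for the Bayesian learners (priors and tree counts are
treated as fixed constants, following the original accounting). A perfect
fit (RSS = 0) is reported as $-\infty$ and ranks first. The published
RSS/AICc tables themselves are not reproduction targets: they require the
unpublished per-participant traces, and the $n$ entering the published
AICc values is not recoverable from the available material.

## Synthetic surrogate data

`generate_surrogate_curves()` stands in for the human data: episode-length
curves decay exponentially from 40 to the minimum 5 with a 10-episode time
constant and Gaussian noise (10 subjects); proportion-correct curves rise
from chance 0.5 toward 0.9 with binomial window noise (14 subjects). The
sample sizes match the original cohorts; the functional families are the
simplest shapes consistent with the published figures. They emulate curve
*shape and noise level only* — no sequential dependence, no
subject-specific learning rates, no dropout. A green comparison against
surrogate curves therefore establishes that the pipeline (simulation →
curves → RSS → AICc → ranking) is correct and deterministic, not that any
model fits humans.

## Determinism and numerical notes

* Every stochastic component draws from an explicitly seeded stream;
  run-level seeds are derived from a master seed (`derive_seeds()`), and
  constructors restore the caller's RNG state.
* All ties (spike counts, Q values, posterior means at exactly 0.5, MAP
  counters) break uniformly at random under the run seed.
* The Monte-Carlo MAP planner is validated against an exact
  expected-counter enumeration (dynamic programming over active node
  sets); posteriors with exact symmetric ties count any argmax member as
  agreement.
* Value iteration warm-starts from the previous solution and replans only
  when the posterior predictive actually changes (new pair, new successor,
  or a stochastic-looking mixture pair).

## Known limitations

* The spiking reconstruction is population-aggregated (one synapse group
  per stimulus × readout population); it preserves the stated architecture
  but not biophysical detail (no membrane dynamics, no refractoriness).
* Readout weights are fixed; plasticity is input-to-hidden only, matching
  the stated locus of learning. A learned-readout variant is not provided.
* Model 1 does not converge to minimal episodes within 50 episodes in a
  3-action environment — analysis above argues this is a property of the
  model, not a defect of the implementation.
* The delay learner's soft attribution is an approximation to exact
  inference over response–feedback matchings; with hard (oracle)
  attribution its delay-posterior mean recovers the true 3.0 s mean within
  ±0.15 s at 2000 events, and the soft version beats uniform attribution,
  but no exact-matching gold standard is implemented.
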