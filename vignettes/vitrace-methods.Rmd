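---
title: "Models and methods behind vitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vitrace simulates and analyses behaviour on the discrete variable-interval
(VI) reward schedule, the two-alternative "baiting" task used to study
foraging in mice and humans. This vignette explains the environment model,
the decision agents, and the three analysis pipelines (history regression,
likelihood fitting, regret optimisation), together with the numerical and
design choices a user should know about.

## The baiting environment

Each of two options carries a *set* reward probability $P_{set}(R|i,t)$
that changes only at block transitions. The *momentary* probability
$P(R|i,t)$ obeys

$$P(R|i,t+1) = 1 - (1 - P_{set}(R|i,t))\,(1 - P(R|i,t)(1-\delta_{i,t})),$$

where $\delta_{i,t}=1$ when option $i$ was chosen at trial $t$. A chosen
option resets to its set probability; an unchosen one accumulates reward
opportunity. Under a constant set probability the recursion has the closed
form $P(R|i) = 1-(1-P_{set})^{T_i+1}$ with $T_i$ the number of completed
trials since option $i$ was last chosen ($T_i = 0$ immediately after a
choice). Two bookkeeping conventions are possible for the exponent ($T_i$ or
$T_i+1$, depending on when the counter is read); the package adopts the
$T_i+1$ form everywhere, so a just-chosen option has probability exactly $P_{set}$, and
the Bayesian agent's predictions use the same convention (the initial state
$P(R|i,1)=P_{set}$ is this closed form at $T_i=0$).

Rewards are realised as Bernoulli draws on the tracked probability rather
than by explicit bait bookkeeping. The two schemes are distributionally
identical — a persistent bait assigned with probability $P_{set}$ per trial
and collected at the next visit yields a hit probability of exactly
$1-(1-P_{set})^{k}$ after a $k$-trial gap — and the test-suite verifies the
equivalence against a brute-force bait simulator. At block transitions the
accumulated probability of unchosen options carries over and is compounded
with the *new* set probability; the chosen option resets to the new value.

Named schedule protocols reproduce the study conditions: `mouse` (9 blocks
of 50–150 trials; pairs 0.25:0.25, 0.40:0.10, 0.10:0.40), `human` (at
least 6 blocks, default 8, of 20–30 trials; pairs 0.40:0.10 and 0.10:0.40),
`oracle_uniform` (one block, each set probability uniform on $[0, 0.5]$),
plus `alternating` and `fixed` for explicit designs.

## Agents

All agents share one contract: choice probabilities from their internal
state (softmax with inverse temperature $\beta$ unless noted), then a state
update from their own choice and reward. Only the Oracle sees the true
probabilities, and the tests enforce that every other agent behaves
identically whether or not the true probabilities are offered.

* **Oracle** — greedy argmax of the true momentary probabilities, ties
  uniform. On a constant 0.1 : 0.4 pair it settles into the characteristic
  period-5 cycle (the 0.1 option is worth visiting exactly when
  $1-0.9^{k+1}$ exceeds 0.4, i.e. every fifth trial).
* **Inference-based (IB)** — per option, $N = 1000$ particles over the set
  probability, initialised uniform on $[0,1]$. The option value is the
  particle mean of the predicted reward probability
  $1-(1-\hat\theta)^{T_i+1}$. After each outcome the chosen option's
  particles are reweighted by that prediction (or its complement),
  multinomially resampled, jittered by $U(-0.025, 0.025)$ and clipped to
  $[0,1]$; the unchosen cloud is untouched, because the outcome carries no
  information about it under the baiting likelihood. If all weights vanish
  numerically the cloud is resampled uniformly with a warning. The softmax
  $\beta$ for the IB agent is a free parameter with default 10 (10 makes
  the agent exploit its beliefs while the baiting dynamics still force occasional sampling of the
  leaner option).
* **LK** — estimates the set probability by Rescorla–Wagner
  ($Q_{set}$, rate $\alpha$, chosen option only) and reconstructs the
  baiting recursion through a dynamic factor $\psi \in [0,1]$ whose
  learning rate $\alpha_\psi$ tracks the reward prediction error through
  $\alpha_\psi \leftarrow \alpha_\psi + \tau_\psi((PE+1)/2-\alpha_\psi)$,
  which keeps $\alpha_\psi \in [0,1]$ for rewards in $[0,1]$. The
  within-trial order is fixed as: prediction error, $Q_{set}$,
  $\alpha_\psi$, $\psi$ (reset to 0 for the chosen option), then
  $Q = 1-(1-Q_{set})(1-Q\psi)$ for every option, so the $Q$ update uses the
  freshly updated $\psi$ and $Q_{set}$. Initial values: $Q_{set}=Q=0.5$
  (uninformative midpoint), $\psi=0$, $\alpha_\psi=0.5$.
* **Double trace (DT)** — forgetting-Q reward expectation plus two choice
  traces inside the softmax, $\beta(Q_i + \varphi F_i + \vartheta S_i)$:
  $Q_i \mathrel{+}= \alpha(\delta_i R - Q_i)$,
  $F_i \mathrel{+}= \tau_F(\delta_i - F_i)$,
  $S_i \mathrel{+}= \tau_S(\delta_i - S_i)$. $F$ is the fast trace
  (short-term alternation when $\varphi < 0$), $S$ the slow trace
  (long-term perseverance when $\vartheta > 0$). The constrained variant
  rejects $\varphi > 0$ or $\vartheta < 0$ at construction. States start at
  $Q = 0$ (the forgetting fixed point for never-chosen options) and
  $F = S = 0.5$, which makes $F_l + F_r = 1$ and $S_l + S_r = 1$ exact at
  every trial in the two-option case.
* **Comparison family** — indirect actor (chosen option only), direct
  actor (policy-gradient update $(\delta_i - P(i))(R - c)$ with an
  average-reward offset $c$), forgetting Q, forgetting Q with one choice
  trace, and F-Q "up" (unchosen value grows towards a ceiling $C$ with its
  own rate; $Q$ initialised uniform on $[0,1]$ as specified).

### The DT model is a lagged logistic regression

Expanding the three linear recursions gives the exact lag form: reward
coefficients $b_{R,m} = \alpha(1-\alpha)^{m-1}$ and choice coefficients
$b_{C,m} = \varphi\,\tau_F(1-\tau_F)^{m-1} + \vartheta\,\tau_S(1-\tau_S)^{m-1}$,
with bias $K = \varphi + \vartheta$ from the two-option complement
identity. A variant of the choice decay that swaps the base and the prefactor
($\varphi(1-\tau_F)\tau_F^{m-1}$) is sometimes written, but it is
inconsistent with the trace recursions themselves (and with the fast/slow
reading in which $\tau_F \ge 0.5$ means fast decay), so the package uses
the recursion-consistent expansion throughout — it is the only form under
which the softmax and the lag expansion agree to $10^{-6}$, which the
acceptance suite checks on random histories after a 100-trial burn-in
(initial-condition terms decay like $(1-\tau)^{t-1}$, below $10^{-6}$ for
$\tau \ge 0.2$ at $t > 100$).

## History regression

`build_design()` creates, per trial, lagged signed rewards
$R(t-m) = R_{right}-R_{left} \in \{-1,0,1\}$ and lagged choices
$C(t-m) \in \{0,1\}$; the response is the current choice. The first $M$
trials of every session are dropped so no row mixes histories across
sessions. The extended design replaces the signed-reward block with six
blocks (unsigned rewards, choices, right/left rewards, right/left
no-rewards), whose four outcome indicators partition every trial.

`fit_elastic_net()` fits the penalised logistic regression with penalty
$\lambda \sum_j (0.25\,\beta_j^2 + 0.5\,|\beta_j|)$ — glmnet with mixing
0.5, which reproduces that form exactly — choosing $\lambda$ at the
minimum mean binomial deviance over 5 contiguous-block cross-validation
folds (contiguous rather than shuffled, to limit serial-correlation leakage
across autocorrelated trials) and refitting once on all rows.
Defaults: $M = 15$ basic / 30 extended; $\lambda$ grid of 50 values
log-spaced on $[10^{-4}, 10]$;
`standardize = FALSE` so coefficients remain log-odds per unit of the
already-comparable regressors; the intercept is never penalised. Because
choices are coded $\{0,1\}$ rather than $\pm 1$, fitted choice
coefficients correspond to $2 b_{C,m}$ of the DT expansion; `fit_decay_model()`
and the equivalence tests carry that factor.

`fit_decay_model()` inverts the lag profiles: the reward decay by a 1-D
least-squares search, and the two-exponential choice decay by variable
projection (for fixed decay rates the scalings are an exact linear
least-squares solve, leaving a smooth 2-D multistart search over the
rates). Components are relabelled so $\tau_F \ge \tau_S$; an all-zero
choice profile returns the flagged degenerate fit. Per-session fits can be
correlated against session covariates with `condition_correlation()`
(Pearson, with rank-based tercile summaries).

## Likelihood fitting and model comparison

`session_log_likelihood()` evaluates any model on recorded behaviour by
teacher forcing: per trial the model's probability of the *recorded* choice
enters a Bernoulli log-likelihood, then the state is updated with the
recorded choice and reward. Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before the log. For the DT family the whole
evaluation is a compiled recursion (`src/dt_loglik.cpp`); the same
quantities are also computable through the generic per-trial engine, and
the tests hold the two paths to $10^{-12}$ agreement.

`anneal_fit()` implements the sampling search: 1000 uniform draws in the
bounds, keep the top 1%, redraw from a Gaussian at their mean and SD
(clipped to the bounds), and stop when the best log-likelihood changes by
less than 0.01% in relative magnitude for two consecutive iterations, with
an iteration cap of 50. An elite of fewer than two draws would leave
the Gaussian spread undefined, so the elite size is floored at two.
Behavioural bounds: $\alpha, \tau_F, \tau_S, \tau_M \in [0,1]$,
$\beta \in [0,50]$, $\varphi, \vartheta, \iota \in [-25,25]$. The
undefined scalar $\iota$ in that list is interpreted as the extra scalar of
whichever model is being fitted (the direct actor's $c$, F-Q up's $C$);
$\tau_M$ is accepted in configurations for forward compatibility but no
shipped model uses a third trace.

`crossval_compare()` splits the concatenated trials into five contiguous
folds shared across models, fits on four fifths and reports held-out mean
per-trial negative log-likelihood and AUC (score = predicted probability
of "right", label = recorded choice; rank formulation with ties counted
half). Variational Bayesian model selection is out of scope; CV NLL/AUC is
the comparison currency.

### Parameter recovery

The recovery protocol draws true DT parameters uniformly in the narrow box
($\alpha,\tau_F,\tau_S \in [0,1]$, $\beta,\vartheta \in [0,4]$,
$\varphi \in [-4,0]$), simulates closed-loop sessions on alternating
0.1:0.4 / 0.4:0.1 blocks of 100 trials, and refits with the *wide*
behavioural bounds. The wide refit box matters: it is what lets poorly
identified temperature and scaling parameters escape the truth range, which
is precisely the asymmetry the protocol demonstrates (learning rates
recover better than $\beta$, $\varphi$, $\vartheta$). Refitting inside the
truth box clips that escape and artificially inflates the scaling
correlations — we verified both variants and ship the wide-box protocol
for the recovery *study*. When the goal is instead to recover one known
parameter set from a sizeable dataset (as in the benchmark refit of the
mouse-fit parameters), the narrow recovery box gives the better-calibrated
estimate: under the wide box the learning rate absorbs a small upward bias
from compensating temperature/scaling values.

## Harvesting efficiency

Regret is the cumulative maximal expected reward minus collected rewards.
Both baselines are implemented because both readings are in use: the default
*trajectory* mode sums $\max_a P(R|a,t)$ along the realised session; the
*oracle-run* mode compares against an independent greedy Oracle simulation
on the same schedule.

`optimize_in_env()` reproduces the two-stage sampling search: uniform
draws scored by mean regret over 4 fresh 1000-trial sessions, keep the
lowest 5%; Gaussian redraws at 3 SD around the keepers, keep the lowest
10%, re-test each 100 times, return the best mean. The stage-1 draw count
is a knob (default 10,000) and
the test-suite uses the documented reduced preset of 500/250 draws with 20
re-tests. Each draw is an independent column of one vectorised closed-loop
simulation, and per-draw seeds derive deterministically from the master
seed, reproducing the "different random number generator per draw" design.
Named conditions: volatility (blocks of 50/100/500 at 0.10:0.40) and two
set-probability-difference families (0.20:0.80 / 0.30:0.70 / 0.40:0.60,
and 0.45:0.05 / 0.40:0.10 / 0.35:0.15); neither delta family is
privileged.

## Synthetic data and fixtures

`generate_recovery_dataset()` produces closed-loop DT datasets with a JSON
manifest (schema version, ground truth, per-session seeds) so any fixture
regenerates from one integer; `tau_F = tau_S` parameterisations are flagged
as trace-degenerate ($\varphi$ and $\vartheta$ identified only through
their sum). `edge_fixtures()` ships deterministic degenerate sessions
(all-left, strict alternation, single trial, shorter-than-lag,
all-rewarded) used across the test-suite.

## Problem sizes used by the test-suite

The shipped tests run the full pipelines at sizes chosen to keep the suite
brisk while leaving the qualitative findings stable across seeds: IB
recovery at 30 sessions x 1000 trials per probability pair; the uniform
set-probability Oracle regression at 40 sessions x 1000 trials; parameter
recovery at 100 draws with single 1000-trial sessions and a 250-draw,
12-iteration search; harvesting optimisation at 500/250 draws with 50
evaluation sessions. The acceptance script uses 30 sessions per IB pair
and 10 independent 1000-draw refits of a 20-session DT dataset.

## What the generators do and do not emulate

Simulated sessions reproduce the task's reward contingencies, block
structure and trial counts, and the DT generator reproduces the mouse-fit
parameter regime used throughout the examples. They do not emulate reaction times,
inter-trial timing, satiation or attention drift, or between-subject
parameter heterogeneity; passing tests therefore validate the algorithms
under the task's generative assumptions, not the biological completeness
of those assumptions.

## Known limitations

* The regression reports penalised point estimates only — no standard
  errors or intervals, matching the analysis it mirrors.
* The IB agent's likelihood is stochastic (particle resampling), so it is
  simulated and analysed but not fitted by the annealing search.
* The DT-to-logistic equivalence, and the complement identities, are
  two-option results; the softmax itself supports more options.
* Continuous-time VI schedules, changeover delays and multiple reward
  sizes are out of scope.
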