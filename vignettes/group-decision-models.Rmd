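---
title: "Modelling collective decisions: social drift-diffusion and social reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupcog)
```

`groupcog` implements two complementary model families for groups whose
members influence each other in real time, together with the likelihood
machinery to fit them to data. This vignette is the package's account of
the science: the models and their assumptions, the parameters and their
defaults, the numerical choices, what the synthetic scenarios emulate, and
the limits of what the tests can show.

## The social drift-diffusion model

Each of $N$ agents accumulates noisy evidence $L_i(t)$ for a binary choice
(option A is the designated correct option). In discrete time,

$$L_i(t + \Delta t) = L_i(t) + \delta_i(t)\,\Delta t + \sqrt{\Delta t}\,\epsilon, \qquad \epsilon \sim \mathcal{N}(0, \sigma^2),$$

and agent $i$ decides when $L_i$ reaches the upper threshold (choice A) or
the lower threshold (choice B). The drift decomposes into a personal and a
social part,

$$\delta_i(t) = \delta_{p,i} + \delta_s(M(t)), \qquad
  \delta_s(M) = s \cdot \operatorname{sign}(M)\,|M|^{q},$$

where $M(t) = N_A(t) - N_B(t)$ is the signed majority among group members
who have already decided and whose choices are therefore observable. With
$q = 1$ the social drift is the linear majority rule $sM$; $q < 1$
saturates (each additional observed choice adds less), $q > 1$ amplifies
large majorities. Because a plain power $M^q$ is undefined for negative
majorities at non-integer $q$, the package uses the sign-preserving power
above, which keeps the social drift an odd function of $M$ and the two
options exactly symmetric. That is a modelling commitment, not a numerical
trick, and it is the only reading under which anticonformity-free copying
treats A and B alike.

Assumptions worth making explicit: social information enters only through
*observed decisions* (no communication of graded evidence states); decided
agents are fixed (no revisions); every agent sees every other agent
(complete network); and there is no non-decision time — the trial clock is
the decision clock. The trial-record format reserves no column for
non-decision time; adding one is a forward-compatible extension.

### Parameters, units and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `delta_p` | personal drift rate | evidence / time | 0.3 |
| `s` | social-drift scale | evidence / (time x majority) | 0 |
| `q` | social power exponent | — | 1 |
| `threshold_upper`, `threshold_lower` | decision boundaries | evidence | +1, -1 |
| `start` | initial evidence | evidence | 0 |
| `noise_sd` | diffusion SD per unit time | evidence | 1 |

`noise_sd = 1` fixes the evidence unit — the standard Wiener-likelihood
identifiability convention — and is also why `noise_sd` stays fixed during
fitting. The simulator default `dt = 0.001` is small enough that halving
it moves absorption probabilities by less than Monte-Carlo error at
$10^5$ trials (a tested invariant); scenario batches use `dt = 0.005` for
replicate throughput, which the directional contrasts are insensitive to.

### Numerical choices

**Crossing detection.** The default records a decision when the evidence
is at or beyond a boundary at a step's end. End-point monitoring of a
diffusion systematically overshoots first-passage times by
$\approx 0.583\,\sigma\sqrt{\Delta t}$ per boundary, so the simulator also
offers `crossing = "bridge"`: within each step, absorption is additionally
drawn from the exact Brownian-bridge crossing probability
$\exp(-2(b - L_t)(b - L_{t+\Delta t})/(\sigma^2 \Delta t))$. The bridge
option removes the $O(\sqrt{\Delta t})$ bias (decisions are still stamped
at step ends, an $O(\Delta t)$ effect) and is what all oracle-equivalence
checks use; the default remains the plain step rule, which is the more
literal reading of the discrete update above. The bridge draw tests the
upper boundary first; the event that both bridge probabilities are
non-negligible in one step has vanishing probability at the step sizes
used.

**Ties and visibility.** Agents crossing within the same step are all
stamped with the step-end time; their decision rank is broken by agent
index (deterministic and documented). A decision made at step $k$ enters
the majority that other agents' drifts see from step $k+1$ on — the counts
used in a step are exactly the decisions recorded strictly before it, a
tested invariant.

**Censoring.** Agents still undecided at `t_max` (default 20) are returned
with `NA` choice and RT, never forced; the likelihood scores them by their
surviving probability mass.

**First-passage densities.** `ddm_fpt_grid()` propagates the evidence
distribution through an explicit tridiagonal Markov chain on `n_bins`
interior nodes: per step, mass moves one node up or down or stays, with
probabilities matched to the step mean $\delta\,\Delta t$ and variance
$\sigma^2 \Delta t$. This kernel is a probability transition only when
$\sigma^2 \Delta t + (\delta \Delta t)^2 \le h^2$ (node spacing $h$);
unstable combinations are rejected with instructions to shrink `dt` rather
than silently renormalised. The starting point is linearly interpolated
between its two neighbouring nodes, which removes an $O(h)$ placement
error. Against the closed-form two-boundary absorption formula the grid is
accurate to about $10^{-5}$–$10^{-4}$ at 100–200 bins, and total mass
(absorbed plus surviving) is conserved to well below $10^{-9}$.

**Likelihood of group data.** Each agent's drift schedule is a
piecewise-constant function of the *observed* decision timeline of the
others, conditioned on as exogenous covariates — the standard conditional
factorisation; a joint path likelihood over all agents is out of scope.
Observed decisions contribute the absorbed-mass density at their
(boundary, time); censored agents contribute surviving mass. The grid
geometry (thresholds, noise, `q`) must be shared across agents; `delta_p`,
`s` and the starting point may vary per agent. Fitting (`ddm_fit()`)
estimates shared `delta_p` and `s` by Nelder-Mead from a small number of
starts (default 2; the profile is smooth and two-dimensional), with
standard errors from the numerical Hessian. Refining the grid (double the
bins, quarter the step) moves fixture log-likelihoods by well under
$10^{-3}$ relative, a tested invariant.

## The social reinforcement-learning model

Across repeated trials each agent keeps a latent value $Q_i$ per option,
updated after every choice by the reward-prediction error,

$$Q_{i,t} = Q_{i,t-1} + \alpha\,(\pi_{i,t-1} - Q_{i,t-1}),$$

and turns values into choice probabilities through a softmax with rate
$\beta$. Social influence is *decision biasing*: the choice probability is
a mixture

$$P_i = (1 - \sigma)\,\frac{e^{\beta Q_i}}{\sum_m e^{\beta Q_m}} + \sigma\,\frac{n_i^{\theta}}{\sum_m n_m^{\theta}},$$

where $n_i$ counts group members observed choosing option $i$ on the
immediately preceding trial (the $t-1$ subscript is taken literally: a
one-trial window, not a cumulative history). $\theta > 1$ is conformity —
majorities are copied disproportionately — and $\theta < 1$
anticonformity. Value shaping (social information entering the $Q$ update
itself) is deliberately not implemented.

Choices the model family leaves open, resolved as follows:

* **Self-inclusion.** "Group members previously choosing" is read as the
  *other* $N - 1$ members; `include_self = TRUE` switches to whole-group
  counts. Recorded tables are self-describing (the counts are stored per
  row) and the validator detects either convention.
* **First trial.** With nothing yet observed the copying term is
  undefined; trial 1 (and any all-zero count vector, via
  $0^\theta := 0$) falls back to the asocial softmax, keeping the rule a
  proper mixture rather than raising a division error.
* **Initial values.** $Q$ starts at `q0 = 0` (configurable). With payoff
  means of 15–20 points this makes early choices near-uniform.
* **Payoffs.** Gaussian with the stated SD, not truncated or rounded; the
  reversal swaps the two option means after the changepoint trial.

Fitting (`rl_fit()`) maximises the exact choice likelihood with $Q$
trajectories reconstructed from the recorded payoffs. Parameters are
optimised on transformed scales (logit for $\alpha, \sigma$; log for
$\beta, \theta$) from 10 jittered starts by default, with delta-method
standard errors. When $\hat\sigma \approx 0$ the conformity exponent drops
out of the likelihood; the fit flags `theta_unidentifiable` instead of
reporting a meaningless number. The asocial sub-model ($\sigma = 0$,
two parameters) is the natural AIC null.

## Scenarios: what the synthetic data emulate

The scenario generators are first-class, tested code; they define the
study conditions.

The three RL scenarios use the canonical published settings: five agents,
two options paying on average 15 (A) and 20 (B) points with SD 3, reversed
after trial 50 of 100; $\alpha = 0.3$, $\beta = 0.18$ for everyone; and
$\sigma = 0$, $(\sigma = 0.3, \theta = 1.5)$, $(\sigma = 0.7, \theta = 5)$
for the asocial, weak-conformist and strong-conformist panels. The number
of trials is not stated alongside those values; 100 is the package default
and is exposed. The expected pattern — weak conformists both converge
pre-reversal and re-adapt best, strong conformists converge fastest but
herd on the outdated option — is asserted directionally over replicate
groups.

The DDM scenario parameters are *not* published values: the source figures
state the qualitative designs only (five agents; varying ability = drifts;
varying caution = thresholds). The package fixes, once: drifts
0.1–0.5 (heterogeneous-ability panel), symmetric thresholds 0.4–1.6
(heterogeneous-caution panel), baseline $\delta_p = 0.3$ and thresholds
$\pm 1$, and a shared linear social coupling $s = 0.5$. The coupling was
calibrated once to the captioned orderings — in particular, with weak
coupling the "hasty agents undermine later deciders" contrast does not
separate from its control, because high-threshold late deciders are
intrinsically more accurate and weak cascades cannot overcome that
composition effect. Tests assert only the directional contrasts: ability
predicts decision order and late deciders gain accuracy only when coupled;
low thresholds buy speed at the cost of accuracy and export that cost to
later deciders relative to a homogeneous group.

What the scenarios do *not* emulate: non-decision time, trial-to-trial
parameter drift, network structure, group turnover, more than two options,
and any coupling between the two model families. Passing tests therefore
certify the implementation under the models' own assumptions, not the
models' adequacy for any empirical data set.

## Problem sizes and error budgets

Monte-Carlo checks state their error budgets explicitly: proportions are
compared at three binomial standard errors, directional contrasts at twice
their pooled standard error. The suite uses $10^5$ trials for the
closed-form oracle comparisons (binomial SE $\approx 0.0016$),
$6 \times 10^4$ first-passage draws for the distribution-level
(Kolmogorov-Smirnov) comparison against the numeric grid, $8 \times 10^3$
group trials per decision-order contrast, and 1500 replicate groups per
social-learning panel. Parameter recovery runs 12 replicate RL groups
(5 agents x 100 trials) and 4 DDM datasets (80 group trials x 5 agents);
the tolerance for each parameter's median absolute error was fixed in
advance as three times the error measured in an independent pilot run
whose report ships with the package
(`inst/extdata/recovery_tolerances.json`).

## Known limitations

* The social-DDM likelihood conditions on others' observed decision times;
  it does not integrate over their randomness, so it is a partial
  (conditional) likelihood. This is the standard choice and is exact for
  inference on $\delta_p, s$ given the social timeline, but it is not a
  generative likelihood for whole-group data.
* The explicit grid forces $\Delta t \le h^2/\sigma^2$; very fine evidence
  grids therefore cost quadratically finer time steps. An implicit solver
  would lift the restriction and is a natural extension hook.
* Step-end decision stamping quantises RTs to multiples of `dt`; fitted
  data are binned accordingly.
* `theta` is weakly identified whenever majorities are small or `sigma` is
  small — visible in its comparatively wide pilot recovery error — and the
  fit flags the degenerate case only.
* Hierarchical (random-effects) estimation across agents is out of scope;
  fits are shared-parameter or fully per-agent.
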