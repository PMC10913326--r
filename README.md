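# groupcog

Simulation and likelihood-based inference for collective decision-making,
for researchers in computational cognitive science and collective-behaviour
modelling who want to link *individual* cognitive parameters to *group*
outcomes — information cascades, self-organised decision order, collective
intelligence, and maladaptive herding — and to recover those parameters
from group experiments.

Two model families are implemented end to end:

**Social drift-diffusion model (DDM).** Each of *N* agents accumulates
noisy evidence `L(t + Δt) = L(t) + δ(t)Δt + √Δt·ε` between two absorbing
thresholds (upper = option A, the designated correct choice). The drift
splits into a personal and a social part,

```
δ_i(t) = δp_i + s · sign(M(t)) · |M(t)|^q,     M(t) = N_A(t) − N_B(t),
```

where `M(t)` is the signed majority of group members who have *already*
decided — so early choices feed back into the evidence accumulation of the
rest, in real time. With `q = 1` this is the linear majority rule.

**Social reinforcement-learning model (RL).** Over repeated trials, agents
update latent option values by reward-prediction errors,
`Q_t = Q_{t−1} + α(π_{t−1} − Q_{t−1})`, and choose via a mixture of their
own softmax policy (rate `β`) and frequency-dependent copying of the other
members' previous choices,

```
P_i = (1 − σ) · exp(βQ_i) / Σ_m exp(βQ_m)  +  σ · n_i^θ / Σ_m n_m^θ,
```

with social weight `σ` and conformity exponent `θ` (`θ > 1`: majorities
are copied disproportionately). A two-option Gaussian payoff environment
reverses its means mid-session, so conformity can be tested against
adaptability.

Around the simulators sit exact likelihoods (`rl_loglik()`,
`social_ddm_loglik()` via a tridiagonal first-passage grid), closed-form
oracles (`fpt_constant_drift()`), maximum-likelihood fitters with
multi-start optimisation and AIC model comparison (`rl_fit()`,
`ddm_fit()`), a parameter-recovery harness (`rl_recovery()`,
`ddm_recovery()`), canonical five-agent scenarios (`ddm_scenarios()`,
`rl_scenarios()`), CSV/YAML I/O, and a command-line interface.

## Worked example

Five agents who differ in ability (personal drift 0.1–0.5) and share a
linear social coupling `s = 0.5`:

```r
library(groupcog)
ag <- ddm_agents(delta_p = c(0.1, 0.2, 0.3, 0.4, 0.5), s = 0.5, q = 1)
tr <- simulate_group(ag, n_trials = 2000, dt = 0.005, t_max = 20, seed = 1)
tr
#> <group_ddm_trace> 2000 trial(s) x 5 agent(s), dt = 0.005, t_max = 20, crossing = step
#>  trial agent choice    rt rank n_A_at_decision n_B_at_decision
#>      1     1      A 2.285    5               4               0
#>      1     2      A 2.120    4               3               0
#>      1     3      A 0.830    2               1               0
#>      1     4      A 1.975    3               2               0
#>      1     5      A 0.545    1               0               0
#>      2     1      B 2.495    5               0               4
#>  ...
```

In trial 1 the most able agent (5) decides first and correctly; the others
follow it up the cascade. In trial 2 an early error drags the whole group
to the wrong option — both faces of social coupling in one simulation.
Accuracy rises with decision rank, the signature of self-organised
information flow:

```r
subset(summarize_trace(tr), metric == "accuracy_by_rank")
#>             metric group     value
#> 1 accuracy_by_rank     1 0.6380000
#> 2 accuracy_by_rank     2 0.6765000
#> 3 accuracy_by_rank     3 0.6900000
#> 4 accuracy_by_rank     4 0.7310000
#> 5 accuracy_by_rank     5 0.7340000
```

Rank-1 deciders are right 63.8% of the time, rank-5 deciders 73.4% — the
late deciders harvest the information the early ones produced.

On the learning side, strong conformists (`σ = 0.7, θ = 5`) herd: after
the payoff reversal at trial 50, only about two thirds of final-quarter
choices land on the newly better option (weak conformists reach ~0.72,
see `rl_scenarios()`):

```r
env  <- rl_env(means = c(A = 15, B = 20), sd = 3, n_trials = 100, changepoint = 50)
reps <- simulate_rl_groups(rl_agents(0.3, 0.18, 0.7, 5, n_agents = 5), env,
                           n_replicates = 500, seed = 1)
round(mean(adaptation_share(reps)), 3)
#> [1] 0.681
```

And parameters are recoverable from a single simulated group
(5 agents × 100 trials, truth α = 0.3, β = 0.18, σ = 0.3, θ = 1.5):

```r
fit <- rl_fit(simulate_rl_group(rl_agents(0.3, 0.18, 0.3, 1.5, n_agents = 5),
                                env, seed = 2), n_starts = 10, seed = 1)
fit
#> <rl_fit: social> logLik = -268.1595, AIC = 544.319
#>        estimate         se
#> alpha 0.3111363 0.06734589
#> beta  0.1646834 0.02835126
#> sigma 0.3370969 0.08188880
#> theta 3.2844185 4.22650244
```

`α`, `β`, `σ` come back close to truth; `θ`'s wide standard error shows it
is only weakly identified at moderate social weights — which is exactly
what the recovery harness and its pilot-calibrated tolerances quantify.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/groupcog", package = "groupcog"))')
Rscript $CLI scenarios --list
Rscript $CLI scenarios --emit weak_conformist --out cfg.yaml
Rscript $CLI simulate-rl --config cfg.yaml --out trace.csv --seed 7 --replicates 1
Rscript $CLI fit-rl --data trace.csv --out report.json
Rscript $CLI summarize --data trace.csv --out summary.csv
```

All commands are byte-reproducible under a fixed `--seed`.

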