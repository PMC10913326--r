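# Shared fixtures and independent mini-oracles for the test suite.
# Everything is generated in code; no stored data files.

# canonical five-agent RL group at the published parameter values
fix_rl_agents <- function(sigma = 0.3, theta = 1.5)
  rl_agents(alpha = 0.3, beta = 0.18, sigma = sigma, theta = theta,
            q0 = 0, n_agents = 5)

fix_rl_env <- function(n_trials = 100)
  rl_env(means = c(A = 15, B = 20), sd = 3, n_trials = n_trials,
         changepoint = floor(n_trials / 2))

# Independent hand computation of the social-RL log-likelihood: plain
# sequential arithmetic straight from the model equations, sharing no code
# with the package implementation.
hand_rl_loglik <- function(trials, alpha, beta, sigma, theta, q0 = 0) {
  ll <- 0
  for (a in sort(unique(trials$agent))) {
    d <- trials[trials$agent == a, ]
    d <- d[order(d$trial), ]
    qa <- q0; qb <- q0
    for (i in seq_len(nrow(d))) {
      ea <- exp(beta * qa); eb <- exp(beta * qb)
      pa <- ea / (ea + eb)
      na <- d$n_A_prev[i]; nb <- d$n_B_prev[i]
      if (na + nb > 0) {
        wa <- if (na == 0) 0 else na^theta
        wb <- if (nb == 0) 0 else nb^theta
        pa <- (1 - sigma) * pa + sigma * wa / (wa + wb)
      }
      ll <- ll + log(if (d$choice[i] == "A") pa else 1 - pa)
      if (d$choice[i] == "A") qa <- qa + alpha * (d$payoff[i] - qa)
      else qb <- qb + alpha * (d$payoff[i] - qb)
    }
  }
  ll
}

# Monte-Carlo standard error of a proportion
prop_se <- function(p, n) sqrt(p * (1 - p) / n)
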