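test_that("an uninformative first trial scores log(1/2)", {
  t1 <- data.frame(trial = 1, agent = 1, choice = "A", payoff = 14.2,
                   n_A_prev = 0, n_B_prev = 0)
  expect_equal(rl_loglik(t1, rl_agents(0.3, 0.18, 0.3, 1.5)), log(0.5))
})

test_that("the likelihood matches independent hand enumeration", {
  # hand-built 3-trial, 2-agent table (agent 2's counts = agent 1's choices)
  tab <- data.frame(
    trial = rep(1:3, each = 2), agent = rep(1:2, 3),
    choice = c("A", "B", "A", "A", "B", "A"),
    payoff = c(14, 21, 16, 18.5, 19, 13),
    n_A_prev = c(0, 0, 0, 1, 1, 1),
    n_B_prev = c(0, 0, 1, 0, 0, 0))
  pars <- list(alpha = 0.4, beta = 0.25, sigma = 0.35, theta = 2)
  got <- rl_loglik(tab, rl_agents(pars$alpha, pars$beta, pars$sigma,
                                  pars$theta))
  want <- hand_rl_loglik(tab, pars$alpha, pars$beta, pars$sigma, pars$theta)
  expect_equal(got, want, tolerance = 1e-12)
  # and on a simulated table with heterogeneous agents
  ag <- rl_agents(alpha = c(0.2, 0.4, 0.3, 0.5, 0.25), beta = 0.2,
                  sigma = c(0, 0.3, 0.5, 0.2, 0.6), theta = 1.8)
  tr <- simulate_rl_group(ag, fix_rl_env(25), seed = 31)
  got2 <- rl_loglik(tr, ag)
  want2 <- sum(vapply(1:5, function(a)
    hand_rl_loglik(tr[tr$agent == a, ], ag$alpha[a], ag$beta[a], ag$sigma[a],
                   ag$theta[a]), numeric(1)))
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("the likelihood is deterministic and row-order invariant", {
  tr <- simulate_rl_group(fix_rl_agents(), fix_rl_env(30), seed = 12)
  ll <- rl_loglik(tr, fix_rl_agents())
  set.seed(1)
  shuffled <- tr[sample(nrow(tr)), ]
  expect_identical(rl_loglik(shuffled, fix_rl_agents()), ll)
})

test_that("corrupted social counts are rejected with diagnostics", {
  tr <- simulate_rl_group(fix_rl_agents(), fix_rl_env(10), seed = 13)
  tr$n_A_prev[17] <- tr$n_A_prev[17] + 1L
  expect_error(rl_loglik(tr, fix_rl_agents()), "inconsistent")
  expect_error(validate_trial_table(tr[-3, ]), "exactly once")
})

test_that("the generating parameters outscore perturbed ones on average", {
  set.seed(14)
  truth <- fix_rl_agents()
  diffs <- replicate(25, {
    tr <- simulate_rl_group(truth, fix_rl_env(), seed = sample.int(1e6, 1))
    rl_loglik(tr, truth, validate = FALSE) -
      rl_loglik(tr, rl_agents(0.5, 0.18, 0.3, 1.5), validate = FALSE)
  })
  expect_gt(mean(diffs), 0)
})

test_that("asocial data yield sigma near zero and flag theta", {
  tr <- simulate_rl_group(fix_rl_agents(sigma = 0), fix_rl_env(200), seed = 15)
  fit <- rl_fit(tr, n_starts = 4, seed = 1)
  expect_lt(fit$estimates["sigma"], 0.05)
  # the flag fires exactly when sigma is estimated at (numerically) zero
  expect_identical(fit$theta_unidentifiable,
                   unname(fit$estimates["sigma"] < 0.02))
  if (fit$theta_unidentifiable) expect_true(is.na(fit$se["theta"]))
})

test_that("model comparison prefers the generating model", {
  # light version (acceptance runs the full replicate design)
  n_rep <- 6
  hits_social <- hits_asocial <- 0
  for (r in seq_len(n_rep)) {
    tr_s <- simulate_rl_group(fix_rl_agents(0.7, 5), fix_rl_env(), seed = 100 + r)
    f1 <- rl_fit(tr_s, "social", n_starts = 2, seed = r, validate = FALSE)
    f0 <- rl_fit(tr_s, "asocial", n_starts = 2, seed = r, validate = FALSE)
    hits_social <- hits_social + (f1$aic < f0$aic)
    tr_a <- simulate_rl_group(fix_rl_agents(0), fix_rl_env(), seed = 200 + r)
    g1 <- rl_fit(tr_a, "social", n_starts = 2, seed = r, validate = FALSE)
    g0 <- rl_fit(tr_a, "asocial", n_starts = 2, seed = r, validate = FALSE)
    hits_asocial <- hits_asocial + (g0$aic < g1$aic)
  }
  expect_gte(hits_social, n_rep - 1)
  expect_gte(hits_asocial, n_rep - 1)
})
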