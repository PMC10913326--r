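test_that("recorded latent values satisfy the updating rule exactly", {
  tr <- simulate_rl_group(fix_rl_agents(), fix_rl_env(), seed = 1)
  for (a in 1:5) {
    d <- tr[tr$agent == a, ]
    qa <- 0; qb <- 0
    for (i in seq_len(nrow(d))) {
      expect_equal(d$Q_A[i], qa, tolerance = 1e-12)
      expect_equal(d$Q_B[i], qb, tolerance = 1e-12)
      if (d$choice[i] == "A") qa <- update_q(qa, d$payoff[i], 0.3)
      else qb <- update_q(qb, d$payoff[i], 0.3)
    }
  }
})

test_that("trial 1 is asocial and recorded counts are the others' choices", {
  tr <- simulate_rl_group(fix_rl_agents(), fix_rl_env(20), seed = 2)
  t1 <- tr[tr$trial == 1, ]
  expect_true(all(is.na(t1$p_social_A)))
  expect_equal(t1$p_combined_A, t1$p_asocial_A)
  expect_true(all(t1$n_A_prev == 0 & t1$n_B_prev == 0))
  expect_identical(validate_trial_table(tr), "exclude_self")
  expect_true(all((tr$n_A_prev + tr$n_B_prev) %in% c(0L, 4L)))
  # with self-inclusion the counts cover the whole group
  tr2 <- simulate_rl_group(fix_rl_agents(), fix_rl_env(20), seed = 2,
                           include_self = TRUE)
  expect_identical(validate_trial_table(tr2), "include_self")
  expect_true(all(tr2$n_A_prev[tr2$trial > 1] + tr2$n_B_prev[tr2$trial > 1] == 5))
})

test_that("recorded mixture probabilities are a proper mixture", {
  tr <- simulate_rl_group(fix_rl_agents(0.4, 2), fix_rl_env(30), seed = 3)
  later <- tr[tr$trial > 1, ]
  expect_equal(later$p_combined_A,
               0.6 * later$p_asocial_A + 0.4 * later$p_social_A,
               tolerance = 1e-12)
  expect_true(all(tr$p_combined_A >= 0 & tr$p_combined_A <= 1))
})

test_that("group simulation is reproducible and replicates are independent", {
  a <- simulate_rl_groups(fix_rl_agents(), fix_rl_env(30), 3, seed = 9)
  b <- simulate_rl_groups(fix_rl_agents(), fix_rl_env(30), 3, seed = 9)
  expect_identical(a$choices, b$choices)
  expect_identical(a$payoffs, b$payoffs)
  expect_false(identical(a$choices[1, , ], a$choices[2, , ]))
})

test_that("sigma = 0 reproduces an asocial learner path for path", {
  env <- fix_rl_env(40)
  tr <- simulate_rl_group(fix_rl_agents(sigma = 0), env, seed = 77)
  # independent minimal reference: same draw discipline, plain arithmetic
  set.seed(77)
  qa <- rep(0, 5); qb <- rep(0, 5)
  ref_choice <- matrix(NA_character_, 40, 5)
  for (t in 1:40) {
    p <- 1 / (1 + exp(-0.18 * (qa - qb)))
    u <- runif(5)
    ch <- ifelse(u < p, "A", "B")
    mns <- if (t <= env$changepoint) c(A = 15, B = 20) else c(A = 20, B = 15)
    pay <- rnorm(5, mean = mns[ch], sd = 3)
    ref_choice[t, ] <- ch
    up <- ch == "A"
    qa[up] <- qa[up] + 0.3 * (pay[up] - qa[up])
    qb[!up] <- qb[!up] + 0.3 * (pay[!up] - qb[!up])
  }
  got <- matrix(tr$choice, 40, 5, byrow = TRUE)
  expect_identical(got, ref_choice)
})

test_that("a lone asocial learner locks onto the better option", {
  # deterministic payoffs, stable environment, sharp softmax; optimistic
  # initial values guarantee both options get sampled
  ag <- rl_agents(alpha = 0.5, beta = 5, sigma = 0, theta = 1, q0 = 15)
  env <- rl_env(means = c(A = 10, B = 12), sd = 0, n_trials = 60,
                changepoint = 60)
  reps <- simulate_rl_groups(ag, env, n_replicates = 300, seed = 4)
  lastq <- reps$choices[, 46:60, 1]
  expect_gt(mean(lastq == 2), 0.95)
})

test_that("constant payoffs drive Q geometrically to the payoff", {
  ag <- rl_agents(alpha = 0.3, beta = 10, sigma = 0, theta = 1, q0 = 0)
  env <- rl_env(means = c(A = 10, B = -50), sd = 0, n_trials = 30,
                changepoint = 30)
  tr <- simulate_rl_group(ag, env, seed = 5)
  d <- tr[tr$agent == 1 & tr$choice == "A", ]
  runs <- seq_len(nrow(d)) - 1          # A-choices before each A-trial
  expect_equal(d$Q_A, 10 * (1 - 0.7^runs), tolerance = 1e-10)
})

test_that("strong conformists converge fast but herd after the reversal", {
  n <- 150
  weak <- simulate_rl_groups(fix_rl_agents(0.3, 1.5), fix_rl_env(), n, seed = 6)
  strong <- simulate_rl_groups(fix_rl_agents(0.7, 5), fix_rl_env(), n, seed = 7)
  ad_w <- adaptation_share(weak); ad_s <- adaptation_share(strong)
  se <- sqrt(var(ad_w) / n + var(ad_s) / n)
  expect_gt(mean(ad_w) - mean(ad_s), 2 * se)
  ag_w <- agreement_trial(weak); ag_s <- agreement_trial(strong)
  expect_lt(mean(ag_s), mean(ag_w))
})
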