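test_that("a noise-free agent ramps deterministically to the boundary", {
  ag <- ddm_agents(delta_p = 1, s = 0, noise_sd = 1e-12,
                   threshold_upper = 1, threshold_lower = -1)
  tr <- simulate_group(ag, n_trials = 1, dt = 0.01, t_max = 2, seed = 1)
  expect_equal(tr$choice, "A")
  expect_equal(tr$rt, 1.00)
  expect_equal(tr$rank, 1L)
})

test_that("traces are bit-identical under a fixed seed", {
  ag <- ddm_agents(delta_p = c(0.2, 0.4), s = 0.3, n_agents = 2)
  a <- simulate_group(ag, 50, dt = 0.01, t_max = 10, seed = 99)
  b <- simulate_group(ag, 50, dt = 0.01, t_max = 10, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_group(ag, 50, dt = 0.01, t_max = 10, seed = 100)
  expect_false(identical(a$rt, c_$rt))
  # single-trial wrapper is the same engine
  d <- simulate_group_trial(ag, dt = 0.01, t_max = 10, seed = 99)
  e <- simulate_group(ag, 1, dt = 0.01, t_max = 10, seed = 99)
  expect_identical(as.data.frame(d), as.data.frame(e))
})

test_that("agents that never reach a boundary are censored, not forced", {
  ag <- ddm_agents(delta_p = 0, s = 0, noise_sd = 0.01)
  tr <- simulate_group(ag, 5, dt = 0.01, t_max = 0.5, seed = 3)
  expect_true(all(is.na(tr$choice)))
  expect_true(all(is.na(tr$rt)))
  expect_true(all(is.na(tr$rank)))
})

test_that("drift bookkeeping uses only decisions made strictly before a step", {
  ag <- ddm_agents(delta_p = c(0.5, 0.4, 0.3, 0.2, 0.1), s = 0.5)
  tr <- simulate_group_trial(ag, dt = 0.01, t_max = 20, seed = 17,
                             keep_path = TRUE)
  path <- attr(tr, "path")
  expect_false(is.null(path))
  dec <- tr[!is.na(tr$rt), ]
  for (i in seq_len(nrow(path))) {
    visible_A <- sum(dec$choice == "A" & dec$rt <= path$t[i] - 0.01 + 1e-9)
    visible_B <- sum(dec$choice == "B" & dec$rt <= path$t[i] - 0.01 + 1e-9)
    expect_identical(path$n_A_used[i], visible_A)
    expect_identical(path$n_B_used[i], visible_B)
  }
  # counts stamped at decision match the bookkeeping at that agent's last step
  for (j in seq_len(nrow(dec))) {
    expect_identical(dec$n_A_at_decision[j],
                     sum(dec$choice == "A" & dec$rt <= dec$rt[j] - 0.01 + 1e-9))
  }
})

test_that("decision ranks are a time-consistent permutation", {
  ag <- ddm_agents(delta_p = 0.3, s = 0.4, n_agents = 5)
  tr <- simulate_group(ag, 200, dt = 0.005, t_max = 20, seed = 5)
  for (trl in split(tr, tr$trial)) {
    d <- trl[!is.na(trl$rt), ]
    if (!nrow(d)) next
    expect_setequal(d$rank, seq_len(nrow(d)))
    o <- order(d$rank)
    expect_true(all(diff(d$rt[o]) >= 0))
    # ties broken by agent index
    same <- split(d$agent[o], d$rt[o])
    expect_true(all(vapply(same, function(z) all(diff(z) > 0), logical(1))))
  }
})

test_that("mirrored parameters swap choice frequencies", {
  n <- 2e4
  a <- simulate_group(ddm_agents(delta_p = 0.4, start = 0.1, s = 0),
                      n, dt = 0.005, t_max = 25, seed = 8, crossing = "bridge")
  b <- simulate_group(ddm_agents(delta_p = -0.4, start = -0.1, s = 0),
                      n, dt = 0.005, t_max = 25, seed = 8, crossing = "bridge")
  pA <- mean(a$choice == "A", na.rm = TRUE)
  pB <- mean(b$choice == "B", na.rm = TRUE)
  expect_lt(abs(pA - pB), 3 * sqrt(2) * prop_se(pA, n))
})

test_that("simulated absorption matches the closed form for asocial agents", {
  # light version of the oracle-equivalence check (full size in acceptance)
  n <- 2e4
  or <- fpt_constant_drift(0.5, 0, -1, 1, 1)
  tr <- simulate_group(ddm_agents(delta_p = 0.5, s = 0), n, dt = 0.004,
                       t_max = 25, seed = 13, crossing = "bridge")
  p <- mean(tr$choice == "A", na.rm = TRUE)
  expect_lt(abs(p - or$p_upper), 3 * prop_se(or$p_upper, n))
  expect_lt(abs(mean(tr$rt, na.rm = TRUE) - or$mean_fpt), 0.02 * or$mean_fpt +
              3 * sd(tr$rt, na.rm = TRUE) / sqrt(n))
})

test_that("halving dt leaves the absorption probability unchanged within noise", {
  n <- 2e4
  p <- vapply(c(0.004, 0.002), function(dt)
    mean(simulate_group(ddm_agents(delta_p = 0.3, s = 0), n, dt = dt,
                        t_max = 25, seed = 21,
                        crossing = "bridge")$choice == "A", na.rm = TRUE),
    numeric(1))
  expect_lt(abs(diff(p)), 3 * sqrt(2) * prop_se(mean(p), n))
})
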