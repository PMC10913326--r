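test_that("majority size is the signed difference of decided counts", {
  expect_identical(majority_size(3, 1), 2)
  expect_identical(majority_size(0, 0), 0)
  expect_identical(majority_size(1, 4), -3)
  expect_error(majority_size(-1, 0), "non-negative")
})

test_that("social drift is a sign-preserving power of the majority", {
  expect_identical(social_drift(0, s = 0.5, q = 1), 0)
  expect_identical(social_drift(2, s = 0.5, q = 1), 1)
  expect_equal(social_drift(-2, s = 0.5, q = 0.5), -0.5 * sqrt(2))
  # odd function of M for any exponent
  for (q in c(0.5, 1, 2, 3.7))
    expect_equal(social_drift(-3, 0.4, q), -social_drift(3, 0.4, q))
  expect_error(social_drift(2, 0.5, q = 0), "q must be")
  expect_error(social_drift(2, 0.5, q = -1), "q must be")
})

test_that("effective drift sums personal and social components", {
  st <- function(a, b) list(n_A = a, n_B = b)
  expect_equal(effective_drift(ddm_agents(delta_p = 0.3, s = 0), st(4, 0)), 0.3)
  expect_equal(effective_drift(ddm_agents(delta_p = 0.3, s = 0.2), st(2, 0)), 0.7)
  expect_equal(effective_drift(ddm_agents(delta_p = 0.3, s = 0.2), st(0, 3)), -0.3)
})

test_that("effective drift weakly increases with the majority when s > 0", {
  ag <- ddm_agents(delta_p = 0.1, s = 0.3, q = 0.7)
  Ms <- -4:4
  d <- vapply(Ms, function(m)
    effective_drift(ag, list(n_A = max(m, 0), n_B = max(-m, 0))), numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_true(all(diff(d)[Ms[-1] != 0 | Ms[-length(Ms)] != 0] >= 0))
  expect_lt(d[Ms == -1], d[Ms == 1])  # strict across a sign change
})

test_that("evidence step has the prescribed mean and diffusion scale", {
  # noise-free drift step and zero-drift identity are exact
  old <- 0.5
  expect_equal(step_evidence(0, 1, 0.01, noise_sd = 0), 0.01)
  expect_equal(step_evidence(old, 0, 0.01, noise_sd = 0), old)
  expect_error(step_evidence(0, 1, dt = 0), "dt must be")
  # Monte-Carlo oracle: mean delta*dt, SD sqrt(dt)*noise_sd
  set.seed(11)
  x <- step_evidence(rep(0, 1e5), 2, 0.01, noise_sd = 1)
  expect_lt(abs(mean(x) - 0.02), 3 * 0.1 / sqrt(1e5))
  expect_lt(abs(sd(x) - 0.1), 3 * 0.1 / sqrt(2 * 1e5))
})

test_that("closed-form absorption matches the Wiener formulas", {
  o <- fpt_constant_drift(0, 0, -1, 1, 1)
  expect_equal(o$p_upper, 0.5)
  expect_equal(o$mean_fpt, 1)
  expect_equal(fpt_constant_drift(0, 0.5, 0, 1, 1)$p_upper, 0.5)
  o2 <- fpt_constant_drift(1, 0.5, 0, 1, 1)
  expect_equal(o2$p_upper, (1 - exp(-1)) / (1 - exp(-2)), tolerance = 1e-12)
  # drift-free limit is continuous
  o3 <- fpt_constant_drift(1e-13, 0, -1, 1, 1)
  expect_equal(o3$p_upper, 0.5, tolerance = 1e-9)
  expect_equal(o3$mean_fpt, 1, tolerance = 1e-9)
  # strongly negative drift stays a probability
  o4 <- fpt_constant_drift(-500, 0, -1, 1, 1)
  expect_gte(o4$p_upper, 0)
  expect_lte(o4$p_upper, 1e-10)
  expect_error(fpt_constant_drift(0, 1, -1, 1, 1), "strictly between")
  expect_error(fpt_constant_drift(0, 0, -1, 1, 0), "noise_sd")
})

test_that("agent parameter validation enforces the model invariants", {
  expect_error(ddm_agents(start = 2, threshold_upper = 1), "start")
  expect_error(ddm_agents(noise_sd = 0), "noise_sd")
  expect_error(ddm_agents(q = 0), "q must be")
  ag <- ddm_agents(delta_p = c(0.1, 0.2), s = 0.3)
  expect_equal(nrow(ag), 2)
  expect_equal(ag$s, c(0.3, 0.3))
})
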