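#' Parameter-recovery harnesses
#'
#' Simulate data from known ("true") parameters, fit the model back, and
#' report true vs. estimated values per replicate in a machine-readable
#' table — the standard check that an estimator is implemented correctly
#' and the parameters are identifiable at the design's sample sizes.
#'
#' `rl_recovery()` simulates `n_groups` independent groups of social
#' reinforcement learners with shared parameters and fits each group with
#' [rl_fit()]. `ddm_recovery()` simulates `n_datasets` batches of group
#' trials from the social DDM and fits `delta_p` and `s` (shared across
#' agents) to each batch with [ddm_fit()].
#'
#' @param agents true parameter table ([rl_agents()] / [ddm_agents()]);
#'   the first row is used as the shared truth.
#' @param env payoff environment for the RL harness.
#' @param n_groups,n_datasets number of independent replicate fits.
#' @param n_trials group trials per DDM dataset.
#' @param seed integer seed; replicate r uses `seed + r` for its data and
#'   fit, so reports are reproducible.
#' @param n_starts optimiser starts passed to the fitter.
#' @param dt,t_max,crossing DDM simulation settings.
#' @param n_bins likelihood grid bins for the DDM fits.
#' @return A `data.frame` of class `recovery_report` with columns
#'   `replicate`, `parameter`, `true`, `estimate`, `converged`.
#' @seealso [recovery_mae()]
#' @export
rl_recovery <- function(agents, env = rl_env(), n_groups = 12, seed = 1,
                        n_starts = 4) {
  agents <- as_rl_agents(agents)
  truth <- unlist(agents[1, c("alpha", "beta", "sigma", "theta")])
  out <- vector("list", n_groups)
  for (r in seq_len(n_groups)) {
    tr <- simulate_rl_group(agents, env, seed = seed + r)
    fit <- rl_fit(tr, model = "social", n_starts = n_starts,
                  seed = seed + r, validate = FALSE)
    out[[r]] <- data.frame(replicate = r, parameter = names(truth),
                           true = as.numeric(truth),
                           estimate = as.numeric(fit$estimates[names(truth)]),
                           converged = fit$converged)
  }
  res <- do.call(rbind, out)
  class(res) <- c("recovery_report", "data.frame")
  res
}

#' @rdname rl_recovery
#' @export
ddm_recovery <- function(agents, n_datasets = 4, n_trials = 80, seed = 1,
                         n_starts = 2, dt = 0.002, t_max = 20,
                         crossing = "bridge", n_bins = 50) {
  agents <- as_ddm_agents(agents)
  truth <- unlist(agents[1, c("delta_p", "s")])
  fixed <- agents[1, , drop = FALSE]
  fixed$delta_p <- 0.2; fixed$s <- 0.1       # neutral fit starting values
  out <- vector("list", n_datasets)
  for (r in seq_len(n_datasets)) {
    tr <- simulate_group(agents, n_trials = n_trials, dt = dt, t_max = t_max,
                         seed = seed + r, crossing = crossing)
    set.seed(seed + 1000 + r)                # start jitter
    fit <- ddm_fit(tr, fixed = fixed, n_starts = n_starts, n_bins = n_bins,
                   t_max = t_max)
    out[[r]] <- data.frame(replicate = r, parameter = names(truth),
                           true = as.numeric(truth),
                           estimate = as.numeric(fit$estimates[names(truth)]),
                           converged = fit$converged)
  }
  res <- do.call(rbind, out)
  class(res) <- c("recovery_report", "data.frame")
  res
}

#' Median absolute recovery error per parameter
#'
#' @param report a `recovery_report` from [rl_recovery()] or
#'   [ddm_recovery()].
#' @return Named numeric vector of median absolute errors.
#' @export
recovery_mae <- function(report) {
  err <- abs(report$estimate - report$true)
  out <- tapply(err, report$parameter, stats::median)
  out[unique(report$parameter)]
}
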