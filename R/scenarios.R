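#' Canonical five-agent simulation scenarios
#'
#' `ddm_scenarios()` returns the three social-DDM group setups that
#' illustrate how individual cognitive differences shape collective
#' outcomes; `rl_scenarios()` returns the three social-RL setups spanning
#' asocial learning, weak-conformist and strong-conformist social learning
#' under a mid-session payoff reversal.
#'
#' The RL parameter values are the canonical published settings: five
#' agents, option payoff means 15 (A) and 20 (B) points with SD 3 reversed
#' after half of the 100 trials, `alpha = 0.3`, `beta = 0.18`, and panels
#' `sigma = 0`, `(sigma = 0.3, theta = 1.5)`, `(sigma = 0.7, theta = 5)`.
#' The DDM panels are only qualitatively specified in the source figures,
#' so the numeric values here (drifts 0.1-0.5, thresholds 0.4-1.6,
#' `s = 0.5`) are fixed package choices, documented in the methods
#' vignette; analyses should rely only on the directional contrasts they
#' illustrate.
#'
#' * `homogeneous`: identical agents (`delta_p = 0.3`, thresholds +-1) with
#'   social coupling `s = 0.5` — the baseline cascade setup.
#' * `heterogeneous_drift`: personal drifts 0.1-0.5 (varying "ability"),
#'   shared thresholds — accurate agents decide early and inform the rest.
#' * `heterogeneous_threshold`: shared drift, thresholds +-0.4 to +-1.6
#'   (varying speed-accuracy trade-offs) — hasty agents decide early and
#'   can mislead the rest.
#'
#' @return A named list of `scenario` objects (fields `name`, `family`,
#'   `agents`, and per family `dt`/`t_max`/`n_trials` or
#'   `env`/`n_replicates`).
#' @seealso [simulate_scenario()]
#' @export
ddm_scenarios <- function() {
  base <- list(dt = 0.005, t_max = 20, n_trials = 1000)
  mk <- function(name, agents)
    structure(c(list(name = name, family = "ddm", agents = agents), base),
              class = "scenario")
  list(
    homogeneous = mk("homogeneous",
      ddm_agents(delta_p = 0.3, s = 0.5, q = 1, n_agents = 5)),
    heterogeneous_drift = mk("heterogeneous_drift",
      ddm_agents(delta_p = c(0.1, 0.2, 0.3, 0.4, 0.5), s = 0.5, q = 1)),
    heterogeneous_threshold = mk("heterogeneous_threshold",
      ddm_agents(delta_p = 0.3, s = 0.5, q = 1,
                 threshold_upper = c(0.4, 0.7, 1.0, 1.3, 1.6),
                 threshold_lower = -c(0.4, 0.7, 1.0, 1.3, 1.6)))
  )
}

#' @rdname ddm_scenarios
#' @export
rl_scenarios <- function() {
  env <- rl_env(means = c(A = 15, B = 20), sd = 3, n_trials = 100,
                changepoint = 50)
  mk <- function(name, sigma, theta)
    structure(list(name = name, family = "rl",
                   agents = rl_agents(alpha = 0.3, beta = 0.18, sigma = sigma,
                                      theta = theta, q0 = 0, n_agents = 5),
                   env = env, n_replicates = 500),
              class = "scenario")
  list(
    asocial = mk("asocial", sigma = 0, theta = 1),
    weak_conformist = mk("weak_conformist", sigma = 0.3, theta = 1.5),
    strong_conformist = mk("strong_conformist", sigma = 0.7, theta = 5)
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario '", x$name, "' (", x$family, ")> ", nrow(x$agents),
      " agents\n", sep = "")
  invisible(x)
}

#' Run a named scenario
#'
#' Simulates a scenario object from [ddm_scenarios()] or [rl_scenarios()],
#' optionally overriding the replicate count or agent parameters (e.g. an
#' `s = 0` control group for the DDM scenarios). Regenerating with the same
#' seed reproduces the trace bit-identically.
#'
#' @param scenario a `scenario` object.
#' @param n number of group trials (DDM) or replicate groups (RL);
#'   default from the scenario.
#' @param seed integer seed.
#' @param agents optional replacement agent table (same class as the
#'   scenario's).
#' @param crossing boundary-crossing detection for DDM scenarios (see
#'   [simulate_group()]).
#' @return A `group_ddm_trace` (DDM) or `rl_replicates` (RL) object.
#' @export
simulate_scenario <- function(scenario, n = NULL, seed = NULL, agents = NULL,
                              crossing = "step") {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(agents)) agents <- scenario$agents
  if (scenario$family == "ddm") {
    if (is.null(n)) n <- scenario$n_trials
    simulate_group(agents, n_trials = n, dt = scenario$dt,
                   t_max = scenario$t_max, seed = seed, crossing = crossing)
  } else {
    if (is.null(n)) n <- scenario$n_replicates
    simulate_rl_groups(agents, scenario$env, n_replicates = n, seed = seed)
  }
}

#' Deterministic summaries of simulation traces
#'
#' Reduces a trace to the summary statistics the scenario analyses are
#' built on, in long format (`metric`, `group`, `value`). Summaries are
#' invariant to row order and an empty trace yields an empty frame with the
#' same columns.
#'
#' For group-DDM traces: choice accuracy (share of "A", the designated
#' correct option) and mean RT by decision rank and by agent, RT quantiles
#' (10/50/90%) by agent, and the censoring rate. For RL traces: the
#' proportion choosing "A" per trial, the post-reversal adaptation share
#' ([adaptation_share()]) and the first near-unanimity trial
#' ([agreement_trial()]).
#'
#' @param trace a `group_ddm_trace`, `rl_trace`, or a plain data.frame read
#'   back from a trace CSV (the family is detected from the columns).
#' @return A `data.frame(metric, group, value)`.
#' @export
summarize_trace <- function(trace) {
  if (!nrow(trace))
    return(data.frame(metric = character(), group = character(),
                      value = numeric()))
  if ("payoff" %in% names(trace)) summarize_rl_df(trace)
  else summarize_ddm_df(trace)
}

summarize_ddm_df <- function(x) {
  x <- x[order(x$trial, x$agent), ]
  dec <- x[!is.na(x$choice), ]
  row <- function(metric, group, value)
    data.frame(metric = metric, group = as.character(group), value = value)
  out <- list()
  if (nrow(dec)) {
    acc_rank <- tapply(dec$choice == "A", dec$rank, mean)
    out$a <- row("accuracy_by_rank", names(acc_rank), as.numeric(acc_rank))
    rt_rank <- tapply(dec$rt, dec$rank, mean)
    out$b <- row("mean_rt_by_rank", names(rt_rank), as.numeric(rt_rank))
    acc_ag <- tapply(dec$choice == "A", dec$agent, mean)
    out$c <- row("accuracy_by_agent", names(acc_ag), as.numeric(acc_ag))
    rt_ag <- tapply(dec$rt, dec$agent, mean)
    out$d <- row("mean_rt_by_agent", names(rt_ag), as.numeric(rt_ag))
    for (qq in c(0.1, 0.5, 0.9)) {
      rq <- tapply(dec$rt, dec$agent, quantile, probs = qq, names = FALSE)
      out[[paste0("q", qq)]] <- row(sprintf("rt_q%02d_by_agent", qq * 100),
                                    names(rq), as.numeric(rq))
    }
  }
  out$z <- row("censored_rate", "all", mean(is.na(x$choice)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

summarize_rl_df <- function(x) {
  x <- x[order(x$trial, x$agent), ]
  row <- function(metric, group, value)
    data.frame(metric = metric, group = as.character(group), value = value)
  pA <- tapply(x$choice == "A", x$trial, mean)
  n_tr <- max(x$trial)
  n_ag <- length(unique(x$agent))
  chmat <- matrix(match(x$choice, c("A", "B")), ncol = n_ag, byrow = TRUE)
  share <- apply(chmat, 1, function(z) max(tabulate(z, 2)) / length(z))
  agree <- which(share >= 0.9)
  res <- rbind(row("prop_A_by_trial", names(pA), as.numeric(pA)),
               row("adaptation_share", "final_quarter",
                   mean((x$choice == "A")[x$trial > n_tr * 0.75])),
               row("agreement_trial", "first",
                   if (length(agree)) agree[1] else n_tr))
  rownames(res) <- NULL
  res
}
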