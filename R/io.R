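#' Read and write trace CSV files
#'
#' `write_trace_csv()` writes a simulation trace in the documented CSV
#' dialect (one row per agent x trial; a `seed` column is appended so files
#' are self-describing, and for multi-replicate RL objects a leading
#' `replicate` column). `read_trial_table()` reads such a file back as a
#' plain data.frame for summarising or fitting.
#'
#' @param trace a `group_ddm_trace`, `rl_trace` or `rl_replicates` object.
#' @param path file path.
#' @return `read_trial_table()` returns a data.frame; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "rl_replicates")) {
    n_rep <- dim(trace$choices)[1]
    dfs <- lapply(seq_len(n_rep), function(r) {
      d <- rl_replicate_trace(trace, r)
      cbind(replicate = r, as.data.frame(d))
    })
    df <- do.call(rbind, dfs)
    df$seed <- if (is.null(trace$seed)) NA_integer_ else trace$seed
  } else {
    df <- as.data.frame(trace)
    sd_ <- attr(trace, "seed")
    df$seed <- if (is.null(sd_)) NA_integer_ else sd_
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trial_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write scenario configuration files
#'
#' Scenario configurations are YAML: a `family` field (`ddm` or `rl`), an
#' `agents` list with one map of parameters per agent, and either
#' `dt`/`t_max`/`n_trials` (DDM) or an `env` map with
#' `means`/`sd`/`n_trials`/`changepoint` plus `n_replicates` (RL). An
#' optional `seed` records the intended seed. [ddm_scenarios()] objects can
#' be round-tripped through these files.
#'
#' @param path file path.
#' @param scenario a `scenario` object.
#' @return `read_scenario_config()` returns a `scenario`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$family) || !cfg$family %in% c("ddm", "rl"))
    stop("config must set family: ddm or rl")
  ag_df <- do.call(rbind, lapply(cfg$agents, as.data.frame))
  if (cfg$family == "ddm") {
    agents <- do.call(ddm_agents, c(as.list(ag_df), list(n_agents = nrow(ag_df))))
    structure(list(name = cfg$name %||% "config", family = "ddm",
                   agents = agents,
                   dt = cfg$dt %||% 0.001, t_max = cfg$t_max %||% 20,
                   n_trials = cfg$n_trials %||% 1,
                   seed = cfg$seed),
              class = "scenario")
  } else {
    agents <- do.call(rl_agents, c(as.list(ag_df), list(n_agents = nrow(ag_df))))
    e <- cfg$env
    env <- rl_env(means = unlist(e$means), sd = e$sd %||% 3,
                  n_trials = e$n_trials %||% 100,
                  changepoint = e$changepoint %||% floor((e$n_trials %||% 100) / 2))
    structure(list(name = cfg$name %||% "config", family = "rl",
                   agents = agents, env = env,
                   n_replicates = cfg$n_replicates %||% 1,
                   seed = cfg$seed),
              class = "scenario")
  }
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  ag <- as.data.frame(scenario$agents)
  ag$agent <- NULL
  cfg <- list(name = scenario$name, family = scenario$family,
              agents = lapply(seq_len(nrow(ag)), function(i) as.list(ag[i, ])))
  if (scenario$family == "ddm") {
    cfg$dt <- scenario$dt; cfg$t_max <- scenario$t_max
    cfg$n_trials <- scenario$n_trials
  } else {
    e <- scenario$env
    cfg$env <- list(means = as.list(e$means), sd = e$sd,
                    n_trials = e$n_trials, changepoint = e$changepoint)
    cfg$n_replicates <- scenario$n_replicates
  }
  if (!is.null(scenario$seed)) cfg$seed <- scenario$seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
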