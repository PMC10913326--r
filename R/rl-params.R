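#' Per-agent parameters of the social reinforcement-learning model
#'
#' One row per agent; scalar arguments are recycled.
#'
#' @param alpha updating rate in `[0, 1]`: the weight of the most recent
#'   reward-prediction error in the value update.
#' @param beta exploration/exploitation rate (>= 0): softmax sensitivity to
#'   latent-value differences; 0 means random choice.
#' @param sigma social-learning weight in `[0, 1]`: mixture weight on the
#'   frequency-dependent copying probability vs. the own-experience softmax.
#' @param theta conformity exponent (> 0): values above 1 over-weight
#'   majorities (conformity), below 1 under-weight them (anticonformity).
#' @param q0 initial latent value per option (payoff units).
#' @param n_agents number of agents; defaults to the longest argument.
#' @return A `data.frame` of class `rl_agents`.
#' @examples
#' rl_agents(alpha = 0.3, beta = 0.18, sigma = 0.3, theta = 1.5, n_agents = 5)
#' @export
rl_agents <- function(alpha = 0.3, beta = 0.18, sigma = 0, theta = 1,
                      q0 = 0, n_agents = NULL) {
  args <- list(alpha = alpha, beta = beta, sigma = sigma, theta = theta,
               q0 = q0)
  if (is.null(n_agents)) n_agents <- max(lengths(args))
  if (n_agents < 1) stop("need at least one agent")
  bad <- names(args)[!vapply(args, function(a)
    is.numeric(a) && all(is.finite(a)) && length(a) %in% c(1L, n_agents),
    logical(1))]
  if (length(bad))
    stop("invalid or wrongly sized parameter(s): ", paste(bad, collapse = ", "))
  out <- as.data.frame(lapply(args, rep_len, n_agents))
  if (any(out$alpha < 0 | out$alpha > 1)) stop("alpha must be in [0, 1]")
  if (any(out$beta < 0)) stop("beta must be >= 0")
  if (any(out$sigma < 0 | out$sigma > 1)) stop("sigma must be in [0, 1]")
  if (any(out$theta <= 0)) stop("theta must be > 0")
  out$agent <- seq_len(n_agents)
  class(out) <- c("rl_agents", "data.frame")
  out
}

#' @export
print.rl_agents <- function(x, ...) {
  cat("<rl_agents> ", nrow(x), " agent(s)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

as_rl_agents <- function(x) {
  if (inherits(x, "rl_agents")) return(x)
  do.call(rl_agents, c(as.list(x[setdiff(names(x), "agent")]),
                       list(n_agents = nrow(x))))
}

#' Payoff environment for the social reinforcement-learning model
#'
#' A two-option (by default) Gaussian bandit whose option means are permuted
#' once, after the changepoint trial: trials `1..changepoint` use `means` as
#' given, later trials use the reversed vector. The canonical setup pays on
#' average 15 points for option A and 20 for option B (SD 3) and reverses at
#' the midpoint, so the initially better option becomes the worse one.
#'
#' @param means payoff mean per option (points), in option order (A, B, ...).
#' @param sd payoff standard deviation (points, >= 0), shared by the options.
#' @param n_trials total number of trials.
#' @param changepoint last trial of the initial payoff regime, in
#'   `[1, n_trials]`.
#' @return A list of class `rl_env`.
#' @examples
#' rl_env(means = c(A = 15, B = 20), sd = 3, n_trials = 100, changepoint = 50)
#' @export
rl_env <- function(means = c(A = 15, B = 20), sd = 3, n_trials = 100,
                   changepoint = floor(n_trials / 2)) {
  if (length(means) < 2) stop("need at least two options")
  if (sd < 0) stop("sd must be >= 0")
  if (changepoint < 1 || changepoint > n_trials)
    stop("changepoint must lie in [1, n_trials]")
  if (is.null(names(means))) names(means) <- LETTERS[seq_along(means)]
  structure(list(n_options = length(means), means = means, sd = sd,
                 n_trials = as.integer(n_trials),
                 changepoint = as.integer(changepoint)),
            class = "rl_env")
}

#' @export
print.rl_env <- function(x, ...) {
  cat("<rl_env> ", x$n_options, " options, means (",
      paste(x$means, collapse = "/"), "), sd ", x$sd, ", ",
      x$n_trials, " trials, reversal after trial ", x$changepoint,
      "\n", sep = "")
  invisible(x)
}

# option means in force on a given trial (1-based), reversed past changepoint
env_means_at <- function(env, trial) {
  if (trial <= env$changepoint) env$means else rev(env$means)
}
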