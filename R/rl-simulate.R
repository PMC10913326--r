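#' Simulate replicate groups of social reinforcement learners
#'
#' On every trial each agent draws a choice from the social-learning mixture
#' ([combined_choice_prob()]) evaluated at its current latent values and the
#' counts of the *other* members' choices on the immediately preceding trial
#' (trial 1 is asocial — there is nothing to copy yet), receives a Gaussian
#' payoff from the environment (option means permuted after the
#' changepoint), and Rescorla-Wagner-updates the chosen option's value.
#' Counts come from the previous trial only, not a cumulative history, and
#' exclude the agent's own previous choice unless `include_self = TRUE`.
#'
#' Random draws are consumed in a fixed order (per trial: one uniform per
#' replicate x agent for the choices, then one normal per replicate x agent
#' for the payoffs), so runs are bit-reproducible given the seed and
#' replicate 1 of a multi-replicate run can be reproduced by an independent
#' single-group implementation under the same seed discipline.
#'
#' @param agents an [rl_agents()] table.
#' @param env an [rl_env()]; only two-option environments are supported by
#'   the simulator.
#' @param n_replicates number of independent replicate groups.
#' @param seed optional integer seed.
#' @param include_self count the agent's own previous choice among the
#'   social counts (default `FALSE`: only the other N-1 members are
#'   observed).
#' @return For `simulate_rl_group()` (one group) a `data.frame` of class
#'   `rl_trace`, one row per agent x trial, with columns `trial`, `agent`,
#'   `choice` ("A"/"B"), `payoff`, `Q_A`, `Q_B` (latent values *before* the
#'   choice), `p_asocial_A`, `p_social_A` (`NA` when no social information),
#'   `p_combined_A`, `n_A_prev`, `n_B_prev`. For `simulate_rl_groups()` a
#'   list of class `rl_replicates` holding choice and payoff arrays
#'   `[replicate, trial, agent]` plus the configuration.
#' @examples
#' ag <- rl_agents(alpha = 0.3, beta = 0.18, sigma = 0.3, theta = 1.5,
#'                 n_agents = 5)
#' tr <- simulate_rl_group(ag, rl_env(n_trials = 20), seed = 1)
#' head(tr)
#' @export
simulate_rl_groups <- function(agents, env, n_replicates = 1, seed = NULL,
                               include_self = FALSE) {
  agents <- as_rl_agents(agents)
  stopifnot(inherits(env, "rl_env"))
  if (env$n_options != 2)
    stop("the group simulator supports two-option environments")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n_ag <- nrow(agents)
  n_rep <- as.integer(n_replicates)
  n_tr <- env$n_trials
  bycol <- function(v) matrix(v, n_rep, n_ag, byrow = TRUE)
  al <- bycol(agents$alpha); be <- bycol(agents$beta)
  si <- bycol(agents$sigma); th <- bycol(agents$theta)

  QA <- bycol(agents$q0); QB <- bycol(agents$q0)
  prev <- matrix(0L, n_rep, n_ag)            # 0 none, 1 A, 2 B
  choices <- array(NA_integer_, c(n_rep, n_tr, n_ag))
  payoffs <- array(NA_real_, c(n_rep, n_tr, n_ag))
  qa_rec <- array(NA_real_, c(n_rep, n_tr, n_ag))
  qb_rec <- array(NA_real_, c(n_rep, n_tr, n_ag))
  pa_rec <- array(NA_real_, c(n_rep, n_tr, n_ag))
  ps_rec <- array(NA_real_, c(n_rep, n_tr, n_ag))
  pc_rec <- array(NA_real_, c(n_rep, n_tr, n_ag))
  na_rec <- array(NA_integer_, c(n_rep, n_tr, n_ag))
  nb_rec <- array(NA_integer_, c(n_rep, n_tr, n_ag))

  for (t in seq_len(n_tr)) {
    mns <- env_means_at(env, t)
    p_asoc <- stats::plogis(be * (QA - QB))
    if (t == 1L) {
      nA <- matrix(0L, n_rep, n_ag); nB <- matrix(0L, n_rep, n_ag)
    } else {
      isA <- prev == 1L; isB <- prev == 2L
      nA <- matrix(rowSums(isA), n_rep, n_ag)
      nB <- matrix(rowSums(isB), n_rep, n_ag)
      if (!include_self) { nA <- nA - isA; nB <- nB - isB }
    }
    wA <- ifelse(nA == 0L, 0, nA^th)
    wB <- ifelse(nB == 0L, 0, nB^th)
    den <- wA + wB
    p_soc <- ifelse(den > 0, wA / den, NA_real_)
    p_comb <- ifelse(is.na(p_soc), p_asoc,
                     (1 - si) * p_asoc + si * p_soc)
    ch <- ifelse(matrix(runif(n_rep * n_ag), n_rep, n_ag) < p_comb, 1L, 2L)
    pay <- rnorm(n_rep * n_ag,
                 mean = mns[as.vector(ch)], sd = env$sd)
    pay <- matrix(pay, n_rep, n_ag)

    qa_rec[, t, ] <- QA; qb_rec[, t, ] <- QB
    pa_rec[, t, ] <- p_asoc; ps_rec[, t, ] <- p_soc; pc_rec[, t, ] <- p_comb
    na_rec[, t, ] <- nA; nb_rec[, t, ] <- nB
    choices[, t, ] <- ch; payoffs[, t, ] <- pay

    chA <- ch == 1L
    QA <- ifelse(chA, QA + al * (pay - QA), QA)
    QB <- ifelse(!chA, QB + al * (pay - QB), QB)
    prev <- ch
  }

  structure(list(choices = choices, payoffs = payoffs,
                 Q_A = qa_rec, Q_B = qb_rec,
                 p_asocial_A = pa_rec, p_social_A = ps_rec,
                 p_combined_A = pc_rec,
                 n_A_prev = na_rec, n_B_prev = nb_rec,
                 agents = agents, env = env,
                 include_self = include_self, seed = seed),
            class = "rl_replicates")
}

#' @rdname simulate_rl_groups
#' @export
simulate_rl_group <- function(agents, env, seed = NULL,
                              include_self = FALSE) {
  reps <- simulate_rl_groups(agents, env, n_replicates = 1, seed = seed,
                             include_self = include_self)
  rl_replicate_trace(reps, 1L)
}

#' Extract one replicate of an `rl_replicates` object as a tidy trace
#'
#' @param reps an object from [simulate_rl_groups()].
#' @param replicate replicate index.
#' @return An `rl_trace` data.frame (see [simulate_rl_groups()]).
#' @export
rl_replicate_trace <- function(reps, replicate = 1L) {
  stopifnot(inherits(reps, "rl_replicates"))
  n_tr <- reps$env$n_trials
  n_ag <- nrow(reps$agents)
  grab <- function(a) as.vector(t(a[replicate, , ]))  # agent fastest
  out <- data.frame(
    trial = rep(seq_len(n_tr), each = n_ag),
    agent = rep(seq_len(n_ag), n_tr),
    choice = c("A", "B")[grab(reps$choices)],
    payoff = grab(reps$payoffs),
    Q_A = grab(reps$Q_A), Q_B = grab(reps$Q_B),
    p_asocial_A = grab(reps$p_asocial_A),
    p_social_A = grab(reps$p_social_A),
    p_combined_A = grab(reps$p_combined_A),
    n_A_prev = grab(reps$n_A_prev), n_B_prev = grab(reps$n_B_prev)
  )
  attr(out, "agents") <- reps$agents
  attr(out, "env") <- reps$env
  attr(out, "include_self") <- reps$include_self
  attr(out, "seed") <- reps$seed
  class(out) <- c("rl_trace", "data.frame")
  out
}

#' @export
print.rl_replicates <- function(x, ...) {
  cat("<rl_replicates> ", dim(x$choices)[1], " replicate group(s) x ",
      x$env$n_trials, " trials x ", nrow(x$agents), " agent(s)\n", sep = "")
  invisible(x)
}

#' @export
print.rl_trace <- function(x, ...) {
  cat("<rl_trace> ", max(x$trial), " trials x ", max(x$agent),
      " agent(s)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Post-reversal adaptation share
#'
#' Fraction of choices, inside a trailing window of the session, that land
#' on the option that is best *after* the payoff reversal. High values mean
#' the group tracked the environmental change; herding groups stay low.
#'
#' @param x an `rl_trace` or `rl_replicates` object.
#' @param window fraction of trials at the end of the session to score
#'   (default the final quarter).
#' @return A scalar for a single trace; one value per replicate group for
#'   `rl_replicates`.
#' @export
adaptation_share <- function(x, window = 0.25) {
  if (inherits(x, "rl_trace")) {
    env <- attr(x, "env")
    best <- which.max(rev(env$means))            # post-reversal best option
    keep <- x$trial > env$n_trials * (1 - window)
    return(mean((match(x$choice, c("A", "B"))) [keep] == best))
  }
  stopifnot(inherits(x, "rl_replicates"))
  env <- x$env
  best <- which.max(rev(env$means))
  keep <- seq_len(env$n_trials) > env$n_trials * (1 - window)
  apply(x$choices[, keep, , drop = FALSE], 1,
        function(m) mean(m == best))
}

#' First trial of near-unanimous group agreement
#'
#' Earliest trial on which at least `level` of the group chose the same
#' option; groups that never reach that level score the total number of
#' trials (an upper bound, so means remain comparable).
#'
#' @param x an `rl_trace` or `rl_replicates` object.
#' @param level required share of agents on one option (default 0.9).
#' @return Scalar (trace) or per-replicate vector (`rl_replicates`).
#' @export
agreement_trial <- function(x, level = 0.9) {
  first_tr <- function(chmat, n_tr) {                 # [trial, agent]
    share <- apply(chmat, 1, function(z) max(tabulate(z, 2)) / length(z))
    w <- which(share >= level)
    if (length(w)) w[1] else n_tr
  }
  if (inherits(x, "rl_trace")) {
    env <- attr(x, "env")
    n_ag <- max(x$agent)
    chmat <- matrix(match(x$choice, c("A", "B")), ncol = n_ag, byrow = TRUE)
    return(first_tr(chmat, env$n_trials))
  }
  stopifnot(inherits(x, "rl_replicates"))
  vapply(seq_len(dim(x$choices)[1]),
         function(r) first_tr(x$choices[r, , ], x$env$n_trials),
         numeric(1))
}
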