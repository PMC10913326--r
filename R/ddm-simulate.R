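#' Simulate trials of a socially coupled evidence-accumulation group
#'
#' Each undecided agent advances one Euler step per `dt` with an effective
#' drift equal to its personal drift plus the social drift implied by the
#' majority among members already decided at the *start* of the step.
#' Agents whose evidence reaches a boundary within a step are recorded as
#' decided at the step's end (upper boundary = choice "A", lower = "B"), and
#' their choice becomes visible to the others from the *next* step on.
#' Agents crossing in the same step are all stamped with that step's end
#' time; their decision rank is broken by agent index. Agents still
#' undecided at `t_max` are returned censored (`NA` choice and RT), not
#' forced.
#'
#' Boundary crossing is detected at step end by default
#' (`crossing = "step"`). With `crossing = "bridge"` a within-step
#' Brownian-bridge absorption draw is added for paths that end the step
#' inside the boundaries, removing the O(sqrt(dt)) boundary-displacement
#' bias of pure end-point monitoring; decisions are still stamped at step
#' end. The bridge option is what the closed-form oracle comparisons use.
#'
#' @param agents a [ddm_agents()] table.
#' @param n_trials number of independent group trials.
#' @param dt time step (> 0).
#' @param t_max trial horizon (time units).
#' @param seed optional integer seed; identical `(seed, arguments)` give a
#'   bit-identical trace.
#' @param crossing `"step"` (end-point detection) or `"bridge"`.
#' @param keep_path record the evidence paths and the majority counts each
#'   agent's drift used (only for `n_trials = 1`).
#' @return A `data.frame` of class `group_ddm_trace`, one row per
#'   agent x trial, with columns `trial`, `agent`, `choice` ("A"/"B"/`NA`),
#'   `rt`, `rank`, `n_A_at_decision`, `n_B_at_decision` (the counts the
#'   agent's drift saw on its crossing step), and attributes `dt`, `t_max`,
#'   `seed`, `crossing`. With `keep_path = TRUE` the path is attached as
#'   attribute `path` (columns `t`, `agent`, `L`, `n_A_used`, `n_B_used`).
#' @examples
#' ag <- ddm_agents(delta_p = 1, s = 0, noise_sd = 1e-9)
#' simulate_group(ag, n_trials = 1, dt = 0.01, t_max = 2, seed = 1)
#' @export
simulate_group <- function(agents, n_trials = 1, dt = 0.001, t_max = 20,
                           seed = NULL, crossing = c("step", "bridge"),
                           keep_path = FALSE) {
  agents <- as_ddm_agents(agents)
  crossing <- match.arg(crossing)
  if (dt <= 0) stop("dt must be > 0")
  if (t_max <= 0) stop("t_max must be > 0")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (keep_path && n_trials != 1)
    stop("keep_path is only supported for a single trial")
  if (!is.null(seed)) set.seed(seed)

  n_ag <- nrow(agents)
  up <- agents$threshold_upper
  lo <- agents$threshold_lower
  dp <- agents$delta_p
  s_ <- agents$s
  q_ <- agents$q
  sd_ <- agents$noise_sd
  social <- any(s_ != 0)

  L <- matrix(rep(agents$start, each = n_trials), n_trials, n_ag)
  choice <- matrix(NA_integer_, n_trials, n_ag)      # 1 = A, 2 = B
  rt <- matrix(NA_real_, n_trials, n_ag)
  seenA <- matrix(NA_integer_, n_trials, n_ag)
  seenB <- matrix(NA_integer_, n_trials, n_ag)
  active <- matrix(TRUE, n_trials, n_ag)
  nA_cnt <- integer(n_trials)
  nB_cnt <- integer(n_trials)
  sqdt <- sqrt(dt)
  n_steps <- as.integer(ceiling(t_max / dt - 1e-9))
  path <- if (keep_path) vector("list", n_steps) else NULL

  for (k in seq_len(n_steps)) {
    act <- which(active)
    if (!length(act)) break
    tr <- ((act - 1L) %% n_trials) + 1L
    ag <- ((act - 1L) %/% n_trials) + 1L
    nA_pre <- nA_cnt[tr]
    nB_pre <- nB_cnt[tr]
    drift <- dp[ag]
    if (social) {
      M <- nA_pre - nB_pre
      drift <- drift + s_[ag] * sign(M) * abs(M)^q_[ag]
    }
    Lold <- L[act]
    Lnew <- Lold + drift * dt + sqdt * sd_[ag] * rnorm(length(act))

    hit_up <- Lnew >= up[ag]
    hit_dn <- !hit_up & Lnew <= lo[ag]
    if (crossing == "bridge") {
      rem <- which(!hit_up & !hit_dn)
      if (length(rem)) {
        agr <- ag[rem]
        v <- sd_[agr]^2 * dt
        p_up <- exp(-2 * (up[agr] - Lold[rem]) * (up[agr] - Lnew[rem]) / v)
        bu <- runif(length(rem)) < p_up
        hit_up[rem[bu]] <- TRUE
        rem2 <- rem[!bu]
        if (length(rem2)) {
          agr2 <- ag[rem2]
          v2 <- sd_[agr2]^2 * dt
          p_dn <- exp(-2 * (Lold[rem2] - lo[agr2]) * (Lnew[rem2] - lo[agr2]) / v2)
          bd <- runif(length(rem2)) < p_dn
          hit_dn[rem2[bd]] <- TRUE
        }
      }
    }

    dec <- hit_up | hit_dn
    if (any(dec)) {
      idx <- act[dec]
      choice[idx] <- ifelse(hit_up[dec], 1L, 2L)
      rt[idx] <- k * dt
      seenA[idx] <- nA_pre[dec]
      seenB[idx] <- nB_pre[dec]
      active[idx] <- FALSE
      nA_cnt <- nA_cnt + tabulate(tr[dec & hit_up], n_trials)
      nB_cnt <- nB_cnt + tabulate(tr[dec & hit_dn], n_trials)
    }
    L[act] <- Lnew
    if (keep_path)
      path[[k]] <- data.frame(t = k * dt, agent = ag, L = Lnew,
                              n_A_used = nA_pre, n_B_used = nB_pre)
  }

  out <- data.frame(
    trial = rep(seq_len(n_trials), n_ag),
    agent = rep(seq_len(n_ag), each = n_trials),
    choice = c("A", "B")[as.vector(choice)],
    rt = as.vector(rt),
    n_A_at_decision = as.vector(seenA),
    n_B_at_decision = as.vector(seenB)
  )
  out <- out[order(out$trial, out$agent), , drop = FALSE]
  rownames(out) <- NULL
  # decision rank within trial: by time, ties by agent index; censored -> NA
  rk <- order(out$trial, out$rt, out$agent, na.last = TRUE)
  rank_vec <- integer(nrow(out))
  pos <- ave(ifelse(is.na(out$rt[rk]), NA_real_, out$rt[rk]),
             out$trial[rk], FUN = function(z) seq_along(z))
  rank_vec[rk] <- ifelse(is.na(out$rt[rk]), NA_integer_, as.integer(pos))
  out$rank <- rank_vec
  out <- out[, c("trial", "agent", "choice", "rt", "rank",
                 "n_A_at_decision", "n_B_at_decision")]
  attr(out, "dt") <- dt
  attr(out, "t_max") <- t_max
  attr(out, "seed") <- seed
  attr(out, "crossing") <- crossing
  attr(out, "n_agents") <- n_ag
  attr(out, "n_trials") <- n_trials
  if (keep_path) attr(out, "path") <- do.call(rbind, path)
  class(out) <- c("group_ddm_trace", "data.frame")
  out
}

#' Simulate a single group trial (optionally recording the paths)
#'
#' Thin wrapper around [simulate_group()] with `n_trials = 1`; with
#' `keep_path = TRUE` the returned trace carries the per-step evidence
#' states and the majority counts actually used by each undecided agent's
#' drift, which the bookkeeping invariants are tested against.
#'
#' @inheritParams simulate_group
#' @return A one-trial `group_ddm_trace` (see [simulate_group()]).
#' @export
simulate_group_trial <- function(agents, dt = 0.001, t_max = 20, seed = NULL,
                                 crossing = c("step", "bridge"),
                                 keep_path = FALSE) {
  simulate_group(agents, n_trials = 1, dt = dt, t_max = t_max, seed = seed,
                 crossing = crossing, keep_path = keep_path)
}

#' @export
print.group_ddm_trace <- function(x, ...) {
  cat("<group_ddm_trace> ", attr(x, "n_trials"), " trial(s) x ",
      attr(x, "n_agents"), " agent(s), dt = ", attr(x, "dt"),
      ", t_max = ", attr(x, "t_max"), ", crossing = ",
      attr(x, "crossing"), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
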