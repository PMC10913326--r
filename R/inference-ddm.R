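#' Numeric first-passage density under a piecewise-constant drift
#'
#' Propagates the evidence distribution of a diffusion with two absorbing
#' boundaries through a discrete-state Markov chain: the open interval
#' `(lower, upper)` is discretised into `n_bins` interior nodes with spacing
#' `h`, and each time step moves mass one node up, one node down, or keeps
#' it in place with probabilities matched to the step mean `delta * dt` and
#' variance `noise_sd^2 * dt`. Mass stepping beyond an extreme node is
#' absorbed at the corresponding boundary, giving the first-passage density
#' over (time step, boundary). The drift may change over time
#' (piecewise-constant schedule), which is how the social drift induced by
#' other members' observed decisions enters the likelihood.
#'
#' The explicit kernel is only a probability transition when
#' `noise_sd^2 * dt + (delta * dt)^2 <= h^2` and `|delta| * dt <= h`; unstable
#' combinations are rejected with guidance to shrink `dt` (or use fewer
#' bins).
#'
#' @param delta either a single drift rate or a `data.frame(time, delta)`
#'   with `time[1] == 0`: drift `delta[i]` applies from `time[i]` until the
#'   next breakpoint.
#' @param lower,upper absorbing boundaries.
#' @param start starting evidence, strictly inside the interval; placed on
#'   the grid by linear interpolation between the two neighbouring nodes.
#' @param noise_sd diffusion standard deviation (> 0).
#' @param dt grid time step.
#' @param n_bins number of interior evidence nodes (>= 50 recommended).
#' @param t_max propagation horizon.
#' @return A list of class `ddm_fpt_grid`: `times` (step-end times),
#'   `upper`, `lower` (absorbed mass per step and boundary), `survival`
#'   (mass still inside at `t_max`), `p_upper`, `p_lower` (total absorbed
#'   mass), and the grid constants.
#' @examples
#' g <- ddm_fpt_grid(0, -1, 1, 0, dt = 4e-4, n_bins = 60, t_max = 12)
#' g$p_upper  # ~0.5 by symmetry
#' @export
ddm_fpt_grid <- function(delta, lower, upper, start, noise_sd = 1,
                         dt = 1e-4, n_bins = 200, t_max = 20) {
  if (!(lower < start && start < upper))
    stop("start must lie strictly between the boundaries")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (dt <= 0 || t_max <= 0) stop("dt and t_max must be > 0")
  if (n_bins < 3) stop("n_bins must be >= 3")
  if (is.numeric(delta) && length(delta) == 1)
    delta <- data.frame(time = 0, delta = delta)
  if (!all(c("time", "delta") %in% names(delta)) || delta$time[1] != 0)
    stop("delta must be a scalar or a data.frame(time, delta) starting at 0")

  h <- (upper - lower) / (n_bins + 1)
  K <- as.integer(ceiling(t_max / dt - 1e-9))
  # drift in force during step k, i.e. on ((k-1) dt, k dt]
  dvec <- delta$delta[findInterval((seq_len(K) - 1) * dt, delta$time)]
  pu <- (noise_sd^2 * dt + (dvec * dt)^2) / (2 * h^2) + dvec * dt / (2 * h)
  pd <- (noise_sd^2 * dt + (dvec * dt)^2) / (2 * h^2) - dvec * dt / (2 * h)
  if (any(pu < 0 | pd < 0 | pu + pd > 1))
    stop("unstable discretization: per-step transition probabilities fall ",
         "outside [0, 1]; shrink dt (need noise_sd^2*dt + (delta*dt)^2 <= ",
         "h^2 and |delta|*dt <= h)")
  ps <- 1 - pu - pd

  m <- numeric(n_bins)
  j <- (start - lower) / h              # fractional node index
  j0 <- floor(j)
  w <- j - j0
  if (j0 >= 1 && j0 <= n_bins) m[j0] <- m[j0] + (1 - w)
  if (j0 + 1 >= 1 && j0 + 1 <= n_bins) m[j0 + 1] <- m[j0 + 1] + w

  up_abs <- numeric(K)
  dn_abs <- numeric(K)
  n <- n_bins
  for (k in seq_len(K)) {
    up_abs[k] <- m[n] * pu[k]
    dn_abs[k] <- m[1] * pd[k]
    m2 <- m * ps[k]
    m2[2:n] <- m2[2:n] + m[1:(n - 1)] * pu[k]
    m2[1:(n - 1)] <- m2[1:(n - 1)] + m[2:n] * pd[k]
    m <- m2
    if (sum(m) < 1e-14) { K <- k; up_abs <- up_abs[1:k]; dn_abs <- dn_abs[1:k]; break }
  }

  structure(list(times = seq_len(K) * dt, upper = up_abs, lower = dn_abs,
                 survival = sum(m), p_upper = sum(up_abs),
                 p_lower = sum(dn_abs), dt = dt, h = h, n_bins = n_bins,
                 t_max = t_max),
            class = "ddm_fpt_grid")
}

#' @export
print.ddm_fpt_grid <- function(x, ...) {
  cat("<ddm_fpt_grid> ", x$n_bins, " bins, dt = ", x$dt,
      ": p_upper = ", signif(x$p_upper, 6),
      ", p_lower = ", signif(x$p_lower, 6),
      ", survival = ", signif(x$survival, 6), "\n", sep = "")
  invisible(x)
}

# ---- social-DDM likelihood -------------------------------------------------

# Precompute, per agent x trial case, the social-drift multiplier
# g_k = sign(M)|M|^q in force during each grid step, the observed boundary
# and the grid step of the observed RT. Others' decision events are treated
# as exogenous covariates; an event at time tau is visible from step starts
# >= tau (matching the simulator's next-step visibility).
build_ddm_cases <- function(trace, q, dt, t_max) {
  K <- as.integer(ceiling(t_max / dt - 1e-9))
  trials <- split(seq_len(nrow(trace)), trace$trial)
  n_case <- nrow(trace)
  G <- matrix(0, K, n_case)
  rt_step <- integer(n_case)
  boundary <- integer(n_case)          # 1 upper, 2 lower, 0 censored
  agent <- as.integer(trace$agent)
  step_starts <- (seq_len(K) - 1) * dt
  for (rows in trials) {
    for (i in rows) {
      oth <- rows[rows != i]
      ev_t <- trace$rt[oth]
      ev_c <- trace$choice[oth]
      keep <- !is.na(ev_t)
      ev_t <- ev_t[keep]; ev_c <- ev_c[keep]
      if (is.na(trace$rt[i])) {
        rt_step[i] <- K; boundary[i] <- 0L
      } else {
        rt_step[i] <- max(1L, as.integer(round(trace$rt[i] / dt)))
        boundary[i] <- if (trace$choice[i] == "A") 1L else 2L
      }
      if (length(ev_t)) {
        o <- order(ev_t)
        ev_t <- ev_t[o]; ev_c <- ev_c[o]
        nA <- cumsum(ev_c == "A"); nB <- cumsum(ev_c == "B")
        idx <- findInterval(step_starts, ev_t + 1e-12) + 1L  # 1 = no event yet
        M <- c(0, nA - nB)[idx]
        G[, i] <- sign(M) * abs(M)^q
      }
    }
  }
  Kneed <- max(rt_step)                  # censored cases carry step K
  list(G = G[seq_len(Kneed), , drop = FALSE], rt_step = rt_step,
       boundary = boundary, agent = agent, K = K, n_case = n_case)
}

# Vectorised multi-case grid propagation; returns log-likelihood.
# delta_case[k, ] = dp[agent] + s[agent] * G[k, ].
ddm_cases_loglik <- function(cases, dp, s, start, lower, upper, noise_sd,
                             dt, n_bins) {
  h <- (upper - lower) / (n_bins + 1)
  n_case <- cases$n_case
  c1 <- noise_sd^2 * dt / (2 * h^2)
  m <- matrix(0, n_case, n_bins)
  j <- (start - lower) / h
  j0 <- floor(j); w <- j - j0
  if (length(start) == 1) {
    if (j0 >= 1 && j0 <= n_bins) m[, j0] <- 1 - w
    if (j0 + 1 <= n_bins) m[, j0 + 1] <- m[, j0 + 1] + w
  } else {
    for (i in seq_len(n_case)) {
      if (j0[i] >= 1 && j0[i] <= n_bins) m[i, j0[i]] <- 1 - w[i]
      if (j0[i] + 1 <= n_bins) m[i, j0[i] + 1] <- m[i, j0[i] + 1] + w[i]
    }
  }
  dens <- numeric(n_case)
  surv <- numeric(n_case)
  cens <- cases$boundary == 0L
  Kmax <- max(cases$rt_step)
  dpv <- dp[cases$agent]; sv <- s[cases$agent]
  n <- n_bins
  # cases are retired once their observed step has been harvested; columns
  # are physically dropped in batches so late steps only carry the tail
  alive <- seq_len(n_case)                 # global ids of current rows of m
  rt_al <- cases$rt_step
  done <- 0L
  for (k in seq_len(Kmax)) {
    dl <- dpv[alive] + sv[alive] * cases$G[k, alive]
    dd <- dl * dt
    base <- c1 + dd^2 / (2 * h^2)
    pu <- base + dd / (2 * h)
    pd <- base - dd / (2 * h)
    if (any(pu < 0 | pd < 0 | pu + pd > 1))
      stop("unstable discretization in likelihood grid; shrink dt")
    up_flux <- m[, n] * pu
    dn_flux <- m[, 1] * pd
    m2 <- m * (1 - pu - pd)
    m2[, 2:n] <- m2[, 2:n] + m[, 1:(n - 1)] * pu
    m2[, 1:(n - 1)] <- m2[, 1:(n - 1)] + m[, 2:n] * pd
    m <- m2
    hit <- which(rt_al[alive] == k)
    if (length(hit)) {
      ids <- alive[hit]
      bu <- cases$boundary[ids]
      dens[ids[bu == 1L]] <- up_flux[hit[bu == 1L]]
      dens[ids[bu == 2L]] <- dn_flux[hit[bu == 2L]]
      surv[ids] <- rowSums(m[hit, , drop = FALSE])
      done <- done + length(hit)
      if (done > 0.25 * length(alive) || k == Kmax) {
        keep <- rt_al[alive] > k
        m <- m[keep, , drop = FALSE]
        alive <- alive[keep]
        done <- 0L
      }
    }
  }
  ll <- sum(log(pmax(dens[!cens] / dt, 1e-300)))
  if (any(cens)) ll <- ll + sum(log(pmax(surv[cens], 1e-300)))
  ll
}

#' Log-likelihood of observed group choices and response times
#'
#' Evaluates the social-DDM likelihood of a trace of group trials. Each
#' agent's drift schedule is fixed by the *observed* decision timeline of
#' the other members (conditioned on as exogenous covariates — the standard
#' conditional factorisation), so the per-agent likelihood is a
#' first-passage density under piecewise-constant drift, computed on the
#' numeric grid of [ddm_fpt_grid()]. Censored agents (no decision by the
#' horizon) contribute their surviving probability mass.
#'
#' The grid geometry must be shared across agents (equal thresholds and
#' noise SD); `delta_p`, `s` and the starting point may differ per agent.
#' `noise_sd` is fixed at 1 by convention during fitting (scale invariance).
#'
#' @param trace a `group_ddm_trace` or a data.frame with columns `trial`,
#'   `agent`, `choice`, `rt` (and a `t_max` attribute or `t_max` argument).
#' @param agents a [ddm_agents()] table: one row shared by all agents, or
#'   one row per agent.
#' @param dt grid time step; must satisfy the stability bound of
#'   [ddm_fpt_grid()] for the given `n_bins`.
#' @param n_bins number of interior evidence nodes.
#' @param t_max horizon; defaults to the trace attribute.
#' @return The summed log-likelihood (scalar).
#' @export
social_ddm_loglik <- function(trace, agents, dt = NULL, n_bins = 48,
                              t_max = NULL) {
  agents <- as_ddm_agents(agents)
  n_ag <- max(trace$agent)
  if (nrow(agents) == 1 && n_ag > 1)
    agents <- agents[rep(1, n_ag), , drop = FALSE]
  if (nrow(agents) != n_ag)
    stop("agents must have one row, or one row per agent in the trace")
  if (length(unique(agents$threshold_upper)) != 1 ||
      length(unique(agents$threshold_lower)) != 1 ||
      length(unique(agents$noise_sd)) != 1 ||
      length(unique(agents$q)) != 1)
    stop("the grid likelihood requires shared thresholds, noise_sd and q")
  if (is.null(t_max)) t_max <- attr(trace, "t_max")
  if (is.null(t_max)) t_max <- max(trace$rt, na.rm = TRUE) * 1.5
  if (any(trace$rt > t_max + 1e-9, na.rm = TRUE))
    stop("observed RT outside the horizon t_max")
  up <- agents$threshold_upper[1]; lo <- agents$threshold_lower[1]
  sdv <- agents$noise_sd[1]
  h <- (up - lo) / (n_bins + 1)
  if (is.null(dt)) dt <- 0.8 * h^2 / sdv^2
  cases <- build_ddm_cases(trace, q = agents$q[1], dt = dt, t_max = t_max)
  start <- if (length(unique(agents$start)) == 1) agents$start[1]
           else agents$start[cases$agent]
  ddm_cases_loglik(cases, dp = agents$delta_p, s = agents$s,
                   start = start, lower = lo, upper = up, noise_sd = sdv,
                   dt = dt, n_bins = n_bins)
}

#' Maximum-likelihood fit of the social DDM to a group trace
#'
#' Estimates the personal drift `delta_p` and the social-drift scale `s`
#' (shared across agents) by maximising [social_ddm_loglik()] with
#' Nelder-Mead from `n_starts` jittered starting points. Thresholds, the
#' starting point, the social exponent `q` and `noise_sd` (fixed at 1 for
#' identifiability — the Wiener scale convention) are taken from `fixed`.
#'
#' @param trace observed `group_ddm_trace` (or compatible data.frame).
#' @param fixed a one-row [ddm_agents()] carrying the non-estimated
#'   parameters and the starting values for `delta_p`, `s`.
#' @param n_starts number of optimiser starts (start 1 is `fixed`'s values,
#'   the rest are jittered).
#' @param dt,n_bins likelihood grid resolution (see [social_ddm_loglik()]).
#' @param t_max horizon; defaults to the trace attribute.
#' @param jitter_sd SD of the Gaussian start jitter.
#' @return List of class `ddm_fit`: `estimates` (`delta_p`, `s`), `se`
#'   (inverse-Hessian standard errors), `loglik`, `aic`, `convergence`
#'   (optim code of the best start), `start_spread` (range of the best
#'   log-likelihood across starts) and `starts` (per-start results).
#' @export
ddm_fit <- function(trace, fixed = ddm_agents(delta_p = 0.2, s = 0.1),
                    n_starts = 2, dt = NULL, n_bins = 48, t_max = NULL,
                    jitter_sd = 0.15) {
  fixed <- as_ddm_agents(fixed)[1, , drop = FALSE]
  if (is.null(t_max)) t_max <- attr(trace, "t_max")
  if (is.null(t_max)) t_max <- max(trace$rt, na.rm = TRUE) * 1.5
  n_ag <- max(trace$agent)
  up <- fixed$threshold_upper; lo <- fixed$threshold_lower
  sdv <- fixed$noise_sd
  h <- (up - lo) / (n_bins + 1)
  if (is.null(dt)) dt <- 0.8 * h^2 / sdv^2
  cases <- build_ddm_cases(trace, q = fixed$q, dt = dt, t_max = t_max)
  nll <- function(par) {
    out <- tryCatch(
      -ddm_cases_loglik(cases, dp = rep(par[1], n_ag), s = rep(par[2], n_ag),
                        start = fixed$start, lower = lo, upper = up,
                        noise_sd = sdv, dt = dt, n_bins = n_bins),
      error = function(e) 1e10)
    if (!is.finite(out)) 1e10 else out
  }
  p0 <- c(delta_p = fixed$delta_p, s = fixed$s)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    st <- if (i == 1) p0 else p0 + rnorm(2, 0, jitter_sd)
    fits[[i]] <- optim(st, nll, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-6))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  Hs <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  se <- hessian_se(Hs, 2)
  structure(list(
    estimates = setNames(best$par, c("delta_p", "s")),
    se = setNames(se, c("delta_p", "s")),
    loglik = -best$value,
    aic = 2 * 2 + 2 * best$value,
    convergence = best$convergence,
    converged = best$convergence == 0,
    start_spread = diff(range(-vals)),
    starts = data.frame(start = seq_len(n_starts),
                        delta_p = vapply(fits, function(f) f$par[1], 0),
                        s = vapply(fits, function(f) f$par[2], 0),
                        loglik = -vals),
    dt = dt, n_bins = n_bins), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> logLik = ", signif(x$loglik, 7), ", AIC = ",
      signif(x$aic, 7), if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(data.frame(estimate = x$estimates, se = x$se))
  invisible(x)
}
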