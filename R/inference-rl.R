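# inverse-Hessian standard errors on the optimisation scale; NA where the
# Hessian is missing, singular, or not positive at the optimum (flat or
# unidentified directions)
hessian_se <- function(H, k) {
  if (is.null(H)) return(rep(NA_real_, k))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, k))
  d <- diag(V)
  ifelse(is.finite(d) & d > 0, sqrt(pmax(d, 0)), NA_real_)
}

#' Validate a trial table of group learning records
#'
#' Checks that a table of agent x trial records is complete (every agent
#' appears exactly once per trial), that choices/payoffs are well formed,
#' and that the recorded social counts (`n_A_prev`, `n_B_prev`) are
#' consistent with the other members' recorded choices on the previous
#' trial — under either the exclude-self convention (the default of the
#' simulator) or the include-self convention. Inconsistent rows are
#' reported by trial and agent.
#'
#' @param trials data.frame with columns `trial`, `agent`, `choice`,
#'   `payoff`, `n_A_prev`, `n_B_prev`.
#' @return Invisibly, the detected counting convention
#'   (`"exclude_self"` or `"include_self"`).
#' @export
validate_trial_table <- function(trials) {
  need <- c("trial", "agent", "choice", "payoff", "n_A_prev", "n_B_prev")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(trials$choice %in% c("A", "B")))
    stop("choice must be 'A' or 'B' in every row")
  tab <- table(trials$trial, trials$agent)
  if (any(tab != 1))
    stop("each agent must appear exactly once per trial")
  trials <- trials[order(trials$trial, trials$agent), ]
  n_ag <- length(unique(trials$agent))
  n_tr <- length(unique(trials$trial))
  ch <- matrix(trials$choice, n_tr, n_ag, byrow = TRUE)
  nA <- matrix(trials$n_A_prev, n_tr, n_ag, byrow = TRUE)
  nB <- matrix(trials$n_B_prev, n_tr, n_ag, byrow = TRUE)
  totA <- rowSums(ch == "A"); totB <- rowSums(ch == "B")
  check <- function(include_self) {
    expA <- matrix(0, n_tr, n_ag); expB <- matrix(0, n_tr, n_ag)
    if (n_tr > 1) {
      prevA <- matrix(totA[-n_tr], n_tr - 1, n_ag)
      prevB <- matrix(totB[-n_tr], n_tr - 1, n_ag)
      if (!include_self) {
        prevA <- prevA - (ch[-n_tr, , drop = FALSE] == "A")
        prevB <- prevB - (ch[-n_tr, , drop = FALSE] == "B")
      }
      expA[-1, ] <- prevA; expB[-1, ] <- prevB
    }
    which(nA != expA | nB != expB, arr.ind = TRUE)
  }
  bad_ex <- check(FALSE)
  if (nrow(bad_ex) == 0) return(invisible("exclude_self"))
  bad_in <- check(TRUE)
  if (nrow(bad_in) == 0) return(invisible("include_self"))
  ex <- head(bad_ex, 5)
  stop("social counts inconsistent with recorded choices (first offending ",
       "trial/agent pairs: ",
       paste(sprintf("%d/%d", sort(unique(trials$trial))[ex[, 1]], ex[, 2]),
             collapse = ", "), ")")
}

#' Log-likelihood of a social reinforcement-learning trial table
#'
#' Reconstructs each agent's latent-value trajectories from its recorded
#' choices and payoffs (Rescorla-Wagner updating), evaluates the
#' social-learning mixture probability of every realised choice given the
#' recorded social counts, and sums the logs. Fully deterministic and
#' invariant to the row order of the table (rows are sorted internally).
#'
#' @param trials data.frame with columns `trial`, `agent`, `choice`,
#'   `payoff`, `n_A_prev`, `n_B_prev` (the dialect written by
#'   [simulate_rl_group()]).
#' @param params an [rl_agents()] table: one row (shared parameters) or one
#'   row per agent.
#' @param validate check count/choice consistency first (see
#'   [validate_trial_table()]).
#' @return Scalar log-likelihood.
#' @export
rl_loglik <- function(trials, params, validate = TRUE) {
  if (validate) validate_trial_table(trials)
  params <- as_rl_agents(params)
  trials <- trials[order(trials$trial, trials$agent), ]
  agents_ids <- sort(unique(trials$agent))
  n_ag <- length(agents_ids)
  if (nrow(params) == 1 && n_ag > 1) params <- params[rep(1, n_ag), ]
  if (nrow(params) != n_ag)
    stop("params must have one row, or one row per agent")
  n_tr <- length(unique(trials$trial))
  ch <- matrix(trials$choice == "A", n_tr, n_ag, byrow = TRUE)
  pay <- matrix(trials$payoff, n_tr, n_ag, byrow = TRUE)
  nA <- matrix(trials$n_A_prev, n_tr, n_ag, byrow = TRUE)
  nB <- matrix(trials$n_B_prev, n_tr, n_ag, byrow = TRUE)
  rl_loglik_kernel(ch, pay, nA, nB,
                   params$alpha, params$beta, params$sigma, params$theta,
                   params$q0)
}

# matrix kernel shared by rl_loglik and the rl_fit objective: ch is a
# logical [trial, agent] matrix (TRUE = choice A), remaining matrices
# likewise; parameter vectors have one entry per agent.
rl_loglik_kernel <- function(ch, pay, nA, nB, al, be, si, th, q0) {
  n_tr <- nrow(ch)
  QA <- rep_len(q0, ncol(ch))
  QB <- QA
  ll <- 0
  for (t in seq_len(n_tr)) {
    p_asoc <- 1 / (1 + exp(-be * (QA - QB)))
    wA <- nA[t, ]^th                    # 0^theta = 0 for theta > 0
    wB <- nB[t, ]^th
    den <- wA + wB
    p <- (1 - si) * p_asoc + si * wA / den
    none <- den == 0
    if (any(none)) p[none] <- p_asoc[none]
    cht <- ch[t, ]
    pr <- p + (1 - 2 * p) * !cht         # p if A chosen, 1 - p otherwise
    ll <- ll + sum(log(pmax(pr, 1e-300)))
    QA <- QA + al * (pay[t, ] - QA) * cht
    QB <- QB + al * (pay[t, ] - QB) * !cht
  }
  ll
}

#' Maximum-likelihood fit of the social reinforcement-learning model
#'
#' Fits shared parameters by bounded multi-start optimisation of
#' [rl_loglik()] on transformed scales (logit for `alpha` and `sigma`, log
#' for `beta` and `theta`, which keeps every start inside the admissible
#' region). `model = "asocial"` fixes `sigma = 0` (and `theta`, which then
#' drops out of the likelihood) and estimates only `alpha`, `beta` — the
#' natural null model for AIC comparison against the social model.
#'
#' When the estimated `sigma` is near 0 the conformity exponent is not
#' identified (it enters only through the social term); the fit flags this
#' (`theta_unidentifiable`) rather than reporting a meaningless estimate.
#'
#' @param trials trial table (see [rl_loglik()]).
#' @param model `"social"` (alpha, beta, sigma, theta) or `"asocial"`
#'   (alpha, beta).
#' @param n_starts number of optimiser starts (default 10).
#' @param init optional named list of natural-scale starting values.
#' @param q0 initial latent value (fixed, not estimated).
#' @param seed seed for the start jitter.
#' @param validate check the table first.
#' @return List of class `rl_fit` with `estimates`, `se` (delta-method),
#'   `loglik`, `aic`, `convergence`/`converged`, `theta_unidentifiable`,
#'   `start_spread` (range of the best log-likelihood across starts) and
#'   the per-start table `starts`.
#' @export
rl_fit <- function(trials, model = c("social", "asocial"), n_starts = 10,
                   init = NULL, q0 = 0, seed = NULL, validate = TRUE) {
  model <- match.arg(model)
  if (validate) validate_trial_table(trials)
  if (!is.null(seed)) set.seed(seed)
  n_min <- 20L
  if (length(unique(trials$trial)) < n_min)
    warning("fewer than ", n_min, " trials per agent; estimates may be poor")
  social <- model == "social"
  defaults <- list(alpha = 0.3, beta = 0.2, sigma = 0.3, theta = 1)
  if (!is.null(init)) defaults[names(init)] <- init
  to_par <- function(d) {
    p <- c(stats::qlogis(d$alpha), log(d$beta))
    if (social) p <- c(p, stats::qlogis(d$sigma), log(d$theta))
    p
  }
  from_par <- function(p) {
    out <- list(alpha = stats::plogis(p[1]), beta = exp(p[2]))
    out$sigma <- if (social) stats::plogis(p[3]) else 0
    out$theta <- if (social) exp(p[4]) else 1
    out
  }
  trials <- trials[order(trials$trial, trials$agent), ]
  n_ag <- length(unique(trials$agent))
  n_tr <- length(unique(trials$trial))
  ch <- matrix(trials$choice == "A", n_tr, n_ag, byrow = TRUE)
  pay <- matrix(trials$payoff, n_tr, n_ag, byrow = TRUE)
  nA <- matrix(trials$n_A_prev, n_tr, n_ag, byrow = TRUE)
  nB <- matrix(trials$n_B_prev, n_tr, n_ag, byrow = TRUE)
  nll <- function(p) {
    d <- from_par(p)
    # extreme transformed values can overflow the power weights; such
    # points simply score as infeasible
    v <- suppressWarnings(
      -rl_loglik_kernel(ch, pay, nA, nB, d$alpha, d$beta, d$sigma,
                        d$theta, q0))
    if (!is.finite(v)) 1e10 else v
  }
  p0 <- to_par(defaults)
  k <- length(p0)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    st <- if (i == 1) p0 else p0 + rnorm(k, 0, 1)
    fits[[i]] <- optim(st, nll, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-9))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  est <- from_par(best$par)
  Hs <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  se_t <- hessian_se(Hs, k)
  # delta method back to the natural scale
  jac <- c(est$alpha * (1 - est$alpha), est$beta)
  if (social) jac <- c(jac, est$sigma * (1 - est$sigma), est$theta)
  se <- se_t * jac
  nm <- if (social) c("alpha", "beta", "sigma", "theta") else c("alpha", "beta")
  theta_flag <- social && est$sigma < 0.02
  if (theta_flag) se[4] <- NA_real_
  structure(list(
    model = model,
    estimates = setNames(unlist(est)[nm], nm),
    se = setNames(se, nm),
    loglik = -best$value,
    aic = 2 * k + 2 * best$value,
    n_params = k,
    convergence = best$convergence,
    converged = best$convergence == 0,
    theta_unidentifiable = theta_flag,
    start_spread = diff(range(-vals)),
    starts = data.frame(start = seq_len(n_starts), loglik = -vals)),
    class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit: ", x$model, "> logLik = ", signif(x$loglik, 7), ", AIC = ",
      signif(x$aic, 7), if (!x$converged) "  [NOT CONVERGED]",
      if (x$theta_unidentifiable) "  [theta unidentifiable: sigma ~ 0]",
      "\n", sep = "")
  print(data.frame(estimate = x$estimates, se = x$se))
  invisible(x)
}
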