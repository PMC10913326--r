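#' Signed majority size
#'
#' The social signal seen by undecided agents: the difference between the
#' number of group members already decided for option A and for option B.
#'
#' @param n_A,n_B non-negative counts of members decided for A and for B.
#' @return `n_A - n_B` (integer-valued, vectorised).
#' @examples
#' majority_size(3, 1)  # 2
#' @export
majority_size <- function(n_A, n_B) {
  if (any(n_A < 0) || any(n_B < 0)) stop("counts must be non-negative")
  n_A - n_B
}

#' Social component of the drift rate
#'
#' Frequency-dependent social-information uptake: a power function of the
#' signed majority size, `s * sign(M) * |M|^q`. The sign-preserving power
#' keeps the social drift an odd function of `M`, so options A and B are
#' treated symmetrically for any exponent; with `q = 1` it reduces to the
#' linear majority rule `s * M`.
#'
#' @param M signed majority size (see [majority_size()]).
#' @param s social-drift scale.
#' @param q power exponent, > 0. `q > 1` up-weights large majorities,
#'   `q < 1` saturates (diminishing returns per additional observed choice).
#' @return Drift contribution (same units as the personal drift).
#' @examples
#' social_drift(2, s = 0.5, q = 1)    # 1
#' social_drift(-2, s = 0.5, q = 0.5) # -0.5 * sqrt(2)
#' @export
social_drift <- function(M, s, q) {
  if (any(q <= 0)) stop("q must be > 0")
  s * sign(M) * abs(M)^q
}

#' Effective drift of an undecided agent
#'
#' Decomposes the drift rate into a personal part (own information intake)
#' and a social part driven by the current majority among decided members:
#' `delta = delta_p + social_drift(M, s, q)`.
#'
#' @param params a single-row [ddm_agents()] table (or a row index into a
#'   multi-row one via `agent`).
#' @param state list or data.frame with counts `n_A`, `n_B` (a field `M` is
#'   ignored and recomputed).
#' @param agent row to use when `params` has several agents.
#' @return The effective drift rate (scalar or vectorised over the state).
#' @export
effective_drift <- function(params, state, agent = 1L) {
  p <- as_ddm_agents(params)[agent, ]
  M <- majority_size(state$n_A, state$n_B)
  p$delta_p + social_drift(M, p$s, p$q)
}

#' One Euler step of the evidence process
#'
#' Advances the evidence state by `delta * dt` plus Gaussian diffusion noise
#' `sqrt(dt) * e`, `e ~ N(0, noise_sd^2)`. This is the elementary update the
#' group simulator applies to every undecided agent each time step.
#'
#' @param L current evidence state (vectorised).
#' @param delta drift rate.
#' @param dt time step, > 0.
#' @param noise_sd diffusion standard deviation per unit time (>= 0 here so
#'   the deterministic ramp is available for checks).
#' @return Updated evidence state(s).
#' @export
step_evidence <- function(L, delta, dt, noise_sd = 1) {
  if (any(dt <= 0)) stop("dt must be > 0")
  n <- max(length(L), length(delta))
  L + delta * dt + sqrt(dt) * rnorm(n, 0, 1) * noise_sd
}

#' Closed-form absorption of a constant-drift diffusion
#'
#' Analytic oracle for the two-boundary Wiener process: probability of
#' absorption at the upper boundary and the unconditional mean first-passage
#' time, for constant drift `delta`, diffusion SD `noise_sd` and absorbing
#' boundaries `lower < start < upper`. Used throughout to validate the
#' simulators and the numeric first-passage grid.
#'
#' With `x = start - lower`, `a = upper - lower`, `k = 2 delta / noise_sd^2`:
#' `p_upper = (1 - exp(-k x)) / (1 - exp(-k a))`, and
#' `E[T] = (a / delta) * p_upper - x / delta`; the drift-free limits are
#' `x / a` and `x (a - x) / noise_sd^2`.
#'
#' @param delta constant drift rate.
#' @param start starting evidence, strictly inside `(lower, upper)`.
#' @param lower,upper absorbing boundaries.
#' @param noise_sd diffusion standard deviation, > 0.
#' @return List with `p_upper` and `mean_fpt` (unconditional).
#' @examples
#' fpt_constant_drift(0, 0, -1, 1, 1)   # p_upper = 0.5, mean_fpt = 1
#' @export
fpt_constant_drift <- function(delta, start, lower, upper, noise_sd = 1) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!(lower < start && start < upper))
    stop("start must lie strictly between the boundaries")
  x <- start - lower
  a <- upper - lower
  k <- 2 * delta / noise_sd^2
  if (abs(k * a) < 1e-10) {
    p_upper <- x / a
    mean_fpt <- x * (a - x) / noise_sd^2
  } else if (-k * a > 700) {
    # strongly negative drift: both expm1 terms overflow; use the limit ratio
    p_upper <- exp(k * (a - x))
    mean_fpt <- (a * p_upper - x) / delta
  } else {
    p_upper <- expm1(-k * x) / expm1(-k * a)
    mean_fpt <- (a * p_upper - x) / delta
  }
  list(p_upper = p_upper, mean_fpt = mean_fpt)
}

# sign-preserving power of the majority sizes for a vector M and scalar q
signed_power <- function(M, q) sign(M) * abs(M)^q
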