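#' Rescorla-Wagner value update
#'
#' Moves the chosen option's latent value a fraction `alpha` of the way
#' towards the received payoff: `q + alpha * (payoff - q)`. Values of
#' unchosen options are carried forward unchanged by the simulator.
#'
#' @param q current latent value.
#' @param payoff received payoff (points).
#' @param alpha updating rate in `[0, 1]`.
#' @return Updated value (vectorised).
#' @examples
#' update_q(0, 15, 0.3)  # 4.5
#' @export
update_q <- function(q, payoff, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]")
  q + alpha * (payoff - q)
}

#' Softmax choice probabilities
#'
#' Translates latent values into choice probabilities,
#' `P_i = exp(beta * Q_i) / sum_m exp(beta * Q_m)`, computed with the usual
#' max-subtraction so large `beta * Q` cannot overflow.
#'
#' @param q_values numeric vector of latent values, one per option.
#' @param beta exploration/exploitation rate (>= 0); 0 yields the uniform
#'   distribution regardless of the values.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_choice_prob(c(20, 15), 0.18)
#' @export
softmax_choice_prob <- function(q_values, beta) {
  if (!all(is.finite(q_values))) stop("q_values must be finite")
  if (beta < 0) stop("beta must be >= 0")
  z <- beta * q_values
  e <- exp(z - max(z))
  e / sum(e)
}

#' Frequency-dependent (conformist) copying probabilities
#'
#' `P_S,i = n_i^theta / sum_m n_m^theta` over the observed counts of group
#' members previously choosing each option, with `0^theta := 0`. When all
#' counts are zero there is no social information to copy; instead of a
#' division error the function returns a vector of `NA` — the dedicated
#' "no social information" signal that [combined_choice_prob()] maps to the
#' asocial softmax.
#'
#' @param counts non-negative count per option.
#' @param theta conformity exponent (> 0); above 1 amplifies majorities,
#'   below 1 dampens them, exactly 1 copies proportionally.
#' @return Probability vector summing to 1, or all-`NA` when no member has
#'   been observed choosing.
#' @examples
#' conformist_prob(c(3, 1), 1)  # 0.75 0.25
#' conformist_prob(c(3, 1), 5)  # 243/244 1/244
#' @export
conformist_prob <- function(counts, theta) {
  if (theta <= 0) stop("theta must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) return(rep(NA_real_, length(counts)))
  w <- ifelse(counts == 0, 0, counts^theta)
  w / sum(w)
}

#' Social-learning mixture of experience and copying
#'
#' The decision-biasing rule
#' `P_i = (1 - sigma) * softmax_i + sigma * P_S,i`: a convex mixture of the
#' agent's own-experience softmax and the frequency-dependent copying
#' probabilities. If [conformist_prob()] signals "no social information"
#' (all counts zero, e.g. on the first trial), the asocial softmax is
#' returned unchanged, keeping the rule a proper probability distribution.
#'
#' @inheritParams softmax_choice_prob
#' @inheritParams conformist_prob
#' @param sigma social-learning weight in `[0, 1]`.
#' @return Probability vector summing to 1.
#' @examples
#' combined_choice_prob(c(20, 15), 0.18, c(1, 3), sigma = 0.3, theta = 1.5)
#' @export
combined_choice_prob <- function(q_values, beta, counts, sigma, theta) {
  if (sigma < 0 || sigma > 1) stop("sigma must be in [0, 1]")
  p_a <- softmax_choice_prob(q_values, beta)
  p_s <- conformist_prob(counts, theta)
  if (anyNA(p_s)) return(p_a)
  (1 - sigma) * p_a + sigma * p_s
}
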