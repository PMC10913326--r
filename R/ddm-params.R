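#' Per-agent parameters of the social drift-diffusion model
#'
#' Builds a validated parameter table with one row per agent. All arguments
#' are recycled to the number of agents, so homogeneous groups can be
#' specified with scalars.
#'
#' @param delta_p personal drift rate (evidence units per unit time);
#'   positive values drift towards the upper ("A", correct) threshold.
#' @param s social-drift scale (evidence units per unit time per unit
#'   majority). `s = 0` gives an asocial agent.
#' @param q power exponent of the social drift (> 0). `q = 1` is the linear
#'   majority rule; the social drift is kept an odd function of the majority
#'   via a sign-preserving power (see [social_drift()]).
#' @param threshold_lower,threshold_upper decision boundaries (evidence
#'   units); crossing the upper boundary records choice "A", the lower "B".
#' @param start initial evidence state, strictly between the thresholds.
#' @param noise_sd diffusion standard deviation per unit time (> 0). The
#'   default 1 fixes the evidence unit, the usual DDM convention.
#' @param n_agents number of agents; defaults to the longest argument.
#'
#' @return A `data.frame` of class `ddm_agents` with columns `delta_p`, `s`,
#'   `q`, `threshold_lower`, `threshold_upper`, `start`, `noise_sd` and one
#'   row per agent.
#' @examples
#' ddm_agents(delta_p = c(0.1, 0.3, 0.5), s = 0.2)
#' @export
ddm_agents <- function(delta_p = 0.3, s = 0, q = 1,
                       threshold_lower = -1, threshold_upper = 1,
                       start = 0, noise_sd = 1, n_agents = NULL) {
  args <- list(delta_p = delta_p, s = s, q = q,
               threshold_lower = threshold_lower,
               threshold_upper = threshold_upper,
               start = start, noise_sd = noise_sd)
  if (is.null(n_agents)) n_agents <- max(lengths(args))
  if (n_agents < 1) stop("need at least one agent")
  bad <- names(args)[!vapply(args, function(a)
    is.numeric(a) && all(is.finite(a)) && length(a) %in% c(1L, n_agents),
    logical(1))]
  if (length(bad))
    stop("invalid or wrongly sized parameter(s): ", paste(bad, collapse = ", "))
  out <- as.data.frame(lapply(args, rep_len, n_agents))
  if (any(out$noise_sd <= 0)) stop("noise_sd must be > 0")
  if (any(out$q <= 0)) stop("q must be > 0")
  if (any(out$threshold_lower >= out$start | out$start >= out$threshold_upper))
    stop("need threshold_lower < start < threshold_upper for every agent")
  out$agent <- seq_len(n_agents)
  class(out) <- c("ddm_agents", "data.frame")
  out
}

#' @export
print.ddm_agents <- function(x, ...) {
  cat("<ddm_agents> ", nrow(x), " agent(s)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

as_ddm_agents <- function(x) {
  if (inherits(x, "ddm_agents")) return(x)
  do.call(ddm_agents, c(as.list(x[setdiff(names(x), "agent")]),
                        list(n_agents = nrow(x))))
}
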