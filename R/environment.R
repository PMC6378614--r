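# Environmental shock series and their mapping onto realized per-year
# demographic rates under the three survival-fecundity covariation
# scenarios.

#' Environmental scenario
#'
#' A scenario is defined by the covariation mode between the survival and
#' fecundity shocks and by the shock standard deviation \eqn{\sigma}:
#'
#' * `"negative"`: fecundity shocks are exactly opposite to survival shocks
#'   (within-year survival-reproduction trade-off), \eqn{\delta_t =
#'   -\epsilon_t};
#' * `"null"`: the two shock series are drawn independently;
#' * `"positive"`: shocks are identical in direction and magnitude,
#'   \eqn{\delta_t = \epsilon_t}.
#'
#' @param mode one of `"negative"`, `"null"`, `"positive"`.
#' @param sigma non-negative shock standard deviation.
#' @param seed optional integer seed; when set, shock draws are
#'   reproducible.
#' @return an object of class `env_scenario`.
#' @export
env_scenario <- function(mode = c("negative", "null", "positive"),
                         sigma, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    .stopf("sigma must be a single non-negative number")
  if (!is.null(seed)) stopifnot(.is_count(seed))
  structure(list(mode = mode, sigma = sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "env_scenario")
}

#' @export
print.env_scenario <- function(x, ...) {
  cat(sprintf("<env_scenario> mode = %s, sigma = %g%s\n", x$mode, x$sigma,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Draw an environmental shock series
#'
#' Survival shocks \eqn{\epsilon_t} are i.i.d. Normal(0, \eqn{\sigma^2});
#' fecundity shocks \eqn{\delta_t} follow the scenario mode (see
#' [env_scenario()]). One scalar shock per rate per time step is shared
#' across all ages.
#'
#' @param scenario an `env_scenario`.
#' @param T number of time steps (>= 1).
#' @return a list with numeric vectors `eps` and `delta`, each of length
#'   `T`.
#' @export
draw_shocks <- function(scenario, T) {
  stopifnot(inherits(scenario, "env_scenario"), .is_count(T), T >= 1)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  eps <- stats::rnorm(T, 0, scenario$sigma)
  delta <- switch(scenario$mode,
    negative = -eps,
    positive = eps,
    null = stats::rnorm(T, 0, scenario$sigma))
  list(eps = eps, delta = delta)
}

#' Map shocks onto realized demographic rates
#'
#' Survival is perturbed additively on the logit scale,
#' \eqn{\mathrm{logit}(p_{x,t}) = \mathrm{logit}(\rho_x) + \epsilon_t}
#' (rates exactly 0 or 1 are left fixed), and fecundity on the log scale
#' with a lognormal mean correction,
#' \eqn{\ln b_{x,t} = \ln \beta_x + \delta_t - \sigma^2/2} (zero fecundity
#' stays zero), so that \eqn{E[b_{x,t}] = \beta_x} and all realized rates
#' remain in their valid domains at any shock size.
#'
#' @param survival mean survival probabilities (one per class).
#' @param fecundity mean fecundities (one per class).
#' @param eps,delta scalar shocks for one time step.
#' @param sigma shock standard deviation used in the mean correction.
#' @return a list with vectors `p` and `b` of realized rates.
#' @export
perturb_rates <- function(survival, fecundity, eps, delta, sigma = 0) {
  stopifnot(length(eps) == 1L, length(delta) == 1L)
  p <- survival
  i <- survival > 0 & survival < 1
  p[i] <- stats::plogis(stats::qlogis(survival[i]) + eps)
  b <- fecundity
  j <- fecundity > 0
  b[j] <- exp(log(fecundity[j]) + delta - sigma^2 / 2)
  list(p = p, b = b)
}

# Whole-series version: realized rate matrices (classes x T) from shock
# vectors, used by the simulators.
.realized_matrices <- function(survival, fecundity, shocks, sigma) {
  i <- survival > 0 & survival < 1
  P <- matrix(survival, length(survival), length(shocks$eps))
  P[i, ] <- stats::plogis(outer(stats::qlogis(survival[i]), shocks$eps, "+"))
  j <- fecundity > 0
  B <- matrix(fecundity, length(fecundity), length(shocks$delta))
  B[j, ] <- exp(outer(log(fecundity[j]),
                      shocks$delta - sigma^2 / 2, "+"))
  list(P = P, B = B)
}
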