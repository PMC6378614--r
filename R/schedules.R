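# Per-age mean demographic schedules: survival probabilities rho_x and
# fecundities beta_x on ages 0..omega.

#' Build per-age demographic schedules from a mortality model and a
#' fecundity trajectory
#'
#' Discretises a continuous [hazard_model()] into per-age survival
#' probabilities \eqn{\rho_x = \exp(-(H(x+1) - H(x)))} up to the truncation
#' age \eqn{\omega} (chosen by [truncation_age()]), assigns the terminal
#' class \eqn{\rho_\omega = 0}, and evaluates the fecundity trajectory
#' \eqn{\beta_x} on the same ages.
#'
#' @param mortality a `hazard_model`.
#' @param fecundity a `fecundity_shape`.
#' @param survivorship_floor,cap passed to [truncation_age()].
#' @return an object of class `schedules` with fields `omega`, `alpha`,
#'   `rho` (length `omega + 1`, terminal entry 0) and `beta`.
#' @examples
#' m <- hazard_model("gompertz", c(a = 0.05, b = 0.15))
#' f <- fecundity_shape("F1_flat", c(level = 1), maturity = 2)
#' s <- make_schedules(m, f)
#' head(as.data.frame(s))
#' @export
make_schedules <- function(mortality, fecundity,
                           survivorship_floor = 1e-4, cap = 200L) {
  stopifnot(inherits(mortality, "hazard_model"),
            inherits(fecundity, "fecundity_shape"))
  omega <- truncation_age(mortality, survivorship_floor, cap)
  if (fecundity$maturity > omega)
    .stopf("maturity age (%d) exceeds truncation age (%d)",
           fecundity$maturity, omega)
  rho <- c(annual_survival(mortality, 0:(omega - 1)), 0)
  beta <- fecundity_schedule(fecundity, omega)
  schedules(rho = rho, beta = beta, alpha = fecundity$maturity,
            mortality = mortality, fecundity = fecundity)
}

#' Construct schedules directly from rate vectors
#'
#' Low-level constructor used by [make_schedules()] and useful for
#' hand-built examples. `rho` and `beta` must have equal length
#' `omega + 1`; the terminal survival `rho[omega + 1]` must be 0 and all
#' other survival probabilities must lie in (0, 1].
#'
#' @param rho per-age survival probabilities for ages `0..omega`.
#' @param beta per-age fecundities for ages `0..omega`, zero below `alpha`.
#' @param alpha maturity age.
#' @param mortality,fecundity optional generating model objects (metadata).
#' @return an object of class `schedules`.
#' @export
schedules <- function(rho, beta, alpha = 0L,
                      mortality = NULL, fecundity = NULL) {
  if (length(rho) != length(beta))
    .stopf("rho and beta must have equal length")
  omega <- length(rho) - 1L
  if (omega < 1L) .stopf("need at least two age classes (omega >= 1)")
  if (rho[omega + 1L] != 0)
    .stopf("terminal survival rho_omega must be 0")
  body_rho <- rho[seq_len(omega)]
  if (any(body_rho <= 0) || any(body_rho > 1))
    .stopf("survival probabilities for x < omega must lie in (0, 1]")
  if (any(beta < 0)) .stopf("fecundities must be >= 0")
  if (!.is_count(alpha) || alpha < 0 || alpha > omega)
    .stopf("alpha must be an integer age in [0, omega]")
  if (alpha > 0 && any(beta[seq_len(alpha)] != 0))
    .stopf("fecundity must be zero below the maturity age")
  structure(list(omega = as.integer(omega), alpha = as.integer(alpha),
                 rho = as.numeric(rho), beta = as.numeric(beta),
                 mortality = mortality, fecundity = fecundity),
            class = "schedules")
}

#' @export
print.schedules <- function(x, ...) {
  cat(sprintf("<schedules> omega = %d, alpha = %d\n", x$omega, x$alpha))
  cat(sprintf("  rho: %s ...\n",
              paste(sprintf("%.3f", utils::head(x$rho, 5)), collapse = " ")))
  cat(sprintf("  beta: %s ...\n",
              paste(sprintf("%.3f", utils::head(x$beta, 5)), collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.schedules <- function(x, ...) {
  data.frame(age = 0:x$omega, rho = x$rho, beta = x$beta)
}
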