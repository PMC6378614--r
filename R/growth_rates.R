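# Long-run growth-rate estimators: empirical, second-order Taylor, and the
# Tuljapurkar small-noise approximation.

#' Empirical long-run stochastic growth rate
#'
#' The logarithm of the geometric mean of the yearly growth rates,
#' \eqn{r_e = \mathrm{mean}(\ln \lambda_t)}, after discarding `burn_in`
#' steps. By Jensen's inequality \eqn{r_e \le \ln \lambda_e}, strictly when
#' the growth rate varies.
#'
#' @param run a [simulate_run()] result.
#' @param burn_in initial steps discarded.
#' @return a list with `r_e` and `lambda_s = exp(r_e)`.
#' @export
empirical_r <- function(run, burn_in = 0L) {
  stopifnot(inherits(run, "simulation_run"))
  lam <- run$lambda[(burn_in + 1L):run$T]
  if (any(lam <= 0))
    .stopf("non-positive yearly growth rate: degenerate run")
  r_e <- mean(log(lam))
  list(r_e = r_e, lambda_s = exp(r_e))
}

#' Second-order Taylor approximation to the long-run growth rate
#'
#' \deqn{r_T = \ln(\lambda_e) - V_\lambda / (2 \lambda_e^2),}
#' a second-order expansion of \eqn{E[\ln \lambda_t]} around
#' \eqn{\lambda_e} that turns the mean and variance of the yearly growth
#' rate into an estimate of its long-run (geometric-mean) counterpart.
#'
#' @param lambda_e expected yearly growth rate (> 0).
#' @param V_lambda variance of the yearly growth rate (>= 0).
#' @return a list with `r_T` and `lambda_T = exp(r_T)`.
#' @export
taylor_r <- function(lambda_e, V_lambda) {
  if (!is.finite(lambda_e) || lambda_e <= 0)
    .stopf("lambda_e must be positive")
  if (!is.finite(V_lambda) || V_lambda < 0)
    .stopf("V_lambda must be non-negative")
  r_T <- log(lambda_e) - V_lambda / (2 * lambda_e^2)
  list(r_T = r_T, lambda_T = exp(r_T))
}

#' Small-noise approximation to the long-run growth rate
#'
#' Tuljapurkar's approximation
#' \deqn{r \approx \ln \lambda_0 - \tau_0^2 / (2 \lambda_0^2),}
#' where \eqn{\lambda_0} is the dominant eigenvalue of the matrix of
#' time-averaged realized rates (a quantity that need not equal the
#' deterministic \eqn{\lambda_d} of the calibrated matrix), and
#' \eqn{\tau_0^2} is the sensitivity-weighted sum of covariances among the
#' stochastic matrix entries:
#' \deqn{\tau_0^2 = \sum \mathrm{cov}(a_{ij,t}, a_{kl,t}) s_{ij} s_{kl},}
#' with sensitivities \eqn{s_{ij} = v_i w_j / (v \cdot w)} taken from the
#' eigenvectors of the mean-rate matrix. Because every nonzero entry of a
#' Leslie matrix is one of the per-class rates, the quadratic form is
#' computed as the (1/T) variance of the scalar series
#' \eqn{g_t = \sum_x s^{(p)}_x p_{x,t} + \sum_x s^{(b)}_x b_{x,t}}.
#'
#' @param run a [simulate_run()] result (T >= 100 recommended).
#' @param burn_in initial steps discarded.
#' @return a list with `r_small_noise`, `lambda_0` and `tau_sq`.
#' @export
small_noise <- function(run, burn_in = 0L) {
  stopifnot(inherits(run, "simulation_run"))
  z <- .run_window(run, burn_in)
  kind <- run$model_kind
  surv_mean <- rowMeans(z$P)
  fec_mean <- rowMeans(z$B)
  A0 <- .assemble_matrix(surv_mean, fec_mean, kind)
  eig <- dominant_eigen(A0)
  lambda_0 <- eig$lambda
  n <- length(surv_mean)
  # sensitivity of entry (1, x) is v_1 w_x; of subdiagonal (x+1, x) is
  # v_{x+1} w_x; the adult self-loop (n, n) has v_n w_n
  s_b <- eig$v[1L] * eig$w
  s_p <- numeric(n)
  if (n > 1L) s_p[1:(n - 1L)] <- eig$v[2:n] * eig$w[1:(n - 1L)]
  if (kind == "one_adult_stage") s_p[n] <- s_p[n] + eig$v[n] * eig$w[n]
  g <- drop(crossprod(z$P, s_p)) + drop(crossprod(z$B, s_b))
  tau_sq <- .var1(g)
  r <- log(lambda_0) - tau_sq / (2 * lambda_0^2)
  list(r_small_noise = r, lambda_0 = lambda_0, tau_sq = tau_sq)
}

#' Growth-rate estimate table for a run
#'
#' Convenience wrapper assembling the empirical, Taylor and small-noise
#' estimates of the long-run growth rate from one run.
#'
#' @inheritParams empirical_r
#' @return a one-row data.frame with columns `r_e`, `lambda_s`, `r_T`,
#'   `lambda_T`, `r_small_noise`, `lambda_0`, `tau_sq`, `lambda_e`,
#'   `V_lambda`.
#' @export
growth_rate_estimates <- function(run, burn_in = 0L) {
  emp <- empirical_r(run, burn_in)
  md <- decompose_mean(run, burn_in)
  vd <- decompose_variance(run, burn_in)
  ty <- taylor_r(md$lambda_e, vd$V_lambda)
  sn <- small_noise(run, burn_in)
  data.frame(r_e = emp$r_e, lambda_s = emp$lambda_s,
             r_T = ty$r_T, lambda_T = ty$lambda_T,
             r_small_noise = sn$r_small_noise, lambda_0 = sn$lambda_0,
             tau_sq = sn$tau_sq, lambda_e = md$lambda_e,
             V_lambda = vd$V_lambda)
}
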