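# Propagation of age structure through time under realized rates, ensemble
# summaries, and integer-valued projection with demographic stochasticity.

#' One projection step
#'
#' Advances a normalized structure vector one time step under realized
#' rates. The yearly growth rate is the structure-weighted sum of per-class
#' production,
#' \deqn{\lambda_t = \sum_x w_{x,t-1} (b_{x,t} + p_{x,t}),}
#' and the new structure is \eqn{w_t = A_t w_{t-1} / \lambda_t} where
#' \eqn{A_t} carries the realized rates.
#'
#' @param w structure proportions at `t - 1` (must sum to 1).
#' @param p,b realized survival probabilities and fecundities at `t`.
#' @param kind `"full_age"` (terminal class dies) or `"one_adult_stage"`
#'   (last class has a self-loop).
#' @return a list with `lambda` and the new structure `w`; if all
#'   production is zero, `lambda = 0` and `degenerate = TRUE`.
#' @export
project_step <- function(w, p, b, kind = c("full_age", "one_adult_stage")) {
  kind <- match.arg(kind)
  n <- length(w)
  stopifnot(length(p) == n, length(b) == n)
  if (abs(sum(w) - 1) > 1e-8) .stopf("structure vector must sum to 1")
  lambda <- sum(w * (p + b))
  if (lambda <= 0)
    return(list(lambda = 0, w = w, degenerate = TRUE))
  w2 <- numeric(n)
  if (n > 1L) w2[2:n] <- p[1:(n - 1L)] * w[1:(n - 1L)]
  if (kind == "one_adult_stage") w2[n] <- w2[n] + p[n] * w[n]
  w2[1L] <- w2[1L] + sum(b * w)
  list(lambda = lambda, w = w2 / sum(w2), degenerate = FALSE)
}

#' Stochastic projection run
#'
#' Simulates `T` time steps of environmental stochasticity: shocks are
#' drawn from the scenario, mapped onto realized rates, and the structure
#' is advanced by [project_step()]. The run records the full series of
#' structure proportions, realized rates and yearly growth rates.
#'
#' @param model a calibrated `projection_model`.
#' @param scenario an [env_scenario()]; its seed (if any) makes the run
#'   reproducible.
#' @param T number of time steps.
#' @param w0 initial structure; defaults to the stable structure of the
#'   calibrated matrix (removes transient bias in short runs).
#' @return an object of class `simulation_run` with fields `w`
#'   (classes x (T+1) structure proportions), `p`, `b` (classes x T
#'   realized rates), `lambda` (length T), `scenario`, `model`,
#'   `model_kind` and `degenerate`.
#' @export
simulate_run <- function(model, scenario, T, w0 = NULL) {
  stopifnot(inherits(model, "projection_model"),
            inherits(scenario, "env_scenario"), .is_count(T), T >= 1)
  n <- length(model$survival)
  if (is.null(w0)) w0 <- model$w
  stopifnot(length(w0) == n)
  w0 <- w0 / sum(w0)
  shocks <- draw_shocks(scenario, T)
  rm_ <- .realized_matrices(model$survival, model$fecundity, shocks,
                            scenario$sigma)
  P <- rm_$P; B <- rm_$B
  W <- matrix(NA_real_, n, T + 1L)
  W[, 1L] <- w0
  lambda <- numeric(T)
  degenerate <- FALSE
  kind <- model$kind
  for (t in seq_len(T)) {
    st <- project_step(W[, t], P[, t], B[, t], kind)
    lambda[t] <- st$lambda
    if (st$degenerate) {
      degenerate <- TRUE
      T <- t
      W <- W[, seq_len(t + 1L), drop = FALSE]
      P <- P[, seq_len(t), drop = FALSE]
      B <- B[, seq_len(t), drop = FALSE]
      lambda <- lambda[seq_len(t)]
      warning("run became degenerate (lambda = 0); truncated at t = ", t)
      break
    }
    W[, t + 1L] <- st$w
  }
  structure(list(T = T, w = W, p = P, b = B, lambda = lambda,
                 shocks = shocks, scenario = scenario, model = model,
                 model_kind = kind, degenerate = degenerate),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf(
    "<simulation_run> %s, T = %d, mode = %s, sigma = %g\n  mean lambda_t = %.6f, var lambda_t = %.3e%s\n",
    x$model_kind, x$T, x$scenario$mode, x$scenario$sigma,
    mean(x$lambda), .var1(x$lambda),
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Ensemble of short stochastic runs
#'
#' Runs `R` independent replicates of [simulate_run()] (per-replicate
#' seeds derived from the scenario seed by [derive_seed()]) and records the
#' arithmetic mean growth rate \eqn{\bar\lambda} of each replicate after
#' discarding `burn_in` initial steps. The distribution of
#' \eqn{\bar\lambda} across replicates is the object compared between
#' full-age and stage-collapsed models.
#'
#' @param model a calibrated `projection_model`.
#' @param scenario an [env_scenario()] with a seed.
#' @param R number of replicates.
#' @param T steps per replicate.
#' @param burn_in initial steps discarded from each replicate mean.
#' @return an object of class `ensemble_summary` with `lambda_bar`
#'   (length `R`), `R`, `T`, `burn_in`.
#' @export
ensemble_growth <- function(model, scenario, R, T, burn_in = 0L) {
  stopifnot(.is_count(R), R >= 1, .is_count(T), T > burn_in)
  if (is.null(scenario$seed))
    .stopf("ensemble_growth requires a seeded scenario")
  keep <- (burn_in + 1L):T
  lambda_bar <- vapply(seq_len(R), function(r) {
    sc <- env_scenario(scenario$mode, scenario$sigma,
                       derive_seed(scenario$seed, r))
    run <- simulate_run(model, sc, T)
    if (run$degenerate) return(NA_real_)
    mean(run$lambda[keep])
  }, numeric(1))
  structure(list(lambda_bar = lambda_bar, R = R, T = T,
                 burn_in = as.integer(burn_in),
                 scenario = scenario, model_kind = model$kind),
            class = "ensemble_summary")
}

#' Integer-valued projection with demographic stochasticity
#'
#' Projects individual counts rather than proportions: survivors of each
#' class are Binomial(n, p) draws and recruits are a Poisson draw with mean
#' equal to the total realized fecundity, on top of the same environmental
#' shock process as [simulate_run()]. Extinction is the first time the
#' population falls below one individual.
#'
#' @param model a calibrated `projection_model`.
#' @param scenario an [env_scenario()].
#' @param N0 initial population size, allocated multinomially across
#'   classes by the stable structure.
#' @param T maximum number of time steps.
#' @param seed optional seed overriding the scenario seed.
#' @return an object of class `demographic_run` with `counts`
#'   (classes x (T+1)), `N` (length T+1), `extinction_time` (`NA` if the
#'   run was censored at `T`) and `extinct` flag.
#' @export
demographic_run <- function(model, scenario, N0 = 10000L, T, seed = NULL) {
  stopifnot(inherits(model, "projection_model"),
            inherits(scenario, "env_scenario"),
            .is_count(N0), N0 >= 0, .is_count(T), T >= 1)
  n <- length(model$survival)
  if (!is.null(seed)) {
    scenario <- env_scenario(scenario$mode, scenario$sigma, seed)
  }
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  # shocks drawn first (same stream layout as simulate_run), then the
  # demographic draws consume the stream sequentially
  shocks <- list(eps = stats::rnorm(T, 0, scenario$sigma),
                 delta = switch(scenario$mode,
                                negative = NULL, positive = NULL,
                                null = stats::rnorm(T, 0, scenario$sigma)))
  shocks$delta <- switch(scenario$mode,
                         negative = -shocks$eps,
                         positive = shocks$eps,
                         null = shocks$delta)
  rm_ <- .realized_matrices(model$survival, model$fecundity, shocks,
                            scenario$sigma)
  counts <- matrix(0L, n, T + 1L)
  if (N0 > 0)
    counts[, 1L] <- as.integer(stats::rmultinom(1, N0, model$w))
  N <- integer(T + 1L)
  N[1L] <- N0
  extinction_time <- if (N0 == 0) 0L else NA_integer_
  kind <- model$kind
  if (N0 > 0) {
    for (t in seq_len(T)) {
      prev <- counts[, t]
      surv <- stats::rbinom(n, prev, rm_$P[, t])
      nxt <- integer(n)
      if (n > 1L) nxt[2:n] <- surv[1:(n - 1L)]
      if (kind == "one_adult_stage") nxt[n] <- nxt[n] + surv[n]
      nxt[1L] <- nxt[1L] + stats::rpois(1, sum(prev * rm_$B[, t]))
      counts[, t + 1L] <- nxt
      N[t + 1L] <- sum(nxt)
      if (N[t + 1L] < 1L) {
        extinction_time <- t
        break
      }
    }
  }
  structure(list(counts = counts, N = N, T = T,
                 extinction_time = extinction_time,
                 extinct = !is.na(extinction_time),
                 scenario = scenario, model_kind = kind),
            class = "demographic_run")
}

#' @export
print.demographic_run <- function(x, ...) {
  cat(sprintf("<demographic_run> %s, T = %d, N0 = %d, %s\n",
              x$model_kind, x$T, x$N[1L],
              if (x$extinct) sprintf("extinct at t = %d", x$extinction_time)
              else sprintf("censored (N_T = %d)", x$N[x$T + 1L])))
  invisible(x)
}
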