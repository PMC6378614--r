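# Likelihood-based fitting and selection of mortality models on
# age-at-death samples. Deaths are fully observed; an optional
# left-truncation age supports adult-only trajectories. Default criterion
# is AIC from maximum likelihood; an adaptive Metropolis sampler provides
# DIC when requested.

# registry of fittable families: free parameter names and starting-value
# heuristics (on the natural scale). Composite juvenile families carry the
# adult family name.
.fit_registry <- function() {
  list(
    constant = list(npar = 1L, pnames = "c"),
    gompertz = list(npar = 2L, pnames = c("a", "b")),
    gompertz_makeham = list(npar = 3L, pnames = c("a", "b", "c")),
    weibull2 = list(npar = 2L, pnames = c("a", "l")),
    weibull3 = list(npar = 3L, pnames = c("a", "l", "c")),
    logistic = list(npar = 3L, pnames = c("a", "b", "s")),
    siler_bathtub = list(npar = 5L,
                         pnames = c("a1", "b1", "c", "a2", "b2")),
    juvenile_gompertz = list(npar = 4L,
                             pnames = c("a1", "b1", "a", "b"),
                             adult = "gompertz"),
    juvenile_gompertz_makeham = list(npar = 5L,
                                     pnames = c("a1", "b1", "a", "b", "c"),
                                     adult = "gompertz_makeham"),
    juvenile_logistic = list(npar = 5L,
                             pnames = c("a1", "b1", "a", "b", "s"),
                             adult = "logistic")
  )
}

#' Registry of fittable mortality families
#'
#' The ten families available to [fit_mle()] and [select_model()]: the six
#' base hazard families, three juvenile-decline composites (a declining
#' exponential juvenile term added to a Gompertz, Gompertz-Makeham or
#' logistic adult hazard) and the Siler bathtub.
#'
#' @return character vector of family names.
#' @export
fit_families <- function() names(.fit_registry())

# build a hazard_model from a registry family name and a parameter vector
.registry_model <- function(family, params) {
  reg <- .fit_registry()[[family]]
  if (is.null(reg)) .stopf("unknown family '%s'", family)
  params <- stats::setNames(as.numeric(params), reg$pnames)
  if (!is.null(reg$adult)) {
    adult_pnames <- .family_param_names[[reg$adult]]
    hazard_model("juvenile_plus_adult", params[c("a1", "b1")],
                 adult = hazard_model(reg$adult, params[adult_pnames]))
  } else {
    hazard_model(family, params)
  }
}

#' Log-likelihood of an age-at-death sample
#'
#' The death-density log-likelihood
#' \deqn{\ell = \sum_i [\ln \mu(x_i) - H(x_i)]}
#' (with \eqn{+ H(x_0)} per observation under left-truncation at age
#' \eqn{x_0}). Out-of-domain parameters return `-Inf` by contract so the
#' function can be used directly inside optimizers and samplers.
#'
#' @param family a family name from [fit_families()].
#' @param params numeric parameter vector in registry order.
#' @param ages numeric vector of observed ages at death (or an
#'   `age_at_death_sample`).
#' @param truncation left-truncation age `x0` (default 0); all ages must
#'   be >= `x0`.
#' @return the log-likelihood (scalar; `-Inf` if parameters are outside
#'   the family domain).
#' @export
loglik_ages <- function(family, params, ages, truncation = 0) {
  if (inherits(ages, "age_at_death_sample")) ages <- ages$ages
  if (!length(ages)) .stopf("empty sample")
  if (any(ages < truncation)) .stopf("ages below the truncation age")
  if (any(!is.finite(params)) || any(params < 0)) return(-Inf)
  model <- tryCatch(.registry_model(family, params),
                    error = function(e) NULL)
  if (is.null(model)) return(-Inf)
  mu <- .mu_eval(model, ages)
  if (any(mu <= 0) || any(!is.finite(mu))) return(-Inf)
  ll <- sum(log(mu) - .H_eval(model, ages))
  if (truncation > 0) ll <- ll + length(ages) * .H_eval(model, truncation)
  if (!is.finite(ll)) return(-Inf)
  ll
}

# moment-based starting values on the natural scale; every rate-like
# parameter scales with 1/mean(age) so fits are age-unit aware
.fit_starts <- function(family, ages, truncation) {
  rate <- 1 / max(mean(ages - truncation), 1e-3)
  switch(family,
    constant = c(rate),
    gompertz = c(0.5 * rate, 0.5 * rate),
    gompertz_makeham = c(0.3 * rate, 0.5 * rate, 0.3 * rate),
    weibull2 = c(1.2, rate),
    weibull3 = c(1.2, rate, 0.3 * rate),
    logistic = c(0.5 * rate, 0.8 * rate, 0.5),
    siler_bathtub = c(rate, 4 * rate, 0.3 * rate, 0.2 * rate, 0.8 * rate),
    juvenile_gompertz = c(rate, 4 * rate, 0.3 * rate, 0.5 * rate),
    juvenile_gompertz_makeham = c(rate, 4 * rate, 0.2 * rate, 0.5 * rate,
                                  0.2 * rate),
    juvenile_logistic = c(rate, 4 * rate, 0.3 * rate, 0.8 * rate, 0.5)
  )
}

#' Maximum-likelihood fit of a mortality family
#'
#' Maximizes [loglik_ages()] by multi-start quasi-Newton optimization on
#' the log-parameter scale (all family parameters are non-negative;
#' the transform keeps the search unconstrained and scale-aware). Starts
#' are a moment-based heuristic plus lognormal jitter.
#'
#' @inheritParams loglik_ages
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the start jitter.
#' @return an object of class `mortality_fit`: `family`, `mle_params`
#'   (named), `loglik`, `k`, `aic`, `converged`, `truncation`, `n`.
#' @export
fit_mle <- function(family, ages, truncation = 0, n_starts = 5L,
                    seed = 1L) {
  if (inherits(ages, "age_at_death_sample")) ages <- ages$ages
  reg <- .fit_registry()[[family]]
  if (is.null(reg)) .stopf("unknown family '%s'", family)
  if (length(ages) < reg$npar)
    .stopf("sample size (%d) below number of free parameters (%d)",
           length(ages), reg$npar)
  # log scale; deaths at exactly 0 break log(mu) for some families, nudge
  ages <- pmax(ages, 1e-9)
  negll <- function(theta) {
    v <- -loglik_ages(family, exp(theta), ages, truncation)
    if (!is.finite(v)) 1e12 else v
  }
  base <- log(.fit_starts(family, ages, truncation))
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- base + if (s == 1L) 0 else stats::rnorm(length(base), 0, 0.7)
    opt <- tryCatch(
      stats::optim(th0, negll, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e11) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(structure(list(family = family,
                          mle_params = stats::setNames(
                            rep(NA_real_, reg$npar), reg$pnames),
                          loglik = NA_real_, k = reg$npar, aic = NA_real_,
                          converged = FALSE, truncation = truncation,
                          n = length(ages)),
                     class = "mortality_fit"))
  }
  # polish the winner with Nelder-Mead (robust near non-smooth boundaries)
  if (length(best$par) > 1L) {
    pol <- stats::optim(best$par, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
    if (pol$value < best$value) best <- pol
  }
  params <- stats::setNames(exp(best$par), reg$pnames)
  ll <- -best$value
  structure(list(family = family, mle_params = params, loglik = ll,
                 k = reg$npar, aic = 2 * reg$npar - 2 * ll,
                 converged = TRUE, truncation = truncation,
                 n = length(ages)),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("<mortality_fit> %s (k = %d, n = %d)%s\n", x$family, x$k,
              x$n, if (x$converged) "" else " [NOT CONVERGED]"))
  if (x$converged) {
    cat("  params:",
        paste(sprintf("%s=%.5g", names(x$mle_params), x$mle_params),
              collapse = ", "), "\n")
    cat(sprintf("  loglik = %.3f, AIC = %.3f", x$loglik, x$aic))
    if (!is.null(x$dic)) cat(sprintf(", DIC = %.3f", x$dic))
    cat("\n")
  }
  invisible(x)
}

#' DIC via adaptive Metropolis sampling
#'
#' Computes the deviance information criterion for one family by a
#' random-walk Metropolis sampler on the log-parameter scale (flat prior
#' there), with the proposal scale adapted during burn-in towards an
#' acceptance rate near 0.3. DIC = \eqn{\bar D + p_D} with
#' \eqn{p_D = \bar D - D(\bar\theta)}, \eqn{\bar\theta} the posterior mean
#' of the log-parameters.
#'
#' @inheritParams loglik_ages
#' @param start starting values (natural scale); defaults to the MLE.
#' @param iter,burn_in total iterations and burn-in (defaults 10000/2000).
#' @param seed sampler seed.
#' @return a list with `dic`, `p_d`, `d_bar`, `acceptance`, `posterior_mean`
#'   (natural scale).
#' @export
dic_metropolis <- function(family, ages, truncation = 0, start = NULL,
                           iter = 10000L, burn_in = 2000L, seed = 1L) {
  if (inherits(ages, "age_at_death_sample")) ages <- ages$ages
  reg <- .fit_registry()[[family]]
  if (is.null(reg)) .stopf("unknown family '%s'", family)
  if (is.null(start)) {
    fit <- fit_mle(family, ages, truncation, seed = seed)
    if (!fit$converged) .stopf("MLE start for '%s' did not converge", family)
    start <- fit$mle_params
  }
  set.seed(as.integer(seed))
  npar <- reg$npar
  theta <- log(pmax(start, 1e-12))
  ll <- loglik_ages(family, exp(theta), ages, truncation)
  scale <- rep(0.1, npar)
  keep <- matrix(NA_real_, iter - burn_in, npar)
  dev <- numeric(iter - burn_in)
  acc <- 0L
  for (i in seq_len(iter)) {
    prop <- theta + stats::rnorm(npar, 0, scale)
    llp <- loglik_ages(family, exp(prop), ages, truncation)
    if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
      theta <- prop; ll <- llp
      if (i > burn_in) acc <- acc + 1L
      if (i <= burn_in) scale <- scale * 1.02
    } else if (i <= burn_in) {
      scale <- scale * 0.99
    }
    if (i > burn_in) {
      keep[i - burn_in, ] <- theta
      dev[i - burn_in] <- -2 * ll
    }
  }
  d_bar <- mean(dev)
  theta_bar <- colMeans(keep)
  d_hat <- -2 * loglik_ages(family, exp(theta_bar), ages, truncation)
  p_d <- d_bar - d_hat
  list(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar,
       acceptance = acc / (iter - burn_in),
       posterior_mean = stats::setNames(exp(theta_bar), reg$pnames))
}

#' Fit and rank competing mortality families
#'
#' Fits each family by [fit_mle()] and ranks them by AIC (default) or DIC
#' (via [dic_metropolis()]). Ties are broken in favour of fewer
#' parameters; non-converged fits are excluded with a warning.
#'
#' @inheritParams loglik_ages
#' @param families character vector of >= 2 family names from
#'   [fit_families()].
#' @param criterion `"aic"` (default) or `"dic"`.
#' @param seed seed passed to the optimizer (and sampler).
#' @param ... further arguments to [dic_metropolis()].
#' @return an object of class `model_selection`: list with `fits` (ranked)
#'   and `table`, a data.frame with columns family, k, loglik, criterion
#'   value, delta, and the fitted parameters collapsed to a string.
#' @export
select_model <- function(ages, families, truncation = 0,
                         criterion = c("aic", "dic"), seed = 1L, ...) {
  criterion <- match.arg(criterion)
  if (length(families) < 2L)
    .stopf("need at least 2 families to rank")
  fits <- lapply(families, function(f)
    fit_mle(f, ages, truncation, seed = seed))
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!ok))
    warning("excluding non-converged fits: ",
            paste(families[!ok], collapse = ", "))
  fits <- fits[ok]
  if (!length(fits)) .stopf("no family converged")
  if (criterion == "dic") {
    for (i in seq_along(fits)) {
      d <- dic_metropolis(fits[[i]]$family, ages, truncation,
                          start = fits[[i]]$mle_params, seed = seed, ...)
      fits[[i]]$dic <- d$dic
    }
    score <- vapply(fits, function(f) f$dic, numeric(1))
  } else {
    score <- vapply(fits, function(f) f$aic, numeric(1))
  }
  k <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(score, k)
  fits <- fits[ord]; score <- score[ord]
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    criterion = score,
    delta = score - score[1L],
    params = vapply(fits, function(f)
      paste(sprintf("%s=%.6g", names(f$mle_params), f$mle_params),
            collapse = "; "), character(1)),
    stringsAsFactors = FALSE)
  names(tab)[4] <- criterion
  structure(list(fits = fits, table = tab, criterion = criterion),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> ranked by %s\n", toupper(x$criterion)))
  print(x$table[, 1:5], row.names = FALSE)
  invisible(x)
}
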