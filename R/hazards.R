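# Parametric age-specific mortality laws and their survival identities.
#
# Each family defines a hazard mu(x) >= 0 with a closed-form cumulative
# hazard H(x); survivorship is S(x) = exp(-H(x)) and the discrete per-age
# survival probability used in Leslie matrices is
# p_x = exp(-(H(x + 1) - H(x))).

.hazard_families <- c(
  "constant", "gompertz", "gompertz_makeham", "weibull2", "weibull3",
  "logistic", "siler_bathtub", "juvenile_plus_adult"
)

.family_param_names <- list(
  constant          = "c",
  gompertz          = c("a", "b"),
  gompertz_makeham  = c("a", "b", "c"),
  weibull2          = c("a", "l"),
  weibull3          = c("a", "l", "c"),
  logistic          = c("a", "b", "s"),
  siler_bathtub     = c("a1", "b1", "c", "a2", "b2"),
  juvenile_plus_adult = c("a1", "b1")
)

#' Parametric age-specific mortality model
#'
#' Constructs a hazard model from one of the families commonly used for
#' vertebrate mortality trajectories:
#'
#' * `constant`: \eqn{\mu(x) = c} (age-independent adult mortality);
#' * `gompertz`: \eqn{\mu(x) = a e^{bx}} (exponential senescent increase);
#' * `gompertz_makeham`: \eqn{\mu(x) = c + a e^{bx}};
#' * `weibull2`: \eqn{\mu(x) = a \ell (\ell x)^{a-1}} (power-law; shape
#'   `a < 1` gives mortality declining with age);
#' * `weibull3`: Weibull plus a Makeham constant `c`;
#' * `logistic`: gamma-Gompertz
#'   \eqn{\mu(x) = a e^{bx} / (1 + (a s / b)(e^{bx} - 1))}, decelerating
#'   towards a plateau for `s > 0`;
#' * `siler_bathtub`: \eqn{\mu(x) = a_1 e^{-b_1 x} + c + a_2 e^{b_2 x}}
#'   (declining juvenile mortality plus Gompertz-Makeham adult mortality);
#' * `juvenile_plus_adult`: a declining juvenile term
#'   \eqn{a_1 e^{-b_1 x}} added to any adult family supplied via `adult`
#'   (one of `gompertz`, `gompertz_makeham`, `logistic`).
#'
#' All parameters must be non-negative; negative values are a
#' parameter-domain error.
#'
#' @param family character; one of the family names above.
#' @param params named numeric vector of family parameters (see Details).
#' @param adult for `juvenile_plus_adult`, a `hazard_model` for the adult
#'   component.
#' @param age_unit label for the age unit ("years" or "months"); metadata
#'   only.
#' @return an object of class `hazard_model`.
#' @seealso [hazard()], [cumulative_hazard()], [annual_survival()],
#'   [truncation_age()]
#' @examples
#' m <- hazard_model("gompertz", c(a = 0.05, b = 0.15))
#' hazard(m, 0:5)
#' annual_survival(m, 0:5)
#' @export
hazard_model <- function(family, params, adult = NULL,
                         age_unit = c("years", "months")) {
  family <- match.arg(family, .hazard_families)
  age_unit <- match.arg(age_unit)
  wanted <- .family_param_names[[family]]
  if (is.null(names(params)) || !all(wanted %in% names(params)))
    .stopf("family '%s' needs named parameters: %s", family,
           paste(wanted, collapse = ", "))
  params <- params[wanted]
  if (any(!is.finite(params)))
    .stopf("non-finite parameter for family '%s'", family)
  if (any(params < 0))
    .stopf("negative parameter for family '%s': parameters must be >= 0",
           family)
  if (family == "juvenile_plus_adult") {
    if (!inherits(adult, "hazard_model"))
      .stopf("juvenile_plus_adult requires an 'adult' hazard_model")
    if (!adult$family %in% c("gompertz", "gompertz_makeham", "logistic"))
      .stopf("adult component must be gompertz, gompertz_makeham or logistic")
  } else if (!is.null(adult)) {
    .stopf("'adult' is only meaningful for family juvenile_plus_adult")
  }
  structure(
    list(family = family, params = params, adult = adult,
         age_unit = age_unit),
    class = "hazard_model"
  )
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("<hazard_model>", x$family, "\n  params:",
      paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "),
      sprintf(" [per %s]\n", sub("s$", "", x$age_unit)))
  if (!is.null(x$adult)) {
    cat("  adult component:\n")
    print(x$adult)
  }
  invisible(x)
}

# family-wise hazard evaluations, vectorised over x
.mu_eval <- function(model, x) {
  p <- model$params
  switch(model$family,
    constant = rep(p[["c"]], length(x)),
    gompertz = p[["a"]] * exp(p[["b"]] * x),
    gompertz_makeham = p[["c"]] + p[["a"]] * exp(p[["b"]] * x),
    weibull2 = {
      a <- p[["a"]]; l <- p[["l"]]
      # a < 1 diverges at x = 0; the limit value is what H increments use
      ifelse(x == 0 & a < 1, Inf,
             ifelse(x == 0 & a == 1, a * l, a * l * (l * x)^(a - 1)))
    },
    weibull3 = {
      a <- p[["a"]]; l <- p[["l"]]
      base <- ifelse(x == 0 & a < 1, Inf,
                     ifelse(x == 0 & a == 1, a * l, a * l * (l * x)^(a - 1)))
      base + p[["c"]]
    },
    logistic = {
      a <- p[["a"]]; b <- p[["b"]]; s <- p[["s"]]
      if (s == 0) {
        a * exp(b * x)
      } else if (b == 0) {
        a / (1 + a * s * x)
      } else {
        a * exp(b * x) / (1 + (a * s / b) * expm1(b * x))
      }
    },
    siler_bathtub = {
      p[["a1"]] * exp(-p[["b1"]] * x) + p[["c"]] +
        p[["a2"]] * exp(p[["b2"]] * x)
    },
    juvenile_plus_adult = {
      p[["a1"]] * exp(-p[["b1"]] * x) + .mu_eval(model$adult, x)
    }
  )
}

# closed-form cumulative hazards, vectorised over x
.H_eval <- function(model, x) {
  p <- model$params
  switch(model$family,
    constant = p[["c"]] * x,
    gompertz = {
      a <- p[["a"]]; b <- p[["b"]]
      if (b == 0) a * x else (a / b) * expm1(b * x)
    },
    gompertz_makeham = {
      a <- p[["a"]]; b <- p[["b"]]
      (if (b == 0) a * x else (a / b) * expm1(b * x)) + p[["c"]] * x
    },
    weibull2 = (p[["l"]] * x)^p[["a"]],
    weibull3 = (p[["l"]] * x)^p[["a"]] + p[["c"]] * x,
    logistic = {
      a <- p[["a"]]; b <- p[["b"]]; s <- p[["s"]]
      if (s == 0) {
        if (b == 0) a * x else (a / b) * expm1(b * x)
      } else if (b == 0) {
        log1p(a * s * x) / s
      } else {
        log1p((a * s / b) * expm1(b * x)) / s
      }
    },
    siler_bathtub = {
      a1 <- p[["a1"]]; b1 <- p[["b1"]]
      a2 <- p[["a2"]]; b2 <- p[["b2"]]
      # -expm1 form avoids catastrophic cancellation at tiny b1
      juv <- if (b1 == 0) a1 * x else -(a1 / b1) * expm1(-b1 * x)
      sen <- if (b2 == 0) a2 * x else (a2 / b2) * expm1(b2 * x)
      juv + p[["c"]] * x + sen
    },
    juvenile_plus_adult = {
      a1 <- p[["a1"]]; b1 <- p[["b1"]]
      juv <- if (b1 == 0) a1 * x else -(a1 / b1) * expm1(-b1 * x)
      juv + .H_eval(model$adult, x)
    }
  )
}

#' Age-specific hazard rate
#'
#' Evaluates the mortality hazard \eqn{\mu(x)} of a [hazard_model()] at the
#' given ages. For the Weibull families with shape `a < 1` the hazard
#' diverges at exactly `x = 0`; `Inf` is returned there (only cumulative
#' hazard increments, which are finite, enter downstream computations).
#'
#' @param model a `hazard_model`.
#' @param x numeric vector of non-negative ages.
#' @return numeric vector of non-negative hazard rates (per age unit).
#' @export
hazard <- function(model, x) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(x < 0)) .stopf("ages must be >= 0")
  .mu_eval(model, x)
}

#' Cumulative hazard
#'
#' \eqn{H(x) = \int_0^x \mu(u) du}, so that survivorship is
#' \eqn{S(x) = e^{-H(x)}}. Closed forms exist for every family and are the
#' default; `method = "quadrature"` integrates the hazard numerically
#' (adaptive quadrature) as an independent cross-check.
#'
#' @param model a `hazard_model`.
#' @param x numeric vector of non-negative ages.
#' @param method "closed" (default) or "quadrature".
#' @return numeric vector, non-decreasing in `x`, with `H(0) = 0`.
#' @export
cumulative_hazard <- function(model, x, method = c("closed", "quadrature")) {
  stopifnot(inherits(model, "hazard_model"))
  method <- match.arg(method)
  if (any(x < 0)) .stopf("ages must be >= 0")
  if (method == "closed") return(.H_eval(model, x))
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    out <- tryCatch(
      stats::integrate(function(u) .mu_eval(model, u), 0, xi,
                       rel.tol = 1e-11, abs.tol = 1e-12,
                       subdivisions = 500L),
      error = function(e) .stopf("quadrature failed at x=%g: %s", xi,
                                 conditionMessage(e)))
    out$value
  }, numeric(1))
}

#' Discrete annual survival probability
#'
#' The probability of surviving the age interval `[x, x + 1)`, obtained
#' from the continuous hazard as
#' \eqn{p_x = \exp(-(H(x+1) - H(x)))}. This is the quantity that fills the
#' subdiagonal of a Leslie matrix.
#'
#' @inheritParams hazard
#' @return numeric vector of probabilities in `(0, 1]`.
#' @export
annual_survival <- function(model, x) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(x < 0)) .stopf("ages must be >= 0")
  exp(-(.H_eval(model, x + 1) - .H_eval(model, x)))
}

#' Truncation age for a finite Leslie matrix
#'
#' The smallest integer age \eqn{\omega} at which survivorship
#' \eqn{e^{-H(\omega)}} falls below `survivorship_floor`, capped at
#' `cap`. Finite projection matrices require such a maximum age; the
#' terminal class is assigned zero survival.
#'
#' @param model a `hazard_model`.
#' @param survivorship_floor survivorship threshold in (0, 1); default 1e-4.
#' @param cap hard maximum age; if the floor is not reached by `cap` a
#'   warning is issued and `cap` returned.
#' @return integer truncation age \eqn{\omega \ge 1}.
#' @export
truncation_age <- function(model, survivorship_floor = 1e-4, cap = 200L) {
  stopifnot(inherits(model, "hazard_model"))
  if (survivorship_floor <= 0 || survivorship_floor >= 1)
    .stopf("survivorship_floor must be in (0, 1)")
  target <- -log(survivorship_floor)
  H <- .H_eval(model, seq_len(cap))
  hit <- which(H > target)
  if (!length(hit)) {
    warning(sprintf(
      "survivorship floor %g not reached by age cap %d; using cap",
      survivorship_floor, cap))
    return(as.integer(cap))
  }
  as.integer(hit[1L])
}
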