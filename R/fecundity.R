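# Age-specific fecundity trajectories.

.fecundity_shapes <- c("F1_flat", "F2_increasing", "F3_declining",
                       "F4_hump_early", "F5_hump_late")

.shape_param_names <- list(
  F1_flat       = "level",
  F2_increasing = c("level", "rate"),
  F3_declining  = c("level", "rate"),
  F4_hump_early = c("level", "peak", "width"),
  F5_hump_late  = c("level", "peak", "width")
)

#' Age-specific fecundity trajectory
#'
#' Five qualitative shapes of adult fecundity, all zero before the maturity
#' age \eqn{\alpha}:
#'
#' * `F1_flat`: constant `level` from maturity on;
#' * `F2_increasing`: saturating increase
#'   `level * (1 - exp(-rate * (x - alpha + 1)))` (negative reproductive
#'   senescence);
#' * `F3_declining`: exponential decline `level * exp(-rate * (x - alpha))`
#'   (reproductive senescence from maturity); `rate = 0` degenerates to
#'   `F1_flat`;
#' * `F4_hump_early` / `F5_hump_late`: Gaussian hump
#'   `level * exp(-(x - peak)^2 / (2 width^2))`, unimodal with the peak age
#'   earlier (F4) or later (F5) in adult life.
#'
#' Fecundity levels are nominal: Leslie-matrix calibration rescales them so
#' the deterministic growth rate is one, so only the shape matters.
#'
#' @param shape one of the five shape names.
#' @param params named numeric vector (see Details); all must be >= 0.
#' @param maturity non-negative integer age at maturity \eqn{\alpha}.
#' @return an object of class `fecundity_shape`.
#' @seealso [fecundity_schedule()]
#' @export
fecundity_shape <- function(shape, params, maturity = 0L) {
  shape <- match.arg(shape, .fecundity_shapes)
  wanted <- .shape_param_names[[shape]]
  if (is.null(names(params)) || !all(wanted %in% names(params)))
    .stopf("shape '%s' needs named parameters: %s", shape,
           paste(wanted, collapse = ", "))
  params <- params[wanted]
  if (any(!is.finite(params)) || any(params < 0))
    .stopf("fecundity parameters must be finite and >= 0")
  if (!.is_count(maturity) || maturity < 0)
    .stopf("maturity must be a non-negative integer age")
  structure(list(shape = shape, params = params,
                 maturity = as.integer(maturity)),
            class = "fecundity_shape")
}

#' @export
print.fecundity_shape <- function(x, ...) {
  cat("<fecundity_shape>", x$shape, "\n  params:",
      paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "),
      sprintf("\n  maturity age: %d\n", x$maturity))
  invisible(x)
}

#' Evaluate a fecundity trajectory on ages 0..omega
#'
#' @param shape a [fecundity_shape()].
#' @param omega integer truncation age; must be >= the maturity age.
#' @return numeric vector of length `omega + 1` of per-age fecundities,
#'   zero below maturity.
#' @export
fecundity_schedule <- function(shape, omega) {
  stopifnot(inherits(shape, "fecundity_shape"))
  if (!.is_count(omega) || omega < 1) .stopf("omega must be an integer >= 1")
  alpha <- shape$maturity
  if (alpha > omega)
    .stopf("maturity age (%d) exceeds truncation age (%d)", alpha, omega)
  x <- 0:omega
  p <- shape$params
  b <- switch(shape$shape,
    F1_flat       = rep(p[["level"]], length(x)),
    F2_increasing = p[["level"]] * (1 - exp(-p[["rate"]] * (x - alpha + 1))),
    F3_declining  = p[["level"]] * exp(-p[["rate"]] * (x - alpha)),
    F4_hump_early = ,
    F5_hump_late  = p[["level"]] *
      exp(-(x - p[["peak"]])^2 / (2 * p[["width"]]^2))
  )
  b[x < alpha] <- 0
  b
}
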