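# Synthetic study inputs: the 5 x 5 mortality-by-fecundity trajectory
# grid, calibrated model pairs, and simulated age-at-death samples for the
# mortality-fitting module.

#' Default trajectory presets
#'
#' Reads the shipped preset file (five mortality shapes M1-M5 across five
#' distinct hazard families, five fecundity shapes F1-F5) or a user file
#' with the same structure, and returns constructed model objects.
#'
#' @param path YAML preset file; defaults to the file shipped with the
#'   package.
#' @return a list with named lists `mortality` (of [hazard_model()]) and
#'   `fecundity` (of [fecundity_shape()]).
#' @export
default_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "agestoch")
  cfg <- yaml::read_yaml(path)
  if (!all(c("mortality", "fecundity") %in% names(cfg)))
    .stopf("preset file must contain 'mortality' and 'fecundity' blocks")
  mortality <- lapply(cfg$mortality, function(m) {
    adult <- if (!is.null(m$adult))
      hazard_model(m$adult$family, unlist(m$adult$params))
    hazard_model(m$family, unlist(m$params), adult = adult)
  })
  fecundity <- lapply(cfg$fecundity, function(f)
    fecundity_shape(f$shape, unlist(f$params),
                    maturity = if (is.null(f$maturity)) 0L else f$maturity))
  list(mortality = mortality, fecundity = fecundity)
}

#' Build the mortality-by-fecundity trajectory grid
#'
#' Crosses the five mortality presets with the five fecundity presets into
#' 25 labelled combinations, builds the per-age schedules for each, and
#' (by default) calibrates both the full-age Leslie model and its
#' one-adult-stage reduction to a stationary deterministic growth rate.
#'
#' @param presets a preset list as returned by [default_presets()]; must
#'   contain exactly 5 mortality and 5 fecundity presets.
#' @param survivorship_floor,cap truncation controls, see
#'   [truncation_age()].
#' @param calibrate if `TRUE` (default), attach calibrated `full` and
#'   `collapsed` projection models to every combination.
#' @return an object of class `trajectory_grid`: a list of 25 combinations,
#'   each with `label` (e.g. "M1-F1"), `mortality_label`,
#'   `fecundity_label`, `schedules` and (if calibrated) `full` and
#'   `collapsed` models.
#' @export
make_grid <- function(presets = default_presets(),
                      survivorship_floor = 1e-4, cap = 200L,
                      calibrate = TRUE) {
  if (length(presets$mortality) != 5L)
    .stopf("expected 5 mortality presets, got %d",
           length(presets$mortality))
  if (length(presets$fecundity) != 5L)
    .stopf("expected 5 fecundity presets, got %d",
           length(presets$fecundity))
  mlab <- names(presets$mortality)
  flab <- names(presets$fecundity)
  if (anyDuplicated(mlab) || anyDuplicated(flab))
    .stopf("preset labels must be unique")
  combos <- list()
  for (mi in seq_along(mlab)) {
    for (fi in seq_along(flab)) {
      sched <- make_schedules(presets$mortality[[mi]],
                              presets$fecundity[[fi]],
                              survivorship_floor, cap)
      cell <- list(label = paste(mlab[mi], flab[fi], sep = "-"),
                   mortality_label = mlab[mi], fecundity_label = flab[fi],
                   schedules = sched)
      if (calibrate) {
        cell$full <- calibrate_fecundity(sched)
        cell$collapsed <- collapse_adult_stage(cell$full)
      }
      combos[[cell$label]] <- cell
    }
  }
  structure(combos, class = "trajectory_grid")
}

#' @export
print.trajectory_grid <- function(x, ...) {
  cat(sprintf("<trajectory_grid> %d combinations: %s ...\n", length(x),
              paste(utils::head(names(x), 5), collapse = ", ")))
  invisible(x)
}

#' Export the schedules of a trajectory grid
#'
#' Writes one long-format CSV with columns
#' (combo, age, rho, beta); output is byte-identical for identical
#' presets.
#'
#' @param grid a [make_grid()] result.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
export_grid_schedules <- function(grid, path) {
  stopifnot(inherits(grid, "trajectory_grid"))
  rows <- do.call(rbind, lapply(grid, function(cell) {
    df <- as.data.frame(cell$schedules)
    cbind(combo = cell$label, df)
  }))
  rows$rho <- sprintf("%.17g", rows$rho)
  rows$beta <- sprintf("%.17g", rows$beta)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Sample ages at death from a mortality model
#'
#' Draws i.i.d. ages at death from the density
#' \eqn{f(x) = \mu(x) e^{-H(x)}} by inverse-CDF sampling: targets
#' \eqn{H(x) = -\ln(1 - U)} are inverted on a dense grid of the cumulative
#' hazard and polished with Newton steps (\eqn{H' = \mu}). Deaths are fully
#' observed (no censoring or recapture process).
#'
#' @param model a [hazard_model()].
#' @param n sample size (>= 1).
#' @param seed integer seed; the sample is reproducible from it.
#' @return an object of class `age_at_death_sample`: list with `ages`
#'   (length `n`), `model`, `seed`.
#' @export
sample_ages_at_death <- function(model, n, seed) {
  stopifnot(inherits(model, "hazard_model"), .is_count(n), n >= 1,
            .is_count(seed))
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  target <- -log1p(-u)
  hmax <- max(target) * 1.0001 + 1e-9
  # find an upper age bound covering the largest target by doubling
  xmax <- 1
  for (i in 1:60) {
    if (.H_eval(model, xmax) >= hmax) break
    xmax <- xmax * 2
    if (i == 60) .stopf("failed to bracket the inverse cumulative hazard")
  }
  xs <- seq(0, xmax, length.out = 4096L)
  Hs <- .H_eval(model, xs)
  # H is non-decreasing; make strictly increasing for interpolation
  keep <- c(TRUE, diff(Hs) > 0)
  x0 <- stats::approx(Hs[keep], xs[keep], xout = target, rule = 2)$y
  # Newton polish; guard against the infinite hazard of Weibull a < 1 at 0
  for (i in 1:4) {
    mu <- .mu_eval(model, x0)
    step <- (.H_eval(model, x0) - target) / mu
    step[!is.finite(step)] <- 0
    x0 <- pmax(x0 - step, 0)
  }
  err <- abs(.H_eval(model, x0) - target)
  if (stats::median(err) > 1e-8)
    .stopf("inverse-CDF sampling failed to converge")
  structure(list(ages = x0, model = model, seed = as.integer(seed)),
            class = "age_at_death_sample")
}

#' @export
print.age_at_death_sample <- function(x, ...) {
  cat(sprintf(
    "<age_at_death_sample> n = %d from %s (seed %d); mean age %.3f\n",
    length(x$ages), x$model$family, x$seed, mean(x$ages)))
  invisible(x)
}
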