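# Projection matrices: construction, eigen-analysis, calibration to a
# stationary deterministic growth rate, and collapse of adult ages into a
# single stage.
#
# Census convention: the first row carries fecundities b_x with no survival
# discounting and the first subdiagonal carries survival probabilities p_x,
# so each column of the matrix sums to b_x + p_x and the yearly growth rate
# is the structure-weighted sum of (b_x + p_x). The stochastic simulator and
# the moment decompositions share this bookkeeping.

# Assemble the matrix from per-class survival/fecundity vectors. For the
# one-adult-stage kind the last class has a self-loop survival entry.
.assemble_matrix <- function(survival, fecundity, kind) {
  n <- length(survival)
  A <- matrix(0, n, n)
  if (n > 1L)
    A[cbind(2:n, 1:(n - 1L))] <- survival[1:(n - 1L)]
  if (kind == "one_adult_stage")
    A[n, n] <- A[n, n] + survival[n]
  A[1L, ] <- A[1L, ] + fecundity
  A
}

.projection_model <- function(survival, fecundity, kind, classes, alpha,
                              calibration_scale = NA_real_) {
  A <- .assemble_matrix(survival, fecundity, kind)
  eig <- dominant_eigen(A)
  structure(list(matrix = A, kind = kind, classes = classes,
                 survival = survival, fecundity = fecundity,
                 alpha = as.integer(alpha),
                 calibration_scale = calibration_scale,
                 lambda_d = eig$lambda, w = eig$w, v = eig$v),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %s, %d classes, lambda_d = %.8f\n",
              x$kind, length(x$classes), x$lambda_d))
  if (!is.na(x$calibration_scale))
    cat(sprintf("  fecundity calibration scale c = %.6g\n",
                x$calibration_scale))
  invisible(x)
}

#' Build an (uncalibrated) full-age Leslie matrix
#'
#' Places the fecundities \eqn{\beta_x} on the first row and the survival
#' probabilities \eqn{\rho_0, \ldots, \rho_{\omega-1}} on the first
#' subdiagonal of an \eqn{(\omega+1) \times (\omega+1)} matrix.
#'
#' @param sched a [schedules()] object.
#' @return a `projection_model` of kind `full_age` (not calibrated;
#'   see [calibrate_fecundity()]).
#' @export
build_leslie <- function(sched) {
  stopifnot(inherits(sched, "schedules"))
  .projection_model(survival = sched$rho, fecundity = sched$beta,
                    kind = "full_age", classes = as.character(0:sched$omega),
                    alpha = sched$alpha)
}

#' Dominant eigenvalue and Perron vectors of a projection matrix
#'
#' Returns the dominant eigenvalue \eqn{\lambda} together with the right
#' eigenvector `w` (stable structure, normalised to sum to one) and the
#' left eigenvector `v` (reproductive values, normalised so that
#' `sum(v * w) = 1`).
#'
#' @param x a `projection_model` or a non-negative square matrix.
#' @return a list with elements `lambda`, `w`, `v`.
#' @export
dominant_eigen <- function(x) {
  A <- if (inherits(x, "projection_model")) x$matrix else as.matrix(x)
  if (nrow(A) != ncol(A)) .stopf("matrix must be square")
  if (any(A < 0)) .stopf("projection matrix entries must be non-negative")
  er <- eigen(A)
  i <- which.max(Re(er$values))
  lambda <- Re(er$values[i])
  if (lambda <= 1e-300) {
    # no reproductive loop (e.g. all fecundities zero): the matrix is
    # nilpotent, the spectral radius is 0 and no Perron pair exists
    return(list(lambda = max(lambda, 0), w = NULL, v = NULL))
  }
  w <- Re(er$vectors[, i])
  w <- w * sign(sum(w))
  if (min(w) < -1e-8 * max(abs(w)))
    .stopf("dominant eigenvector is not non-negative; matrix structure is degenerate")
  w <- pmax(w, 0)
  w <- w / sum(w)
  el <- eigen(t(A))
  j <- which.min(abs(Re(el$values) - lambda) + abs(Im(el$values)))
  v <- Re(el$vectors[, j])
  v <- v * sign(sum(v))
  v <- pmax(v, 0)
  v <- v / sum(v * w)
  resid <- max(abs(A %*% w - lambda * w))
  if (resid > 1e-10 * max(1, lambda))
    .stopf("eigen residual %.3e exceeds tolerance; matrix may be defective",
           resid)
  list(lambda = lambda, w = w, v = v)
}

# TRUE if reproduction is reachable: some age with positive fecundity has
# positive survivorship from birth.
.has_reproductive_path <- function(survival, fecundity) {
  n <- length(survival)
  reach <- c(1, cumprod(survival[-n]))
  any(fecundity * reach > 0)
}

#' Calibrate fecundity so the deterministic growth rate is one
#'
#' Finds the scalar \eqn{c > 0} such that the Leslie matrix built from
#' \eqn{(\rho, c\beta)} has dominant eigenvalue exactly 1 (a stationary
#' population), by bisection on \eqn{\log c}: the dominant eigenvalue is
#' continuous and strictly increasing in the fecundity scale.
#'
#' @param sched a [schedules()] object.
#' @param tol tolerance on `|lambda - 1|` (default 1e-12, well inside the
#'   1e-10 calibration contract so the scale itself is pinned down).
#' @param bracket search interval for `c` (default `c(1e-8, 1e4)`).
#' @param max_iter bisection iteration cap (default 200).
#' @return a calibrated `projection_model` of kind `full_age`, carrying the
#'   scale in `$calibration_scale`.
#' @export
calibrate_fecundity <- function(sched, tol = 1e-12,
                                bracket = c(1e-8, 1e4), max_iter = 200L) {
  stopifnot(inherits(sched, "schedules"))
  if (!.has_reproductive_path(sched$rho, sched$beta))
    .stopf("no reproductive path: no age with positive fecundity is reachable")
  lam <- function(cc)
    .lambda_only(.assemble_matrix(sched$rho, cc * sched$beta, "full_age"))
  scale <- .bisect_calibration(lam, bracket, tol, max_iter)
  .projection_model(survival = sched$rho, fecundity = scale * sched$beta,
                    kind = "full_age", classes = as.character(0:sched$omega),
                    alpha = sched$alpha, calibration_scale = scale)
}

.lambda_only <- function(A)
  max(Re(eigen(A, only.values = TRUE)$values))

.bisect_calibration <- function(lam, bracket, tol, max_iter) {
  lo <- log(bracket[1]); hi <- log(bracket[2])
  flo <- lam(exp(lo)) - 1; fhi <- lam(exp(hi)) - 1
  if (flo > 0 || fhi < 0)
    .stopf("calibration bracket [%g, %g] does not straddle lambda = 1",
           bracket[1], bracket[2])
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- lam(exp(mid)) - 1
    if (abs(fm) < tol) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  exp(mid)
}

#' Collapse adult ages into a single stage
#'
#' Reduces a calibrated full-age model to the corresponding one-adult-stage
#' model: ages \eqn{0..\alpha-1} are kept as age classes and all adult ages
#' \eqn{x \ge \alpha} are pooled into one class with a self-loop. The adult
#' constants are stable-structure-weighted averages of the age-specific
#' rates,
#' \deqn{p_c = \sum_{x \ge \alpha} w^*_x \rho_x / \sum_{x \ge \alpha} w^*_x,}
#' and likewise for the adult fecundity \eqn{b_c}; the collapsed fecundities
#' are then rescaled (bisection again) so the collapsed model also has
#' \eqn{\lambda_d = 1}.
#'
#' @param full a calibrated `projection_model` of kind `full_age`.
#' @param alpha maturity age (first adult age); defaults to the model's own.
#' @param tol,bracket,max_iter recalibration controls as in
#'   [calibrate_fecundity()].
#' @return a calibrated `projection_model` of kind `one_adult_stage` with
#'   classes `0, ..., alpha-1, "adult"`. The pre-rescale adult constants are
#'   attached as attribute `"adult_constants"`.
#' @export
collapse_adult_stage <- function(full, alpha = full$alpha, tol = 1e-12,
                                 bracket = c(1e-8, 1e4), max_iter = 200L) {
  stopifnot(inherits(full, "projection_model"), full$kind == "full_age")
  n <- length(full$survival)
  omega <- n - 1L
  if (!.is_count(alpha) || alpha < 1 || alpha > omega)
    .stopf("alpha must be an integer in [1, omega]")
  w_star <- full$w
  ad <- (alpha + 1L):n
  wt <- w_star[ad] / sum(w_star[ad])
  p_c <- sum(wt * full$survival[ad])
  b_c <- sum(wt * full$fecundity[ad])
  surv <- c(full$survival[seq_len(alpha)], p_c)
  fec <- c(full$fecundity[seq_len(alpha)], b_c)
  if (!.has_reproductive_path_collapsed(surv, fec))
    .stopf("collapsed structure has no reproductive path")
  lam <- function(cc)
    .lambda_only(.assemble_matrix(surv, cc * fec, "one_adult_stage"))
  scale <- .bisect_calibration(lam, bracket, tol, max_iter)
  out <- .projection_model(
    survival = surv, fecundity = scale * fec, kind = "one_adult_stage",
    classes = c(as.character(seq_len(alpha) - 1L), "adult"),
    alpha = alpha, calibration_scale = scale)
  attr(out, "adult_constants") <- c(p_c = p_c, b_c = b_c,
                                    rescale = scale)
  out
}

.has_reproductive_path_collapsed <- function(survival, fecundity) {
  n <- length(survival)
  reach <- c(1, cumprod(survival[-n]))
  any(fecundity * reach > 0)
}

#' Export a projection matrix and its metadata
#'
#' Writes the dense matrix as CSV (with class labels) and a JSON metadata
#' file recording kind, maturity age, calibration scale and the
#' deterministic growth rate.
#'
#' @param model a `projection_model`.
#' @param csv_path,json_path output file paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
export_projection_model <- function(model, csv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(model, "projection_model"))
  if (!is.null(csv_path)) {
    m <- as.data.frame(model$matrix)
    names(m) <- model$classes
    utils::write.csv(cbind(class = model$classes, m), csv_path,
                     row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(kind = model$kind, alpha = model$alpha,
           n_classes = length(model$classes),
           calibration_scale = model$calibration_scale,
           lambda_d = model$lambda_d),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
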