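# Internal helpers shared across modules.

#' Derive a reproducible task seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Per-task
#' seeds are derived by a counter scheme: `(master + 1000003 * counter) mod
#' (2^31 - 1)`, mapped into `[1, 2^31 - 2]`. The scheme is platform
#' independent and documented so that every table produced by the package can
#' be regenerated from the master seed alone.
#'
#' @param master integer master seed.
#' @param counter non-negative integer task index.
#' @return a single integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, counter) {
  stopifnot(length(master) == 1L, length(counter) == 1L, counter >= 0)
  m <- 2147483647
  s <- (as.numeric(master) %% m + 1000003 * as.numeric(counter)) %% m
  as.integer(s %% (m - 1)) + 1L
}

# 1/T-normalised second moments: the decompositions are exact finite-sample
# identities only under the population (not n-1) normalisation.
.var1 <- function(x) mean((x - mean(x))^2)
.cov1 <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.finite(x) && x == floor(x)
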