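# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Family order is scientifically meaningful: increasing GC from L1 to H3.
.FAMILIES <- c("L1", "L2", "H1", "H2", "H3")
.GC_RICH <- c("H1", "H2", "H3")
.GC_POOR <- c("L1", "L2")

#' Isochore family levels
#'
#' The five Bernardi isochore families in order of increasing GC content.
#' `L1` and `L2` are the GC-poor families (the "genome desert"), `H1`,
#' `H2` and `H3` the GC-rich families (the "genome core").
#'
#' @return Character vector `c("L1", "L2", "H1", "H2", "H3")`.
#' @export
isochore_families <- function() .FAMILIES

.family_class <- function(family) {
  out <- rep(NA_character_, length(family))
  out[family %in% .GC_RICH] <- "GC-rich"
  out[family %in% .GC_POOR] <- "GC-poor"
  out[is.na(family) | family == "unassigned"] <- "unassigned"
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a global seed
#'
#' Every pipeline stage draws its random numbers from a seed derived
#' deterministically from the global seed and the stage name, so adding
#' or reordering stages never perturbs another stage's random stream.
#' The derivation is a small polynomial hash of the stage name folded
#' into the seed modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 7
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 99991
  as.integer((abs(as.numeric(seed)) %% 2147483647 + 1000003 * h) %% 2147483647)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector of
# eigenvalue 1, normalised to sum to one).
#' Stationary distribution of a family transition matrix
#'
#' @param transition Row-stochastic square matrix.
#' @return Numeric vector summing to 1, named like the matrix rows.
#' @export
transition_stationary <- function(transition) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition))
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(transition)
  v
}
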