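#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a root seed
#'
#' A fixed multiplicative hash of the root seed and the stage name, kept
#' below 2^31 so it is a valid R integer. Used by [runPipeline()] so that
#' individual stages can be re-run in isolation with the same randomness.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

#' Mean characters per group
#'
#' Utility mirroring the per-primer-pair locus mean reported for AFLP runs:
#' `total / nGroups`, rounded for display to one decimal.
#'
#' @param total total count (e.g. characters over all primer pairs).
#' @param nGroups number of groups (>= 1).
#' @return numeric mean (full precision; print with one decimal).
#' @examples
#' meanPerGroup(3588, 12)  # 299
#' @export
meanPerGroup <- function(total, nGroups) {
  if (nGroups < 1) stop("nGroups must be >= 1", call. = FALSE)
  total / nGroups
}
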