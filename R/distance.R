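#' Nei-Li fragment-sharing distance between two binary profiles
#'
#' Similarity is the fragment-sharing coefficient
#' \eqn{F = 2 n_{xy} / (n_x + n_y)}, where \eqn{n_x} and \eqn{n_y} count
#' bands present in each profile and \eqn{n_{xy}} counts shared bands.
#' Shared band *absence* contributes nothing. Missing cells are removed
#' pairwise before counting. The default distance is the bounded
#' fragment-sharing form \eqn{D = 1 - F}; `variant = "log"` gives the
#' divergence-corrected form \eqn{D = -\ln F}.
#'
#' @param x,y binary vectors (0/1/NA) of equal length.
#' @param variant "one_minus_F" (default) or "log".
#' @return distance; in `[0, 1]` for the default variant.
#' @examples
#' neiLiDistance(c(1, 1, 0, 1), c(1, 0, 1, 1))  # F = 2/3, D = 1/3
#' @export
neiLiDistance <- function(x, y, variant = c("one_minus_F", "log")) {
  variant <- match.arg(variant)
  if (length(x) != length(y))
    stop("profiles differ in length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  nx <- sum(x == 1); ny <- sum(y == 1)
  if (nx == 0L || ny == 0L)
    stop("Nei-Li distance undefined: a profile has zero bands after ",
         "pairwise deletion", call. = FALSE)
  nxy <- sum(x == 1 & y == 1)
  f <- 2 * nxy / (nx + ny)
  if (variant == "one_minus_F") 1 - f else -log(f)
}

#' All pairwise Nei-Li distances for an AFLP matrix
#'
#' @param x an [AFLPMatrix-class] with >= 2 taxa.
#' @param variant passed to [neiLiDistance()].
#' @return a [DistanceMatrix-class].
#' @export
neiLiDistanceMatrix <- function(x, variant = c("one_minus_F", "log")) {
  variant <- match.arg(variant)
  stopifnot(is(x, "AFLPMatrix"))
  if (nTaxa(x) < 2L) stop("need at least 2 taxa", call. = FALSE)
  m <- aflpCharacters(x)
  n <- nrow(m)
  labs <- rownames(m)
  A <- m == 1L
  A[is.na(A)] <- FALSE
  storage.mode(A) <- "numeric"
  V <- !is.na(m)
  storage.mode(V) <- "numeric"
  nxy <- tcrossprod(A)           # shared bands over pairwise-valid loci
  nx <- tcrossprod(A, V)         # bands of row taxon valid in both
  if (any(nx[upper.tri(nx)] == 0 | t(nx)[upper.tri(nx)] == 0)) {
    bad <- which(nx == 0 & upper.tri(nx) | t(nx) == 0 & upper.tri(nx),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("pair (%s, %s): Nei-Li distance undefined: a ",
                        "profile has zero bands after pairwise deletion"),
                 labs[bad[1L]], labs[bad[2L]]), call. = FALSE)
  }
  f <- 2 * nxy / (nx + t(nx))
  v <- if (variant == "one_minus_F") 1 - f else -log(f)
  diag(v) <- 0
  v <- (v + t(v)) / 2
  dimnames(v) <- list(labs, labs)
  DistanceMatrix(v)
}
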