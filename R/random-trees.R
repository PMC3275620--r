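## Tree-length skewness machinery: uniform random labeled topologies scored
## by parsimony, and the g1 moment skewness of the resulting length
## distribution. Strongly negative g1 indicates hierarchical signal.

#' Uniform random unrooted binary topology
#'
#' Sequential taxon addition with a uniformly chosen attachment edge, which
#' samples uniformly over labeled unrooted binary topologies.
#'
#' @param labels tip labels (>= 3).
#' @return an unrooted `phylo` without branch lengths.
#' @export
randomTopology <- function(labels) {
  n <- length(labels)
  if (n < 3L) stop("need >= 3 labels", call. = FALSE)
  nEdge <- 2L * n - 3L
  parent <- integer(nEdge); child <- integer(nEdge)
  parent[1:3] <- n + 1L; child[1:3] <- 1:3
  nedges <- 3L
  nextInternal <- n + 2L
  if (n > 3L) {
    for (k in 4:n) {
      e <- sample.int(nedges, 1L)
      w <- nextInternal; nextInternal <- nextInternal + 1L
      v <- child[e]
      child[e] <- w
      nedges <- nedges + 1L; parent[nedges] <- w; child[nedges] <- v
      nedges <- nedges + 1L; parent[nedges] <- w; child[nedges] <- k
    }
  }
  structure(list(edge = cbind(parent, child, deparse.level = 0),
                 tip.label = labels, Nnode = max(1L, n - 2L)),
            class = "phylo")
}

#' Parsimony lengths of random trees
#'
#' Scores `nTrees` uniformly random labeled topologies on the matrix with
#' the Fitch kernel, giving the tree-length distribution used by the g1
#' hierarchical-structure randomization.
#'
#' @param x an [AFLPMatrix-class].
#' @param nTrees number of random topologies (>= 1).
#' @param seed integer seed.
#' @return object of class `TreeLengthSample`: list with `lengths`
#'   (integer vector), `nTrees` and `seed`.
#' @export
randomTreeLengths <- function(x, nTrees = 10000L, seed = 1L) {
  stopifnot(is(x, "AFLPMatrix"))
  if (nTrees < 1L) stop("nTrees must be >= 1", call. = FALSE)
  labs <- taxonLabels(x)
  codes <- aflpCharacters(x) + 1L
  codes[is.na(codes)] <- 3L
  lengths <- withSeed(seed, vapply(seq_len(nTrees), function(i) {
    tr <- ape::reorder.phylo(randomTopology(labs), "postorder")
    sum(.fitchStepsC(tr$edge, codes, tr$Nnode))
  }, numeric(1)))
  structure(list(lengths = as.integer(lengths), nTrees = as.integer(nTrees),
                 seed = as.integer(seed)),
            class = "TreeLengthSample")
}

#' g1 moment skewness
#'
#' \eqn{g_1 = m_3 / m_2^{3/2}} with central moments using divisor n.
#' Undefined (error) for samples of size < 3 or zero variance.
#'
#' @param sample numeric vector, or a `TreeLengthSample` from
#'   [randomTreeLengths()].
#' @return numeric skewness.
#' @examples
#' g1Skewness(c(1, 2, 3, 4, 5))  # 0
#' @export
g1Skewness <- function(sample) {
  v <- if (inherits(sample, "TreeLengthSample")) sample$lengths else sample
  v <- as.numeric(v)
  n <- length(v)
  if (n < 3L) stop("g1 needs a sample of size >= 3", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop("g1 undefined: zero variance", call. = FALSE)
  m3 <- mean((v - m)^3)
  m3 / m2^1.5
}
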