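## Heuristic maximum-parsimony search: random-addition starting trees
## followed by NNI hill climbing, optionally honoring a topological
## constraint. phangorn::nni supplies the NNI neighborhood; scoring is the
## package's own kernel.

#' Does a tree satisfy a topological constraint?
#'
#' The constraint is a (possibly partially resolved, possibly
#' subset-leaved) tree. The check succeeds iff every non-trivial split of
#' the constraint is a split of `tree` restricted to the constraint's
#' taxa (unrooted split semantics).
#'
#' @param tree a `phylo`.
#' @param constraint a `phylo` on a subset of `tree`'s taxa, or `NULL`.
#' @return logical.
#' @export
checkConstraint <- function(tree, constraint) {
  if (is.null(constraint)) return(TRUE)
  ctaxa <- constraint$tip.label
  if (!all(ctaxa %in% tree$tip.label))
    stop("constraint taxa absent from tree: ",
         paste(setdiff(ctaxa, tree$tip.label), collapse = ", "),
         call. = FALSE)
  if (length(ctaxa) < 4L) return(TRUE)   # no non-trivial splits possible
  taxa <- sort(ctaxa)
  want <- treeSplits(constraint, taxa)
  if (!length(want)) return(TRUE)
  sub <- ape::keep.tip(tree, ctaxa)
  have <- treeSplits(sub, taxa)
  all(want %in% have)
}

## constraint-compatible subtree check during stepwise addition: the partial
## tree only contains some of the constraint taxa, so restrict the
## constraint too.
.partialConstraint <- function(constraint, presentTaxa) {
  if (is.null(constraint)) return(NULL)
  keep <- intersect(constraint$tip.label, presentTaxa)
  if (length(keep) < 4L) return(NULL)
  ape::keep.tip(constraint, keep)
}

## Attach leaf `lab` to edge e of unrooted tree (by Newick surgery through
## ape's bind.tree would be heavy; do it on the edge table instead).
.attachLeaf <- function(tree, edgeIdx, lab) {
  y <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                      tip.label = lab, edge.length = 0.5,
                      Nnode = 1L),
                 class = "phylo")
  out <- ape::bind.tree(tree, y, where = tree$edge[edgeIdx, 2L],
                        position = 0.5)
  out$edge.length <- rep(1, nrow(out$edge))
  out
}

#' Random-addition starting tree
#'
#' Adds taxa in random order; each new leaf is placed on the edge that
#' minimizes the parsimony length of the partial tree (first-best on ties),
#' skipping placements that violate the constraint.
#'
#' @param x an [AFLPMatrix-class].
#' @param constraint optional `phylo` constraint.
#' @return an unrooted `phylo` topology (unit branch lengths).
#' @keywords internal
.randomAdditionTree <- function(x, constraint = NULL) {
  taxa <- sample(taxonLabels(x))
  tree <- ape::unroot(ape::read.tree(
    text = sprintf("(%s,%s,%s);", taxa[1L], taxa[2L], taxa[3L])))
  tree$edge.length <- rep(1, nrow(tree$edge))
  for (lab in taxa[-(1:3)]) {
    pc <- .partialConstraint(constraint, c(tree$tip.label, lab))
    best <- NULL; bestLen <- Inf
    for (e in seq_len(nrow(tree$edge))) {
      cand <- .attachLeaf(tree, e, lab)
      if (!is.null(pc) && !checkConstraint(cand, pc)) next
      len <- sum(fitchSteps(cand, x))
      if (len < bestLen) { bestLen <- len; best <- cand }
    }
    if (is.null(best))
      stop("constraint incompatible with taxon set during stepwise addition",
           call. = FALSE)
    tree <- best
  }
  tree
}

#' Heuristic parsimony search
#'
#' Random-addition starting trees followed by nearest-neighbor-interchange
#' (NNI) hill climbing, rejecting rearrangements that violate the
#' constraint. All equally best distinct topologies encountered are
#' retained up to `keepMax`. Deterministic for a fixed `seed`.
#'
#' @param x an [AFLPMatrix-class] with >= 4 taxa.
#' @param constraint optional `phylo` whose groupings must be honored.
#' @param nStarts number of random-addition replicates.
#' @param keepMax cap on the number of equally parsimonious trees kept.
#' @param seed integer RNG seed.
#' @return list with `trees` (list of `phylo`), `score` (integer best
#'   length) and `nBest` (number of distinct best topologies found,
#'   possibly above the cap).
#' @export
heuristicSearch <- function(x, constraint = NULL, nStarts = 5L,
                            keepMax = 100L, seed = 1L) {
  stopifnot(is(x, "AFLPMatrix"))
  if (nTaxa(x) < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (!is.null(constraint) &&
      !all(constraint$tip.label %in% taxonLabels(x)))
    stop("constraint refers to taxa absent from the matrix", call. = FALSE)
  .checkNewickSafe(taxonLabels(x))
  withSeed(seed, {
    bestScore <- Inf
    bestKeys <- character(0)
    bestTrees <- list()
    nBest <- 0L
    taxaOrder <- sort(taxonLabels(x))
    for (s in seq_len(nStarts)) {
      tree <- .randomAdditionTree(x, constraint)
      score <- sum(fitchSteps(tree, x))
      repeat {
        nbs <- ape::.uncompressTipLabel(phangorn::nni(tree))
        improved <- FALSE
        for (nb in nbs) {
          if (!checkConstraint(nb, constraint)) next
          sc <- sum(fitchSteps(nb, x))
          if (sc < score) { score <- sc; tree <- nb; improved <- TRUE; break }
        }
        if (!improved) break
      }
      key <- paste(sort(treeSplits(tree, taxaOrder)), collapse = "|")
      if (score < bestScore) {
        bestScore <- score
        bestKeys <- key
        bestTrees <- list(tree)
        nBest <- 1L
      } else if (score == bestScore && !key %in% bestKeys) {
        nBest <- nBest + 1L
        if (length(bestTrees) < keepMax) {
          bestKeys <- c(bestKeys, key)
          bestTrees <- c(bestTrees, list(tree))
        }
      }
    }
    list(trees = bestTrees, score = as.integer(bestScore), nBest = nBest)
  })
}
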