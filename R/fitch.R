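## Parsimony scoring. The per-locus kernel is a unit-cost Sankoff dynamic
## program over the two band states, compiled in C++ (src/fitch.cpp); it is
## exact for multifurcating trees and treats missing cells as fully
## ambiguous {0, 1}. The score does not depend on where the tree is rooted.

.tipCodes <- function(tree, x) {
  m <- aflpCharacters(x)
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing))
    stop("tree leaves absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- m[tree$tip.label, , drop = FALSE]
  codes <- m + 1L
  codes[is.na(codes)] <- 3L
  codes
}

#' Per-locus parsimony steps on a tree
#'
#' @param tree a `phylo`; rooted or unrooted, polytomies allowed. Leaves
#'   must be a subset of the matrix taxa.
#' @param x an [AFLPMatrix-class].
#' @return integer vector of minimum state changes, one per locus.
#' @export
fitchSteps <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), is(x, "AFLPMatrix"))
  codes <- .tipCodes(tree, x)
  tr <- ape::reorder.phylo(tree, "postorder")
  steps <- .fitchStepsC(tr$edge, codes, tr$Nnode)
  names(steps) <- locusLabels(x)
  steps
}

#' Total parsimony length of a tree
#'
#' Sums [fitchSteps()] over loci. For binary characters each per-locus
#' count is bounded by `min(#zeros, #ones)`.
#'
#' @inheritParams fitchSteps
#' @return list with `total` (integer) and `perLocus` (integer vector).
#' @examples
#' m <- AFLPMatrix(rbind(A = 0, B = 1, C = 1, D = 1))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitchLength(tr, m)$total  # 1
#' @export
fitchLength <- function(tree, x) {
  perLocus <- fitchSteps(tree, x)
  list(total = sum(perLocus), perLocus = perLocus)
}
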