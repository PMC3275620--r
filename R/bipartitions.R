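## Canonical bipartition (split) handling. A split of the taxon set is stored
## as a 0/1 string relative to a fixed taxon ordering, canonicalized so that
## the block containing the first taxon is coded 0; a split and its complement
## therefore share one key. Trivial splits (single taxon vs rest) are never
## emitted by treeSplits().

#' Canonical key for a taxon-set split
#'
#' @param members character vector: taxa on one side of the split.
#' @param taxa character vector: the full taxon ordering the key is
#'   relative to.
#' @return a single character key; `splitKey(members)` and
#'   `splitKey(setdiff(taxa, members))` are identical.
#' @export
splitKey <- function(members, taxa) {
  if (!all(members %in% taxa))
    stop("split members outside the taxon set", call. = FALSE)
  side <- taxa %in% members
  if (side[1L]) side <- !side
  paste(as.integer(side), collapse = "")
}

.keyToMembers <- function(key, taxa) {
  bits <- as.integer(strsplit(key, "")[[1L]])
  taxa[bits == 1L]
}

#' Non-trivial splits of a tree
#'
#' Returns the canonical keys for every internal (non-trivial, non-root)
#' bipartition of an ape `phylo` tree, relative to the ordering `taxa`.
#'
#' @param tree a `phylo` object (rooted or unrooted, polytomies allowed).
#' @param taxa taxon ordering for the keys; default `tree$tip.label`. Must
#'   be a superset-free permutation of the tree's tips.
#' @return character vector of unique canonical keys.
#' @export
treeSplits <- function(tree, taxa = tree$tip.label) {
  if (!setequal(taxa, tree$tip.label))
    stop("'taxa' must be a permutation of the tree's tip labels",
         call. = FALSE)
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    members <- labs[idx]
    k <- length(members)
    if (k <= 1L || k >= n - 1L) return(NA_character_)
    splitKey(members, taxa)
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Compare two tree topologies by their splits
#'
#' Robinson-Foulds-style comparison on the shared leaf set: counts splits
#' present in both trees, and splits unique to each.
#'
#' @param a,b `phylo` trees on the same leaf set.
#' @return list with `identical` (logical), `shared`, `onlyA`, `onlyB`
#'   (counts) and `rfDistance` (`onlyA + onlyB`).
#' @export
compareTopologies <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  taxa <- sort(a$tip.label)
  sa <- treeSplits(a, taxa)
  sb <- treeSplits(b, taxa)
  shared <- length(intersect(sa, sb))
  onlyA <- length(setdiff(sa, sb))
  onlyB <- length(setdiff(sb, sa))
  list(identical = onlyA == 0L && onlyB == 0L,
       shared = shared, onlyA = onlyA, onlyB = onlyB,
       rfDistance = onlyA + onlyB)
}

## Tree labels must survive a round trip through Newick text; the package
## builds trees by assembling Newick strings, so metacharacters are refused.
.checkNewickSafe <- function(labels) {
  bad <- grepl("[(),:;'\"\\[\\]\\s]", labels, perl = TRUE)
  if (any(bad))
    stop("taxon label not usable in Newick output: '", labels[bad][1L],
         "' (no parentheses, commas, colons, semicolons, quotes, brackets ",
         "or whitespace)", call. = FALSE)
  invisible(TRUE)
}
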