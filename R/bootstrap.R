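## Nonparametric bootstrap over loci (columns resampled with replacement),
## with split frequencies mapped back onto the full-data reference tree.

.buildTree <- function(x, method, mpStarts = 1L, mpSeed = 1L) {
  if (method == "nj") {
    neighborJoining(neiLiDistanceMatrix(x))
  } else {
    heuristicSearch(x, nStarts = mpStarts, seed = mpSeed)$trees[[1L]]
  }
}

## One full bootstrap pass; returns the reference tree, the taxon ordering
## used for keys, and the per-replicate split key sets (needed verbatim by
## the homoplasy excess test).
.bootstrapRun <- function(x, method, replicates, seed, mpStarts = 1L) {
  taxa <- sort(taxonLabels(x))
  reference <- withSeed(deriveSeed(seed, "reference"),
                        .buildTree(x, method, mpStarts, mpSeed = seed))
  repSplits <- withSeed(seed, lapply(seq_len(replicates), function(b) {
    idx <- sample.int(nLoci(x), nLoci(x), replace = TRUE)
    xb <- x[, idx]
    tb <- .buildTree(xb, method, mpStarts,
                     mpSeed = deriveSeed(seed, paste0("rep", b)))
    treeSplits(tb, taxa)
  }))
  list(reference = reference, taxa = taxa, repSplits = repSplits)
}

.supportFromSplits <- function(repSplits, keys) {
  if (!length(keys)) return(numeric(0))
  counts <- vapply(keys, function(k)
    sum(vapply(repSplits, function(s) k %in% s, logical(1))), numeric(1))
  100 * counts / length(repSplits)
}

## Annotate a tree's internal nodes with split support percentages.
.annotateSupport <- function(tree, taxa, repSplits) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  labels <- rep(NA_character_, nn)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  for (i in seq_len(nn)) {
    members <- labs[pp[[i]]]
    k <- length(members)
    if (k <= 1L || k >= n - 1L) next
    key <- splitKey(members, taxa)
    labels[i] <- sprintf("%.1f", .supportFromSplits(repSplits, key))
  }
  tree$node.label <- labels
  tree
}

#' Bootstrap bipartition support
#'
#' Resamples loci with replacement, rebuilds the tree for each replicate
#' (neighbor joining on Nei-Li distances, or heuristic parsimony search),
#' and maps split frequencies onto the full-data reference tree. Mean
#' support is averaged over the reference tree's internal (non-trivial)
#' splits, matching how a mean bootstrap value is read off a drawn tree.
#'
#' @param x an [AFLPMatrix-class].
#' @param method "nj" or "mp".
#' @param replicates bootstrap replicate count (>= 1).
#' @param seed integer seed; the replicate column draws and any search
#'   randomness derive from it.
#' @param mpStarts random-addition starts per parsimony search.
#' @return list with `tree` (reference `phylo`, node labels = support
#'   percentages) and `profile` (a [SupportProfile-class]).
#' @export
bootstrapSupport <- function(x, method = c("nj", "mp"), replicates = 1000L,
                             seed = 1L, mpStarts = 1L) {
  method <- match.arg(method)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  run <- .bootstrapRun(x, method, replicates, seed, mpStarts)
  refKeys <- treeSplits(run$reference, run$taxa)
  allKeys <- unique(c(refKeys, unlist(run$repSplits)))
  support <- .supportFromSplits(run$repSplits, allKeys)
  profile <- new("SupportProfile",
                 splits = data.frame(key = allKeys, support = support,
                                     inReference = allKeys %in% refKeys,
                                     stringsAsFactors = FALSE),
                 taxa = run$taxa, replicates = as.integer(replicates),
                 method = method)
  tree <- .annotateSupport(run$reference, run$taxa, run$repSplits)
  list(tree = tree, profile = profile)
}
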