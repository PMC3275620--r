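#' Neighbor-joining tree construction
#'
#' Standard agglomerative neighbor joining: at each step the pair (i, j)
#' minimizing \eqn{Q(i,j) = (r-2) d(i,j) - R_i - R_j} is joined (r = current
#' number of clusters, R = row sums). Pendant lengths come from the usual
#' rate-corrected formulas. Ties in Q are broken deterministically by
#' joining the lexicographically smallest pair of cluster labels (a cluster
#' is labelled by its smallest leaf). Negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch so that their sum
#' is preserved; at the terminal three-way join negatives are simply
#' clamped.
#'
#' @param d a [DistanceMatrix-class] (or plain labelled symmetric matrix)
#'   on at least 3 taxa.
#' @return an unrooted binary `phylo` with branch lengths.
#' @export
neighborJoining <- function(d) {
  D <- if (is(d, "DistanceMatrix")) as.matrix(d) else as.matrix(d)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labs <- rownames(D)
  .checkNewickSafe(labs)
  sub <- labs                 # Newick fragment per active cluster
  ordlab <- labs              # smallest contained leaf, for tie-breaking
  active <- rep(TRUE, n)
  Dm <- D
  while (sum(active) > 3L) {
    idx <- which(active)
    r <- length(idx)
    Dx <- Dm[idx, idx, drop = FALSE]
    R <- rowSums(Dx)
    Q <- (r - 2) * Dx - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 & upper.tri(Q), arr.ind = TRUE)
    pairLab <- apply(cand, 1L, function(rc) {
      p <- sort(c(ordlab[idx[rc[1L]]], ordlab[idx[rc[2L]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pairLab)[1L], ]
    i <- idx[pick[1L]]; j <- idx[pick[2L]]
    ii <- pick[1L]; jj <- pick[2L]
    dij <- Dx[ii, jj]
    vi <- dij / 2 + (R[ii] - R[jj]) / (2 * (r - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newSub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], vi, sub[j], vj)
    newDist <- (Dm[i, idx] + Dm[j, idx] - dij) / 2
    # reuse slot i for the merged cluster
    Dm[i, idx] <- newDist
    Dm[idx, i] <- newDist
    Dm[i, i] <- 0
    sub[i] <- newSub
    ordlab[i] <- min(ordlab[i], ordlab[j])
    active[j] <- FALSE
  }
  idx <- which(active)
  d12 <- Dm[idx[1L], idx[2L]]
  d13 <- Dm[idx[1L], idx[3L]]
  d23 <- Dm[idx[2L], idx[3L]]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  v <- pmax(v, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 sub[idx[1L]], v[1L], sub[idx[2L]], v[2L], sub[idx[3L]], v[3L])
  ape::read.tree(text = nwk)
}

#' Root an unrooted tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup,
#' splitting that edge's length evenly between the two root children. The
#' outgroup must form one side of a split of the unrooted tree; otherwise
#' an error names the conflict.
#'
#' @param tree unrooted `phylo`.
#' @param outgroup character vector of outgroup tip labels.
#' @return rooted `phylo`.
#' @export
rootTree <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup taxa missing from tree: ",
         paste(setdiff(outgroup, tree$tip.label), collapse = ", "),
         call. = FALSE)
  n <- length(tree$tip.label)
  if (length(outgroup) >= n)
    stop("outgroup cannot contain all taxa", call. = FALSE)
  if (length(outgroup) > 1L && length(outgroup) < n - 1L) {
    taxa <- sort(tree$tip.label)
    key <- splitKey(outgroup, taxa)
    if (!key %in% treeSplits(tree, taxa))
      stop("outgroup {", paste(outgroup, collapse = ", "),
           "} is not monophyletic in the unrooted tree: no split separates ",
           "it from the ingroup", call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!is.null(rooted$edge.length)) {
    rootNode <- length(rooted$tip.label) + 1L
    re <- which(rooted$edge[, 1L] == rootNode)
    if (length(re) == 2L) {
      tot <- sum(rooted$edge.length[re])
      rooted$edge.length[re] <- tot / 2
    }
  }
  rooted
}
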