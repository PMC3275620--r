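# Shared in-code fixtures for the test suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk except the
# packaged care table.

randomAFLP <- function(nTaxa, nLoci, seed, pMissing = 0) {
  withSeed(seed, {
    m <- matrix(rbinom(nTaxa * nLoci, 1L, 0.5), nTaxa,
                dimnames = list(sprintf("t%02d", seq_len(nTaxa)), NULL))
    if (pMissing > 0)
      m[runif(length(m)) < pMissing] <- NA_integer_
    AFLPMatrix(m)
  })
}

# a small calibrated tree-like matrix (cached per arg combination)
.simCache <- new.env()
simulatedMatrix <- function(nSpecies = 12, nLoci = 400, seed = 1,
                            noise = NULL, individuals = 1) {
  key <- paste(nSpecies, nLoci, seed, noise, individuals, sep = "_")
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  args <- list(nSpecies = nSpecies, individualsPerSpecies = individuals,
               nLoci = nLoci, seed = seed)
  if (!is.null(noise)) args$noise <- noise
  cfg <- do.call(simulationConfig, args)
  st <- simulateTree(cfg)
  sa <- simulateAFLP(st$tree, cfg)
  out <- list(config = cfg, tree = st$tree, speciesTree = st$speciesTree,
              speciesMap = st$speciesMap, matrix = sa$matrix,
              truth = sa$groundTruth)
  .simCache[[key]] <- out
  out
}

# matrix whose characters are perfectly compatible with a known topology:
# every internal edge of `tree` is marked by `perEdge` identical binary
# characters (clade members 1, rest 0)
compatibleMatrix <- function(tree, perEdge = 5) {
  taxa <- tree$tip.label
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  cols <- list()
  for (cl in pp) {
    members <- labs[cl]
    if (length(members) <= 1L || length(members) >= n - 1L) next
    col <- as.integer(taxa %in% members)
    cols <- c(cols, rep(list(col), perEdge))
  }
  # pendant bands plus ubiquitous bands, so no taxon can end up bandless
  # even in a column-resampled bootstrap replicate
  for (t_ in taxa) cols <- c(cols, rep(list(as.integer(taxa == t_)), 3))
  cols <- c(cols, rep(list(rep(1L, n)), 8))
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  AFLPMatrix(m)
}

# tree-like simulation conditioned on decent internal edges (mirrors the
# well-supported internodes of the motivating data set); deterministic per
# seedBase
treelikeSim <- function(seedBase, nSpecies = 10, nLoci = 800,
                        minEdge = 0.05, gainRate = NULL, lossRate = NULL) {
  for (k in 0:400) {
    cfg <- simulationConfig(nSpecies = nSpecies, individualsPerSpecies = 1,
                            nLoci = nLoci, noise = 0, sizeHomoplasyProb = 0,
                            gainRate = gainRate, lossRate = lossRate,
                            seed = seedBase + 1000 * k)
    st <- simulateTree(cfg)
    tr <- st$tree
    internal <- tr$edge[, 2] > length(tr$tip.label)
    if (min(tr$edge.length[internal]) < minEdge) next
    return(list(cfg = cfg, tree = tr,
                matrix = simulateAFLP(tr, cfg)$matrix))
  }
  stop("no tree with the required internode lengths")
}

# two maximally distant cherry tips (each parent has a sister whose clade
# the hybrid destabilizes)
cherryParents <- function(tree) {
  n <- length(tree$tip.label)
  tab <- tabulate(tree$edge[tree$edge[, 2] <= n, 1])
  cherries <- which(tab == 2)
  ct <- tree$tip.label[tree$edge[tree$edge[, 1] %in% cherries &
                                 tree$edge[, 2] <= n, 2]]
  D <- ape::cophenetic.phylo(tree)[ct, ct]
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  c(ct[ij[1]], ct[ij[2]])
}

# brute-force minimum parsimony steps for one binary locus by enumerating
# all internal-node state assignments of a rooted binary tree
bruteFitchLocus <- function(tree, states01) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- tr$Nnode
  best <- Inf
  tipStates <- states01[tr$tip.label]
  for (mask in 0:(2^nNode - 1L)) {
    assign_ <- c(tipStates, as.integer(intToBits(mask))[seq_len(nNode)])
    # skip assignments conflicting with observed tips (missing = free)
    changes <- 0
    okAll <- TRUE
    for (e in seq_len(nrow(tr$edge))) {
      p <- assign_[tr$edge[e, 1L]]; c_ <- assign_[tr$edge[e, 2L]]
      if (is.na(c_)) next  # missing tip: choose parent state (cost 0)
      if (is.na(p)) { okAll <- FALSE; break }
      changes <- changes + (p != c_)
    }
    if (okAll) best <- min(best, changes)
  }
  best
}

# brute-force Mk1 likelihood by summing over all internal-state assignments
bruteMk1Loglik <- function(tree, tipStates, alpha, prior = c(0.5, 0.5)) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- tr$Nnode
  ts <- tipStates[tr$tip.label]
  total <- 0
  for (mask in 0:(2^nNode - 1L)) {
    nodeStates <- as.integer(intToBits(mask))[seq_len(nNode)] + 1L
    assign_ <- c(ts, nodeStates)
    p <- prior[assign_[nTip + 1L]]
    for (e in seq_len(nrow(tr$edge))) {
      P <- mk1TransitionMatrix(alpha, tr$edge.length[e])
      p <- p * P[assign_[tr$edge[e, 1L]], assign_[tr$edge[e, 2L]]]
    }
    total <- total + p
  }
  log(total)
}

# distances implied by a tree with branch lengths (additive matrix)
additiveMatrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

randomBinaryTrait <- function(tree, seed, states = c("a", "b")) {
  withSeed(seed, {
    TraitTable(taxon = tree$tip.label,
               state = sample(states, length(tree$tip.label),
                              replace = TRUE),
               alphabet = states)
  })
}
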