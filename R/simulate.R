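## Synthetic AFLP generator with known ground truth. Loci evolve on a
## pure-birth species tree as a two-state (band present/absent) Markov chain
## with separate gain and loss rates; scoring noise flips cells, and
## fragment-size homoplasy merges random locus pairs into a single scored
## bin (logical OR). Conspecific individuals attach as shallow cherries or
## polytomies below each species tip.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a 16-species, 37-individual
#' AFLP survey with 3,588 scored characters of which roughly two thirds are
#' polymorphic: band loss twice as fast as gain, gain rate calibrated at
#' simulation time (see [calibrateGainRate()]) so the expected polymorphic
#' fraction matches `polymorphicTarget`, 2% per-cell scoring noise, 1%
#' bin-merge probability and within-species divergence at 2% of tree depth.
#'
#' @param nSpecies number of species (>= 2).
#' @param individualsPerSpecies integer scalar or vector (recycled) giving
#'   individuals sampled per species.
#' @param nLoci number of scored characters before bin merging.
#' @param gainRate band gain rate per unit branch length; `NULL` (default)
#'   calibrates it against `polymorphicTarget` on the simulated tree.
#' @param lossRate band loss rate; `NULL` gives `lossFactor * gainRate`.
#' @param lossFactor loss/gain ratio used when rates are calibrated.
#' @param polymorphicTarget expected polymorphic locus fraction used by the
#'   calibration (default 0.69, i.e. 2478/3588).
#' @param noise per-cell scoring flip probability (in [0, 0.5)).
#' @param sizeHomoplasyProb probability scale for merging locus pairs into
#'   one scored bin.
#' @param withinSpeciesDepth conspecific divergence as a fraction of tree
#'   depth.
#' @param traitRate symmetric Mk1 rate for the simulated care trait.
#' @param seed integer seed; identical configs give identical outputs.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSpecies = 16L,
                             individualsPerSpecies = c(3L, 1L, 1L, 1L, 3L,
                                                       3L, 1L, 1L, 1L, 2L,
                                                       4L, 3L, 2L, 2L, 4L,
                                                       5L),
                             nLoci = 3588L,
                             gainRate = NULL,
                             lossRate = NULL,
                             lossFactor = 2,
                             polymorphicTarget = 0.69,
                             noise = 0.02,
                             sizeHomoplasyProb = 0.01,
                             withinSpeciesDepth = 0.02,
                             traitRate = 0.5,
                             seed = 1L) {
  if (nSpecies < 2L) stop("nSpecies must be >= 2", call. = FALSE)
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)",
                                      call. = FALSE)
  ind <- rep_len(as.integer(individualsPerSpecies), nSpecies)
  if (any(ind < 1L)) stop("individualsPerSpecies must be >= 1", call. = FALSE)
  structure(list(nSpecies = as.integer(nSpecies),
                 individualsPerSpecies = ind,
                 nLoci = as.integer(nLoci), gainRate = gainRate,
                 lossRate = lossRate, lossFactor = lossFactor,
                 polymorphicTarget = polymorphicTarget, noise = noise,
                 sizeHomoplasyProb = sizeHomoplasyProb,
                 withinSpeciesDepth = withinSpeciesDepth,
                 traitRate = traitRate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a species tree with sampled individuals
#'
#' Pure-birth (Yule) topology with exponential waiting times, rescaled to
#' unit root-to-tip depth; conspecific individuals attach as a shallow
#' cherry/polytomy below each species tip at `withinSpeciesDepth` (capped
#' at half the species' pendant length).
#'
#' @param config a `SimulationConfig`.
#' @return list with `tree` (individual-level `phylo`), `speciesTree`
#'   (`phylo`), and `speciesMap` (named character: individual -> species).
#' @export
simulateTree <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(deriveSeed(config$seed, "tree"), {
    sp <- ape::rphylo(config$nSpecies, birth = 1, death = 0)
    sp$tip.label <- sprintf("sp%02d", seq_len(config$nSpecies))
    depth <- max(ape::node.depth.edgelength(sp))
    sp$edge.length <- sp$edge.length / depth
    nwk <- ape::write.tree(sp)
    pend <- stats::setNames(
      sp$edge.length[match(seq_len(config$nSpecies), sp$edge[, 2L])],
      sp$tip.label)
    speciesMap <- character(0)
    for (i in seq_len(config$nSpecies)) {
      lab <- sp$tip.label[i]
      m <- config$individualsPerSpecies[i]
      inds <- sprintf("%s_%d", lab, seq_len(m))
      speciesMap[inds] <- lab
      if (m == 1L) {
        nwk <- sub(paste0(lab, ":"), paste0(inds[1L], ":"), nwk, fixed = TRUE)
      } else {
        d <- min(config$withinSpeciesDepth, pend[[lab]] / 2)
        grp <- sprintf("(%s)", paste(sprintf("%s:%.10g", inds, d),
                                     collapse = ","))
        old <- sprintf("%s:%.10g", lab, pend[[lab]])
        # pendant string as written by write.tree: find "lab:" and splice
        pat <- paste0(lab, ":")
        pos <- regexpr(pat, nwk, fixed = TRUE)
        rest <- substr(nwk, pos + nchar(pat), nchar(nwk))
        lenStr <- sub("^([0-9eE.+-]+).*$", "\\1", rest)
        stem <- as.numeric(lenStr) - d
        nwk <- paste0(substr(nwk, 1L, pos - 1L),
                      grp, ":", sprintf("%.10g", stem),
                      substr(nwk, pos + nchar(pat) + nchar(lenStr),
                             nchar(nwk)))
      }
    }
    list(tree = ape::read.tree(text = nwk), speciesTree = sp,
         speciesMap = speciesMap)
  })
}

## Asymmetric two-state transition probabilities: state 1 = band absent,
## state 2 = band present; gain rate g (0 -> 1), loss rate l (1 -> 0).
.gainLossP <- function(g, l, t) {
  tot <- g + l
  if (tot == 0) return(diag(2))
  pi1 <- g / tot
  e <- exp(-tot * t)
  matrix(c(1 - pi1 * (1 - e), pi1 * (1 - e),
           (1 - pi1) * (1 - e), pi1 + (1 - pi1) * e),
         2L, 2L, byrow = TRUE)
}

#' Expected polymorphic fraction of a locus under the gain/loss chain
#'
#' Exact computation by pruning: one minus the probability that all tips
#' share the same *observed* band state, starting from the stationary root
#' distribution. Scoring noise enters through the tip emissions
#' (`P(observed | true) = 1 - noise` on the diagonal), so the expectation
#' refers to the scored matrix, which is what an empirical polymorphic
#' count measures.
#'
#' @param tree `phylo` with branch lengths.
#' @param gainRate,lossRate chain rates (> 0).
#' @param noise per-cell scoring flip probability.
#' @return probability between 0 and 1.
#' @export
expectedPolymorphicFraction <- function(tree, gainRate, lossRate,
                                        noise = 0) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  pi1 <- gainRate / (gainRate + lossRate)
  pAll <- vapply(1:2, function(target) {
    down <- vector("list", nTip + tr$Nnode)
    for (i in seq_len(nTip)) {
      v <- c(noise, noise); v[target] <- 1 - noise
      down[[i]] <- v
    }
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
      P <- .gainLossP(gainRate, lossRate, tr$edge.length[e])
      contrib <- as.numeric(P %*% down[[c_]])
      down[[p]] <- if (is.null(down[[p]])) contrib else down[[p]] * contrib
    }
    sum(c(1 - pi1, pi1) * down[[nTip + 1L]])
  }, numeric(1))
  1 - sum(pAll)
}

#' Calibrate the band gain rate to a target polymorphic fraction
#'
#' Solves for the gain rate (with `lossRate = lossFactor * gainRate`) whose
#' exact expected polymorphic fraction on the tree equals `target`.
#'
#' @param tree `phylo` with branch lengths.
#' @param target desired observed polymorphic locus fraction.
#' @param lossFactor loss/gain ratio (default 2).
#' @param noise per-cell scoring flip probability applied after the chain.
#' @return gain rate (numeric).
#' @export
calibrateGainRate <- function(tree, target = 0.69, lossFactor = 2,
                              noise = 0) {
  f <- function(logg) {
    g <- exp(logg)
    expectedPolymorphicFraction(tree, g, lossFactor * g, noise) - target
  }
  lo <- -8; hi <- 4
  if (f(lo) > 0 || f(hi) < 0)
    stop("target polymorphic fraction not reachable on this tree",
         call. = FALSE)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root)
}

#' Simulate an AFLP matrix on a tree
#'
#' Each locus evolves independently as the gain/loss chain from a
#' stationary root draw; scoring noise then flips each cell with
#' probability `noise`; finally, size homoplasy merges randomly chosen
#' disjoint locus pairs into single scored bins (logical OR of presence),
#' the number of merges being Binomial(floor(nLoci/2), sizeHomoplasyProb).
#' Ground truth retains the pre-noise, pre-merge tip and node states.
#'
#' @param tree individual-level `phylo` with branch lengths (e.g. from
#'   [simulateTree()]).
#' @param config a `SimulationConfig`.
#' @return list with `matrix` (an [AFLPMatrix-class]) and `groundTruth`
#'   (list: `tree`, `gainRate`, `lossRate`, `trueStates` tip matrix,
#'   `nodeStates`, `mergedPairs`).
#' @export
simulateAFLP <- function(tree, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  g <- config$gainRate
  if (is.null(g))
    g <- calibrateGainRate(tree, config$polymorphicTarget,
                           config$lossFactor, config$noise)
  l <- config$lossRate
  if (is.null(l)) l <- config$lossFactor * g
  nLoci <- config$nLoci
  withSeed(deriveSeed(config$seed, "aflp"), {
    tr <- ape::reorder.phylo(tree, "cladewise")
    nTip <- length(tr$tip.label)
    nTotal <- nTip + tr$Nnode
    states <- matrix(NA_integer_, nTotal, nLoci)
    pi1 <- if (g + l == 0) 0.5 else g / (g + l)
    root <- nTip + 1L
    states[root, ] <- rbinom(nLoci, 1L, pi1)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
      P <- .gainLossP(g, l, tr$edge.length[e])
      ps <- states[p, ]
      # P[s+1, 2] = probability child has the band given parent state s
      states[c_, ] <- rbinom(nLoci, 1L, P[ps + 1L, 2L])
    }
    tips <- states[seq_len(nTip), , drop = FALSE]
    rownames(tips) <- tr$tip.label
    observed <- tips
    if (config$noise > 0) {
      flips <- matrix(rbinom(length(observed), 1L, config$noise),
                      nrow(observed))
      observed <- abs(observed - flips)
    }
    mergedPairs <- NULL
    if (config$sizeHomoplasyProb > 0 && nLoci >= 4L) {
      nMerge <- rbinom(1L, floor(nLoci / 2), config$sizeHomoplasyProb)
      if (nMerge > 0L) {
        picked <- sample.int(nLoci, 2L * nMerge)
        mergedPairs <- matrix(picked, ncol = 2L)
        for (r in seq_len(nMerge)) {
          a <- mergedPairs[r, 1L]; b <- mergedPairs[r, 2L]
          observed[, a] <- pmax(observed[, a], observed[, b])
        }
        observed <- observed[, -mergedPairs[, 2L], drop = FALSE]
      }
    }
    colnames(observed) <- paste0("L", seq_len(ncol(observed)))
    list(matrix = AFLPMatrix(observed),
         groundTruth = list(tree = tree, gainRate = g, lossRate = l,
                            trueStates = tips,
                            nodeStates = states[(nTip + 1L):nTotal, ,
                                                drop = FALSE],
                            mergedPairs = mergedPairs))
  })
}

#' Append a synthetic hybrid taxon
#'
#' The hybrid copies each locus from `parents[1]` with probability
#' `mixing`, else from `parents[2]`.
#'
#' @param x an [AFLPMatrix-class].
#' @param parents character(2): distinct taxa present in `x`.
#' @param mixing proportion in (0, 1]; 1 duplicates the first parent.
#' @param seed integer seed.
#' @param label hybrid taxon label (default "hybrid").
#' @return list with `matrix` (the augmented [AFLPMatrix-class]) and
#'   `fromParent1` (logical per locus).
#' @export
injectHybrid <- function(x, parents, mixing = 0.5, seed = 1L,
                         label = "hybrid") {
  stopifnot(is(x, "AFLPMatrix"))
  if (length(parents) != 2L || parents[1L] == parents[2L])
    stop("parents must be two distinct taxa", call. = FALSE)
  absent <- setdiff(parents, taxonLabels(x))
  if (length(absent))
    stop("parent absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (mixing <= 0 || mixing > 1)
    stop("mixing must be in (0, 1]", call. = FALSE)
  m <- aflpCharacters(x)
  withSeed(seed, {
    from1 <- runif(ncol(m)) <= mixing
    hyb <- ifelse(from1, m[parents[1L], ], m[parents[2L], ])
    out <- rbind(m, matrix(hyb, 1L, dimnames = list(label, colnames(m))))
    list(matrix = AFLPMatrix(out), fromParent1 = from1)
  })
}

#' Simulate a binary trait under the symmetric Mk1 chain
#'
#' Evolves `n` independent binary characters from a uniform root draw with
#' symmetric rate `alpha`, recording every node state.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alpha symmetric rate (>= 0).
#' @param seed integer seed.
#' @param n number of characters (default 1).
#' @param stateNames character(2) naming the states.
#' @return for `n = 1`: list with `trait` (a [TraitTable-class]),
#'   `nodeStates` (named character) and `nChanges`; for `n > 1`: list with
#'   `tips` (integer matrix tips x n of state indices), `nodes` and
#'   `nChanges` (integer vector).
#' @export
simulateTrait <- function(tree, alpha, seed = 1L, n = 1L,
                          stateNames = c("maternal", "biparental")) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  tr <- ape::reorder.phylo(tree, "cladewise")
  nTip <- length(tr$tip.label)
  nTotal <- nTip + tr$Nnode
  withSeed(seed, {
    states <- matrix(NA_integer_, nTotal, n)
    root <- nTip + 1L
    states[root, ] <- sample(1:2, n, replace = TRUE)
    nChanges <- integer(n)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
      pStay <- 0.5 * (1 + exp(-2 * alpha * tr$edge.length[e]))
      switchIt <- rbinom(n, 1L, 1 - pStay)
      states[c_, ] <- ifelse(switchIt == 1L, 3L - states[p, ], states[p, ])
      nChanges <- nChanges + switchIt
    }
    if (n == 1L) {
      tipStates <- stateNames[states[seq_len(nTip), 1L]]
      list(trait = TraitTable(taxon = tr$tip.label, state = tipStates,
                              alphabet = stateNames),
           nodeStates = stats::setNames(
             stateNames[states[(nTip + 1L):nTotal, 1L]],
             as.character((nTip + 1L):nTotal)),
           nChanges = nChanges[1L])
    } else {
      tips <- states[seq_len(nTip), , drop = FALSE]
      rownames(tips) <- tr$tip.label
      nodes <- states[(nTip + 1L):nTotal, , drop = FALSE]
      rownames(nodes) <- as.character((nTip + 1L):nTotal)
      list(tips = tips, nodes = nodes, nChanges = nChanges)
    }
  })
}
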