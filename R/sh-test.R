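#' Shimodaira-Hasegawa topology test (RELL resampling)
#'
#' Compares candidate topologies on per-locus score vectors. The default
#' backend scores each locus by its Fitch parsimony steps; the "mk1"
#' backend uses per-locus negative log-likelihoods under the symmetric
#' two-state model with a single rate optimized per topology (branch
#' lengths taken from each tree, unit lengths substituted when absent).
#' Loci are resampled with replacement (RELL); each topology's resampled
#' totals are centered by their own mean, and the p-value for topology k is
#' the fraction of resamples in which the centered best-versus-k difference
#' is at least the observed difference. The best topology has difference 0
#' and p = 1.
#'
#' @param x an [AFLPMatrix-class].
#' @param topologies list of `phylo` trees on the same leaf set (subset of
#'   the matrix taxa); names are used in the result table.
#' @param score "parsimony" or "mk1".
#' @param resamples RELL resample count.
#' @param seed integer seed.
#' @return an [SHResult-class].
#' @export
shTest <- function(x, topologies, score = c("parsimony", "mk1"),
                   resamples = 1000L, seed = 1L) {
  score <- match.arg(score)
  if (length(topologies) < 2L)
    stop("need at least 2 topologies", call. = FALSE)
  leafSets <- lapply(topologies, function(t) sort(t$tip.label))
  if (!all(vapply(leafSets[-1L], identical, logical(1), leafSets[[1L]])))
    stop("topologies are on mismatched taxon sets", call. = FALSE)
  nm <- names(topologies)
  if (is.null(nm)) nm <- paste0("tree", seq_along(topologies))
  nm[!nzchar(nm)] <- paste0("tree", which(!nzchar(nm)))

  # per-locus scores, lower = better for both backends
  scores <- t(vapply(topologies, function(tr) {
    if (score == "parsimony") {
      as.numeric(fitchSteps(tr, x))
    } else {
      codes <- .tipCodes(tr, x)
      tr2 <- .ensureBranchLengths(tr)
      fit <- mk1EstimateRate(tr2, {
        cc <- aflpCharacters(x)[tr2$tip.label, , drop = FALSE] + 1L
        cc[is.na(cc)] <- NA_integer_
        cc
      })
      -.mk1SiteLogliks(tr2, codes, fit$alpha)
    }
  }, numeric(nLoci(x))))

  totals <- rowSums(scores)
  best <- which.min(totals)
  deltaObs <- totals - totals[best]

  S <- nLoci(x)
  K <- length(topologies)
  pvals <- withSeed(seed, {
    resTotals <- matrix(0, K, resamples)
    for (b in seq_len(resamples)) {
      idx <- sample.int(S, S, replace = TRUE)
      resTotals[, b] <- rowSums(scores[, idx, drop = FALSE])
    }
    centered <- resTotals - rowMeans(resTotals)
    # centered difference from the per-resample best (minimum score)
    D <- sweep(centered, 2L, apply(centered, 2L, min), "-")
    vapply(seq_len(K), function(k_) mean(D[k_, ] >= deltaObs[k_]),
           numeric(1))
  })
  new("SHResult",
      table = data.frame(topology = nm, score = totals, delta = deltaObs,
                         p = pvals, stringsAsFactors = FALSE),
      resamples = as.integer(resamples), scoreType = score)
}
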