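## Mk1 (Markov k-state, one-parameter) likelihood machinery: Felsenstein
## pruning over the symmetric k-state chain, single-rate estimation, and
## marginal ancestral reconstruction via a combined down/up pass.

#' Mk1 transition probability matrix
#'
#' Symmetric k-state chain with a single rate `alpha`:
#' P(stay, t) = 1/k + (1 - 1/k) exp(-k alpha t / (k - 1)); for k = 2 this
#' is 0.5 (1 + exp(-2 alpha t)). Rows sum to 1 for any t >= 0.
#'
#' @param alpha rate (>= 0), expected changes per unit branch length scale.
#' @param t branch length (>= 0).
#' @param k number of states.
#' @return k x k probability matrix.
#' @export
mk1TransitionMatrix <- function(alpha, t, k = 2L) {
  if (alpha < 0 || t < 0) stop("alpha and t must be >= 0", call. = FALSE)
  stay <- 1 / k + (1 - 1 / k) * exp(-k * alpha * t / (k - 1))
  off <- (1 - stay) / (k - 1)
  m <- matrix(off, k, k)
  diag(m) <- stay
  m
}

## Conditional (down) likelihoods for every node, vectorized across sites.
## tipL: list per tip id -> k x S likelihood matrix (indicator rows, or all
## ones for missing). Returns list per node id of k x S matrices.
.mk1Down <- function(tree, tipL, alpha, k) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nTotal <- nTip + tr$Nnode
  S <- ncol(tipL[[1L]])
  down <- vector("list", nTotal)
  down[seq_len(nTip)] <- tipL
  el <- tr$edge.length
  if (is.null(el)) stop("branch lengths required", call. = FALSE)
  if (any(el < 0)) stop("negative branch length", call. = FALSE)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
    P <- mk1TransitionMatrix(alpha, el[e], k)
    contrib <- P %*% down[[c_]]
    down[[p]] <- if (is.null(down[[p]])) contrib else down[[p]] * contrib
  }
  list(down = down, tree = tr)
}

.traitTipLikelihoods <- function(tree, traits) {
  alphabet <- stateAlphabet(traits)
  k <- length(alphabet)
  states <- traitStates(traits)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("leaf without trait state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tipL <- lapply(tree$tip.label, function(lab) {
    v <- matrix(0, k, 1L)
    v[match(states[[lab]], alphabet), 1L] <- 1
    v
  })
  list(tipL = tipL, k = k, alphabet = alphabet)
}

.ensureBranchLengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; substituting unit lengths",
            call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Mk1 log-likelihood of a discrete trait on a tree
#'
#' Felsenstein pruning over the symmetric one-parameter chain; the root is
#' integrated over `rootPrior` (uniform by default). Unit branch lengths
#' are substituted (with a warning) when the tree has none.
#'
#' @param tree rooted `phylo` with nonnegative branch lengths.
#' @param traits a [TraitTable-class] covering every leaf.
#' @param alpha symmetric rate (>= 0).
#' @param rootPrior numeric vector over states; default uniform.
#' @return log-likelihood (single numeric).
#' @export
mk1Loglik <- function(tree, traits, alpha, rootPrior = NULL) {
  tree <- .ensureBranchLengths(tree)
  tl <- .traitTipLikelihoods(tree, traits)
  if (is.null(rootPrior)) rootPrior <- rep(1 / tl$k, tl$k)
  res <- .mk1Down(tree, tl$tipL, alpha, tl$k)
  root <- length(tree$tip.label) + 1L
  log(sum(rootPrior * res$down[[root]][, 1L]))
}

## Per-site Mk1 log-likelihoods for a 0/1 character matrix (used by the SH
## test's likelihood backend). codes: nTip x S with 1/2/3 (3 = missing).
.mk1SiteLogliks <- function(tree, codes, alpha) {
  k <- 2L
  nTip <- nrow(codes)
  tipL <- lapply(seq_len(nTip), function(i) {
    m <- matrix(1, k, ncol(codes))
    m[2L, codes[i, ] == 1L] <- 0
    m[1L, codes[i, ] == 2L] <- 0
    m
  })
  res <- .mk1Down(tree, tipL, alpha, k)
  root <- nTip + 1L
  log(colSums(res$down[[root]] * 0.5))
}

#' Estimate the Mk1 rate from one or more characters
#'
#' Single-parameter bounded maximization (on log scale) of the summed
#' pruning log-likelihood.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states integer matrix (tips x characters) of state indices
#'   (1..k, `NA` = missing), rownames = tip labels; or a
#'   [TraitTable-class] for a single character.
#' @param k number of states (default 2).
#' @return list with `alpha` and `logLik`.
#' @export
mk1EstimateRate <- function(tree, states, k = 2L) {
  tree <- .ensureBranchLengths(tree)
  if (is(states, "TraitTable")) {
    tl <- .traitTipLikelihoods(tree, states)
    k <- tl$k
    codes <- matrix(vapply(tree$tip.label, function(lab) {
      match(traitStates(states)[[lab]], stateAlphabet(states))
    }, integer(1)), ncol = 1L)
  } else {
    codes <- states[tree$tip.label, , drop = FALSE]
  }
  cc <- codes
  cc[is.na(cc)] <- 3L
  f <- function(logAlpha) -sum(.mk1SiteLogliks(tree, cc, exp(logAlpha)))
  opt <- optimize(f, interval = c(-12, 8))
  if (!is.finite(opt$objective))
    stop("Mk1 rate optimization failed (non-finite likelihood); check ",
         "branch lengths", call. = FALSE)
  list(alpha = exp(opt$minimum), logLik = -opt$objective)
}

#' Marginal ancestral reconstruction under Mk1
#'
#' Fits the single rate by bounded likelihood maximization (unless `alpha`
#' is supplied), then computes marginal state probabilities for every
#' internal node by the standard down/up (re-rooting) pass. Nodes whose
#' best marginal falls below `threshold` are labelled equivocal.
#'
#' @param tree rooted `phylo` with branch lengths (unit lengths substituted
#'   with a warning when absent).
#' @param traits a [TraitTable-class].
#' @param alpha optional fixed rate; estimated when `NULL`.
#' @param threshold reportable-decision threshold on the max marginal
#'   (default 0.75).
#' @param rootPrior numeric prior over states; default uniform.
#' @return an [Mk1ASR-class].
#' @export
mk1Reconstruct <- function(tree, traits, alpha = NULL, threshold = 0.75,
                           rootPrior = NULL) {
  tree <- .ensureBranchLengths(tree)
  tl <- .traitTipLikelihoods(tree, traits)
  k <- tl$k
  if (is.null(rootPrior)) rootPrior <- rep(1 / k, k)
  if (is.null(alpha)) {
    fit <- mk1EstimateRate(tree, traits)
    alpha <- fit$alpha
  }
  res <- .mk1Down(tree, tl$tipL, alpha, k)
  tr <- res$tree
  down <- res$down
  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  nTotal <- nTip + tr$Nnode
  ll <- log(sum(rootPrior * down[[root]][, 1L]))

  # up pass (preorder): up[v] = likelihood of the rest of the tree given
  # the state at v
  up <- vector("list", nTotal)
  up[[root]] <- matrix(rootPrior, k, 1L)
  pre <- ape::reorder.phylo(tr, "cladewise")
  childrenOf <- split(seq_len(nrow(pre$edge)), pre$edge[, 1L])
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; u <- pre$edge[e, 2L]
    if (u <= nTip) next
    P_u <- mk1TransitionMatrix(alpha, pre$edge.length[e], k)
    sibE <- setdiff(childrenOf[[as.character(p)]], e)
    sibProd <- matrix(1, k, 1L)
    for (se in sibE) {
      P_s <- mk1TransitionMatrix(alpha, pre$edge.length[se], k)
      sibProd <- sibProd * (P_s %*% down[[pre$edge[se, 2L]]])
    }
    up[[u]] <- t(P_u) %*% (up[[p]] * sibProd)
  }

  marg <- matrix(NA_real_, tr$Nnode, k,
                 dimnames = list(as.character((nTip + 1L):nTotal),
                                 tl$alphabet))
  for (v in (nTip + 1L):nTotal) {
    w <- down[[v]][, 1L] * up[[v]][, 1L]
    marg[v - nTip, ] <- w / sum(w)
  }
  new("Mk1ASR", tree = tr, marginals = marg, alphaHat = alpha,
      logLik = ll, equivocal = apply(marg, 1L, max) < threshold,
      threshold = threshold)
}
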