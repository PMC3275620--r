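## Unordered-parsimony ancestral reconstruction with explicit enumeration of
## binary resolutions of polytomies, most-parsimonious-reconstruction (MPR)
## state sets, and min-max ranges of directional transition counts over all
## resolutions x all MPR assignments. Also the support-threshold edge
## contraction that produces the polytomies.

#' Collapse weakly supported nodes into polytomies
#'
#' Contracts every internal edge whose child node's support is below
#' `threshold` (percent). Node support is read from `tree$node.label`;
#' unlabelled nodes (e.g. the root) are never contracted. The contracted
#' edge's length is discarded.
#'
#' @param tree rooted or unrooted `phylo` with support values as internal
#'   node labels.
#' @param threshold support percentage below which an edge is contracted
#'   (default 50).
#' @return a `phylo`, possibly with polytomies.
#' @export
collapseWeakNodes <- function(tree, threshold = 50) {
  if (is.null(tree$node.label))
    stop("tree has no node support labels", call. = FALSE)
  nTip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  rootNode <- nTip + 1L
  kill <- which(!is.na(support) & support < threshold) + nTip
  kill <- setdiff(kill, rootNode)
  if (!length(kill)) return(tree)
  .contractNodes(tree, kill)
}

.contractNodes <- function(tree, kill) {
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  parentOf <- integer(nTip + tree$Nnode)
  parentOf[edge[, 2L]] <- edge[, 1L]
  killed <- logical(nTip + tree$Nnode)
  killed[kill] <- TRUE
  effParent <- function(v) {
    while (killed[v]) v <- parentOf[v]
    v
  }
  keepEdge <- !killed[edge[, 2L]]
  newParent <- vapply(edge[keepEdge, 1L], effParent, integer(1))
  newChild <- edge[keepEdge, 2L]
  survivors <- sort(unique(c(newParent, newChild[newChild > nTip])))
  remap <- integer(nTip + tree$Nnode)
  remap[seq_len(nTip)] <- seq_len(nTip)
  remap[survivors] <- nTip + seq_along(survivors)
  out <- list(edge = cbind(remap[newParent],
                           ifelse(newChild <= nTip, newChild,
                                  remap[newChild]),
                           deparse.level = 0),
              tip.label = tree$tip.label,
              Nnode = length(survivors))
  if (!is.null(tree$edge.length))
    out$edge.length <- tree$edge.length[keepEdge]
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[survivors - nTip]
  class(out) <- "phylo"
  out
}

#' Collapse an individual-level tree to one tip per species
#'
#' Verifies that each multi-individual species is monophyletic (an error
#' names the offenders otherwise), then keeps one representative tip per
#' species and relabels it with the species name. The representative keeps
#' its pendant branch, so species tips include the within-species terminal
#' branch.
#'
#' @param tree a `phylo` on individual labels.
#' @param speciesMap named character vector: individual -> species.
#' @return a `phylo` on species labels.
#' @export
collapseToSpecies <- function(tree, speciesMap) {
  if (!all(tree$tip.label %in% names(speciesMap)))
    stop("speciesMap missing individuals: ",
         paste(setdiff(tree$tip.label, names(speciesMap)), collapse = ", "),
         call. = FALSE)
  sp <- speciesMap[tree$tip.label]
  bad <- character(0)
  for (s in unique(sp)) {
    tips <- tree$tip.label[sp == s]
    if (length(tips) < 2L) next
    if (!ape::is.monophyletic(tree, tips)) bad <- c(bad, s)
  }
  if (length(bad))
    stop("species not monophyletic in the tree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  reps <- tapply(tree$tip.label, sp, `[`, 1L)
  out <- ape::keep.tip(tree, unname(reps))
  out$tip.label <- names(reps)[match(out$tip.label, reps)]
  out
}

## ---- nested-tree machinery for MPR over polytomy resolutions ----

.asNested <- function(tree) {
  nTip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(v) {
    if (v <= nTip)
      return(list(id = as.character(v), label = tree$tip.label[v],
                  children = NULL))
    list(id = as.character(v), label = NULL,
         children = lapply(kids[[as.character(v)]], build))
  }
  build(nTip + 1L)
}

## All rooted binary shapes over m items, as nested pair structures of item
## indices; (2m-3)!! shapes.
.binaryShapes <- function(m) {
  insertAll <- function(shape, leaf) {
    res <- list(list(shape, leaf))   # new root above everything
    if (is.list(shape)) {
      for (ci in 1:2) {
        for (sub in insertAll(shape[[ci]], leaf)) {
          s2 <- shape
          s2[[ci]] <- sub
          res <- c(res, list(s2))
        }
      }
    }
    res
  }
  shapes <- list(list(1L, 2L))
  if (m > 2L) {
    for (leaf in 3:m) {
      shapes <- unlist(lapply(shapes, insertAll, leaf = leaf),
                       recursive = FALSE)
    }
  }
  shapes
}

## Apply a pair-shape to a polytomy's children, generating fresh anonymous
## internal nodes.
.applyShape <- function(shape, children, counter) {
  if (!is.list(shape)) return(children[[shape]])
  left <- .applyShape(shape[[1L]], children, counter)
  right <- .applyShape(shape[[2L]], children, counter)
  counter$n <- counter$n + 1L
  list(id = paste0("res", counter$n), label = NULL,
       children = list(left, right))
}

## Enumerate all full binary resolutions of a nested tree (cartesian product
## over its polytomies). The root of a resolved polytomy keeps the original
## node's id so per-node results stay comparable across resolutions.
.enumerateResolutions <- function(node, counter, maxChildren = 7L) {
  if (is.null(node$children)) return(list(node))
  childAlternatives <- lapply(node$children, .enumerateResolutions,
                              counter = counter, maxChildren = maxChildren)
  combos <- list(list())
  for (alts in childAlternatives) {
    combos <- unlist(lapply(combos, function(cmb)
      lapply(alts, function(a) c(cmb, list(a)))), recursive = FALSE)
  }
  m <- length(node$children)
  if (m <= 2L) {
    return(lapply(combos, function(cmb)
      list(id = node$id, label = NULL, children = cmb)))
  }
  if (m > maxChildren)
    stop("polytomy with ", m, " children exceeds the enumeration cap (",
         maxChildren, "); raise the collapse threshold or resolve manually",
         call. = FALSE)
  shapes <- .binaryShapes(m)
  out <- list()
  for (cmb in combos) {
    for (sh in shapes) {
      top <- .applyShape(sh, cmb, counter)
      top$id <- node$id    # keep original identity at the polytomy root
      out <- c(out, list(top))
    }
  }
  out
}

.nestedNewick <- function(node) {
  if (is.null(node$children)) return(node$label)
  paste0("(", paste(vapply(node$children, .nestedNewick, character(1)),
                    collapse = ","), ")")
}

## Sankoff DP over k states with, per state, min and max counts of the
## focal directional change (fromIdx -> toIdx) among cost-optimal
## assignments of the subtree. Returns the node augmented with cost/minT/
## maxT (numeric k-vectors) and processed children.
.mprDown <- function(node, stateOf, k, fromIdx, toIdx) {
  BIG <- 1e9
  if (is.null(node$children)) {
    s <- stateOf[[node$label]]
    cost <- rep(BIG, k); cost[s] <- 0
    node$cost <- cost
    node$minT <- rep(0, k)
    node$maxT <- rep(0, k)
    return(node)
  }
  node$children <- lapply(node$children, .mprDown, stateOf = stateOf, k = k,
                          fromIdx = fromIdx, toIdx = toIdx)
  cost <- rep(0, k); minT <- rep(0, k); maxT <- rep(0, k)
  for (ch in node$children) {
    for (s in seq_len(k)) {
      cand <- ch$cost + as.numeric(seq_len(k) != s)
      best <- min(cand)
      opts <- which(cand - best < 0.5)
      dirAdd <- as.numeric(s == fromIdx & opts == toIdx)
      cost[s] <- cost[s] + best
      minT[s] <- minT[s] + min(ch$minT[opts] + dirAdd)
      maxT[s] <- maxT[s] + max(ch$maxT[opts] + dirAdd)
    }
  }
  node$cost <- cost; node$minT <- minT; node$maxT <- maxT
  node
}

## MPR state sets via the standard above-cost (g) recursion.
.mprStateSets <- function(node, g, globalMin, k, sets) {
  total <- node$cost + g
  sets[[node$id]] <- which(total - globalMin < 0.5)
  if (is.null(node$children)) return(sets)
  for (ci in seq_along(node$children)) {
    ch <- node$children[[ci]]
    sibSum <- rep(0, k)
    for (cj in seq_along(node$children)) {
      if (cj == ci) next
      sib <- node$children[[cj]]
      sibSum <- sibSum + vapply(seq_len(k), function(s)
        min(sib$cost + as.numeric(seq_len(k) != s)), numeric(1))
    }
    gch <- vapply(seq_len(k), function(t_)
      min(g + sibSum + as.numeric(seq_len(k) != t_)), numeric(1))
    sets <- .mprStateSets(ch, gch, globalMin, k, sets)
  }
  sets
}

## Delayed-transformation (DELTRAN) assignment: preorder over the MPR
## final-state sets, keeping the parent's state whenever it belongs to the
## child's MPR set, so ambiguity resolves toward parallel changes near the
## tips. Per resolution this gives the count of independent directional
## origins that a traced reconstruction displays. If the preference ever
## produced a suboptimal assignment it falls back to a conditional-optimal
## (Sankoff backtrack) walk, which is always an MPR.
.deltranAssign <- function(aug, k) {
  gmin <- min(aug$cost)
  Fsets <- .mprStateSets(aug, rep(0, k), gmin, k, list())
  walkF <- function(node, parentState, acc) {
    S <- Fsets[[node$id]]
    s <- if (!is.null(parentState) && parentState %in% S) parentState
         else S[1L]
    acc$states[[node$id]] <- s
    if (!is.null(parentState) && parentState != s) {
      acc$counts[parentState, s] <- acc$counts[parentState, s] + 1L
      acc$changes <- acc$changes + 1L
    }
    for (ch in node$children) acc <- walkF(ch, s, acc)
    acc
  }
  acc <- walkF(aug, NULL,
               list(states = list(), counts = matrix(0L, k, k), changes = 0L))
  if (acc$changes == gmin)
    return(list(states = acc$states, counts = acc$counts))
  # fallback: conditional-optimal backtrack preferring the parent's state
  walkC <- function(node, parentState, acc) {
    cand <- if (is.null(parentState)) node$cost
            else node$cost + as.numeric(seq_len(k) != parentState)
    S <- which(cand - min(cand) < 0.5)
    s <- if (!is.null(parentState) && parentState %in% S) parentState
         else S[1L]
    acc$states[[node$id]] <- s
    if (!is.null(parentState) && parentState != s)
      acc$counts[parentState, s] <- acc$counts[parentState, s] + 1L
    for (ch in node$children) acc <- walkC(ch, s, acc)
    acc
  }
  acc <- walkC(aug, NULL, list(states = list(), counts = matrix(0L, k, k)))
  list(states = acc$states, counts = acc$counts)
}

#' Unordered-parsimony ancestral reconstruction with transition ranges
#'
#' Runs most-parsimonious reconstruction (unordered states, equal
#' transition costs) of a discrete trait on a rooted tree. Polytomies are
#' handled by enumerating every binary resolution (nodes of degree up to
#' `maxChildren + 1`); per-node MPR state sets are unioned over
#' resolutions. Directional transition counts are reported two ways in the
#' `transitions` table: `min`/`max` is the range over resolutions of the
#' per-resolution delayed-transformation (DELTRAN) count — the number of
#' independent directional origins, the quantity usually read off a traced
#' reconstruction — while `mprMin`/`mprMax` are the extremes over all
#' most-parsimonious assignments of all resolutions (these can be wider,
#' since equally parsimonious histories may trade parallel gains for one
#' deep gain plus reversals). Explicit witnesses (a resolution plus a full
#' node-state assignment, itself an MPR) are returned for the endpoints of
#' the focal direction's DELTRAN range.
#'
#' @param tree rooted `phylo` (polytomies allowed).
#' @param traits a [TraitTable-class] covering every leaf.
#' @param direction character(2) `(from, to)`: the focal direction for the
#'   witnesses; defaults to the first two alphabet states.
#' @param maxChildren enumeration cap per polytomy (default 7, i.e. at most
#'   10,395 resolutions per node).
#' @return a [ParsimonyASR-class].
#' @export
fitchMPR <- function(tree, traits, direction = NULL, maxChildren = 7L) {
  stopifnot(inherits(tree, "phylo"), is(traits, "TraitTable"))
  alphabet <- stateAlphabet(traits)
  k <- length(alphabet)
  if (k != 2L)
    stop("transition-range reconstruction is implemented for binary traits",
         call. = FALSE)
  states <- traitStates(traits)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("leaf without trait state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(direction)) direction <- alphabet[1:2]
  if (!all(direction %in% alphabet) || length(direction) != 2L)
    stop("direction must be two states from the alphabet", call. = FALSE)
  stateOf <- as.list(match(states[tree$tip.label], alphabet))
  names(stateOf) <- tree$tip.label

  nested <- .asNested(tree)
  counter <- new.env()
  counter$n <- 0L
  resolutions <- .enumerateResolutions(nested, counter,
                                       maxChildren = maxChildren)

  dirPairs <- list(c(1L, 2L), c(2L, 1L))
  focalIdx <- match(direction, alphabet)
  focalKey <- which(vapply(dirPairs, function(d)
    identical(d, focalIdx), logical(1)))
  nd <- length(dirPairs)
  dMin <- rep(Inf, nd); dMax <- rep(-Inf, nd)       # DELTRAN range
  mprMin <- rep(Inf, nd); mprMax <- rep(-Inf, nd)   # all-MPR extremes
  bestLen <- Inf
  setsUnion <- list()
  wit <- list(min = NULL, max = NULL)
  origIds <- c(as.character(seq_along(tree$tip.label)),
               as.character(length(tree$tip.label) + seq_len(tree$Nnode)))

  for (res in resolutions) {
    deltran <- NULL
    for (di in seq_along(dirPairs)) {
      d <- dirPairs[[di]]
      aug <- .mprDown(res, stateOf, k, d[1L], d[2L])
      gmin <- min(aug$cost)
      bestLen <- min(bestLen, gmin)
      rootStates <- which(aug$cost - gmin < 0.5)
      mprMin[di] <- min(mprMin[di], aug$minT[rootStates])
      mprMax[di] <- max(mprMax[di], aug$maxT[rootStates])
      if (di == 1L) {
        # direction-independent pieces, computed once per resolution
        deltran <- .deltranAssign(aug, k)
        sets <- .mprStateSets(aug, rep(0, k), gmin, k, list())
        for (id in intersect(names(sets), origIds)) {
          setsUnion[[id]] <- sort(unique(c(setsUnion[[id]], sets[[id]])))
        }
      }
      cnt <- deltran$counts[d[1L], d[2L]]
      newMin <- cnt < dMin[di]
      newMax <- cnt > dMax[di]
      dMin[di] <- min(dMin[di], cnt)
      dMax[di] <- max(dMax[di], cnt)
      if (di == focalKey && (newMin || newMax)) {
        w <- list(resolution = paste0(.nestedNewick(res), ";"),
                  states = vapply(deltran$states, function(s) alphabet[s],
                                  character(1)),
                  count = cnt)
        if (newMin) wit$min <- w
        if (newMax) wit$max <- w
      }
    }
  }

  transitions <- data.frame(
    from = vapply(dirPairs, function(d) alphabet[d[1L]], character(1)),
    to = vapply(dirPairs, function(d) alphabet[d[2L]], character(1)),
    min = dMin, max = dMax, mprMin = mprMin, mprMax = mprMax,
    stringsAsFactors = FALSE, row.names = NULL)

  stateSets <- lapply(setsUnion, function(idx) alphabet[idx])
  new("ParsimonyASR", tree = tree, stateSets = stateSets,
      transitions = transitions, minLength = as.integer(bestLen),
      nResolutions = length(resolutions), witnesses = wit,
      focalDirection = direction)
}

#' Transition range accessor
#'
#' @param asr a [ParsimonyASR-class].
#' @param from,to state names; default the object's focal direction.
#' @return numeric c(min, max).
#' @export
transitionRange <- function(asr, from = NULL, to = NULL) {
  if (is.null(from)) from <- asr@focalDirection[1L]
  if (is.null(to)) to <- asr@focalDirection[2L]
  row <- asr@transitions[asr@transitions$from == from &
                         asr@transitions$to == to, ]
  if (!nrow(row)) stop("no such direction", call. = FALSE)
  c(min = row$min, max = row$max)
}
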