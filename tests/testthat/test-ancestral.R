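test_that("collapseWeakNodes contracts exactly the weak edges", {
  tr <- ape::read.tree(text = "((A,B)90,((C,D)30,E)80);")
  # node labels: root (none), then as written
  out <- collapseWeakNodes(tr, threshold = 50)
  expect_equal(out$Nnode, tr$Nnode - 1L)
  degrees <- table(out$edge[, 1])
  expect_true(any(degrees == 3))  # one polytomy of three children
  expect_true(ape::is.monophyletic(out, c("A", "B")))
  # boundary thresholds
  expect_equal(collapseWeakNodes(tr, 0)$Nnode, tr$Nnode)
  star <- collapseWeakNodes(tr, 101)
  expect_equal(star$Nnode, 1L)
  expect_error(collapseWeakNodes(ape::rtree(4), 50), "no node support")
})

test_that("collapseWeakNodes preserves kept branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2)90:3,((C:4,D:5)30:6,E:7)80:8);")
  out <- collapseWeakNodes(tr, threshold = 50)
  lenOf <- function(phy, tip)
    phy$edge.length[match(match(tip, phy$tip.label), phy$edge[, 2])]
  for (tip in LETTERS[1:5])
    expect_equal(lenOf(out, tip), lenOf(tr, tip))
})

test_that("uniform traits reconstruct trivially", {
  tr <- ape::rtree(6)
  traits <- TraitTable(taxon = tr$tip.label,
                       state = rep("maternal", 6),
                       alphabet = c("maternal", "biparental"))
  asr <- fitchMPR(tr, traits)
  expect_true(all(asr@transitions$min == 0) && all(asr@transitions$max == 0))
  expect_true(all(vapply(asr@stateSets, identical, logical(1), "maternal")))
  expect_equal(asr@minLength, 0L)
})

test_that("MPR minimum equals brute force and DELTRAN counts are optimal", {
  # brute force: minimum changes and directional-count extremes among all
  # optimal assignments on a binary tree
  bruteRanges <- function(tree, states) {
    tr <- ape::reorder.phylo(tree, "postorder")
    nTip <- length(tr$tip.label)
    nNode <- tr$Nnode
    ts <- match(states[tr$tip.label], c("a", "b"))
    best <- Inf; lo <- Inf; hi <- -Inf
    for (mask in 0:(2^nNode - 1L)) {
      assign_ <- c(ts, as.integer(intToBits(mask))[seq_len(nNode)] + 1L)
      changes <- 0L; ab <- 0L
      for (e in seq_len(nrow(tr$edge))) {
        p <- assign_[tr$edge[e, 1]]; c_ <- assign_[tr$edge[e, 2]]
        if (p != c_) {
          changes <- changes + 1L
          if (p == 1L && c_ == 2L) ab <- ab + 1L
        }
      }
      if (changes < best) { best <- changes; lo <- ab; hi <- ab }
      else if (changes == best) { lo <- min(lo, ab); hi <- max(hi, ab) }
    }
    list(best = best, lo = lo, hi = hi)
  }
  withSeed(80, {
    for (i in 1:40) {
      n <- sample(5:10, 1)
      tr <- ape::rtree(n)
      traits <- randomBinaryTrait(tr, seed = 800 + i)
      asr <- fitchMPR(tr, traits, direction = c("a", "b"))
      want <- bruteRanges(tr, traitStates(traits))
      expect_equal(asr@minLength, as.integer(want$best), info = i)
      row <- asr@transitions[asr@transitions$from == "a" &
                             asr@transitions$to == "b", ]
      expect_equal(row$mprMin, want$lo, info = i)
      expect_equal(row$mprMax, want$hi, info = i)
      # DELTRAN counts must be achieved by some optimal assignment
      expect_gte(row$min, want$lo)
      expect_lte(row$max, want$hi)
      # witnesses achieve the endpoints they claim
      expect_equal(asr@witnesses$min$count,
                   row$min)
      expect_equal(asr@witnesses$max$count, row$max)
    }
  })
})

test_that("witnesses certify the range endpoints and honor the tip data", {
  tr <- ape::read.tree(text = "(((A,B),(C,D,E)),(F,(G,H)));")
  traits <- TraitTable(taxon = tr$tip.label,
                       state = c("a", "b", "b", "a", "b", "a", "b", "a"),
                       alphabet = c("a", "b"))
  asr <- fitchMPR(tr, traits, direction = c("a", "b"))
  row <- asr@transitions[asr@transitions$from == "a" &
                         asr@transitions$to == "b", ]
  expect_equal(asr@witnesses$min$count, row$min)
  expect_equal(asr@witnesses$max$count, row$max)
  for (w in asr@witnesses) {
    # the witness resolution is a resolution of the input tree
    res <- ape::read.tree(text = w$resolution)
    expect_setequal(res$tip.label, tr$tip.label)
    expect_true(all(treeSplits(tr, sort(tr$tip.label)) %in%
                    treeSplits(res, sort(tr$tip.label))))
    # tip states in the assignment equal the observed data
    obs <- traitStates(traits)
    for (i in seq_along(tr$tip.label))
      expect_equal(w$states[[as.character(i)]],
                   unname(obs[tr$tip.label[i]]))
  }
})

test_that("a binary tree equals its zero-polytomy collapse path", {
  withSeed(83, tr <- ape::rtree(9))
  tr$node.label <- rep("99", tr$Nnode)
  traits <- randomBinaryTrait(tr, seed = 84)
  a <- fitchMPR(tr, traits, direction = c("a", "b"))
  b <- fitchMPR(collapseWeakNodes(tr, 50), traits, direction = c("a", "b"))
  expect_equal(a@transitions, b@transitions)
  expect_equal(a@minLength, b@minLength)
})

test_that("polytomy enumeration respects its cap", {
  tr <- ape::read.tree(text = "(A,B,C,D,E,F,G,H,I);")
  traits <- TraitTable(taxon = tr$tip.label,
                       state = rep(c("a", "b"), length.out = 9),
                       alphabet = c("a", "b"))
  expect_error(fitchMPR(tr, traits), "enumeration cap")
})

test_that("species collapsing verifies monophyly", {
  tr <- ape::read.tree(text = "(((a1,a2),b1),((c1,a3),b2));")
  mapBad <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", c1 = "C")
  expect_error(collapseToSpecies(tr, mapBad),
               "not monophyletic in the tree: A, B")
  tr2 <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(c1,d1));")
  mapOk <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", d1 = "D")
  sp <- collapseToSpecies(tr2, mapOk)
  expect_setequal(sp$tip.label, c("A", "B", "C", "D"))
  expect_true(ape::is.monophyletic(sp, c("A", "B")))
})

test_that("Mk1 transition rows sum to one and likelihood handles alpha = 0", {
  for (a in c(0, 0.3, 2)) for (t_ in c(0, 0.5, 3)) {
    P <- mk1TransitionMatrix(a, t_)
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  }
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  traits <- TraitTable(taxon = LETTERS[1:4], state = rep("a", 4),
                       alphabet = c("a", "b"))
  expect_equal(mk1Loglik(tr, traits, alpha = 0), log(0.5), tolerance = 1e-12)
  expect_error(mk1Loglik(structure(list(
    edge = tr$edge, tip.label = tr$tip.label, Nnode = tr$Nnode,
    edge.length = rep(-1, 6)), class = "phylo"), traits, 0.5), "negative")
})

test_that("two-leaf marginal root probability matches the closed form", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  traits <- TraitTable(taxon = c("A", "B"), state = c("a", "a"),
                       alphabet = c("a", "b"))
  rec <- mk1Reconstruct(tr, traits, alpha = 0.5)
  p00 <- 0.5 * (1 + exp(-1)); p01 <- 0.5 * (1 - exp(-1))
  expect_equal(unname(rec@marginals[1, "a"]),
               p00^2 / (p00^2 + p01^2), tolerance = 1e-9)
  expect_equal(unname(rec@marginals[1, "a"]), 0.8240, tolerance = 1e-4)
})

test_that("pruning equals brute-force enumeration over internal states", {
  withSeed(85, {
    for (i in 1:30) {
      n <- sample(4:6, 1)
      tr <- ape::rtree(n)
      states <- stats::setNames(sample(1:2, n, replace = TRUE),
                                tr$tip.label)
      traits <- TraitTable(taxon = tr$tip.label,
                           state = c("a", "b")[states],
                           alphabet = c("a", "b"))
      alpha <- runif(1, 0.05, 2)
      expect_equal(mk1Loglik(tr, traits, alpha),
                   bruteMk1Loglik(tr, states, alpha), tolerance = 1e-10)
    }
  })
})

test_that("Mk1 reconstruction agrees with the reference implementation", {
  withSeed(86, tr <- ape::rtree(10))
  traits <- randomBinaryTrait(tr, seed = 87)
  rec <- mk1Reconstruct(tr, traits)
  st <- factor(traitStates(traits)[tr$tip.label], levels = c("a", "b"))
  ref <- ape::ace(st, tr, type = "discrete", model = "ER")
  expect_equal(rec@alphaHat, unname(ref$rates), tolerance = 1e-3)
  expect_equal(unname(rec@marginals[1, ]), unname(ref$lik.anc[1, ]),
               tolerance = 1e-3)
})

test_that("state relabeling swaps Mk1 marginals exactly", {
  withSeed(88, tr <- ape::rtree(8))
  traits <- randomBinaryTrait(tr, seed = 89)
  swapped <- TraitTable(taxon = traitData(traits)$taxon,
                        state = ifelse(traitData(traits)$state == "a",
                                       "b", "a"),
                        alphabet = c("a", "b"))
  r1 <- mk1Reconstruct(tr, traits, alpha = 0.7)
  r2 <- mk1Reconstruct(tr, swapped, alpha = 0.7)
  expect_equal(unname(r1@marginals[, "a"]), unname(r2@marginals[, "b"]),
               tolerance = 1e-12)
})

test_that("saturated traits are reported as equivocal", {
  withSeed(90, tr <- ape::rphylo(12, 1, 0))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  sim <- simulateTrait(tr, alpha = 50, seed = 91)
  rec <- mk1Reconstruct(tr, sim$trait, alpha = 50)
  expect_gt(mean(rec@equivocal), 0.9)
  expect_true(all(abs(rowSums(rec@marginals) - 1) < 1e-9))
})

test_that("a deep-split trait at a low fitted rate reconstructs decisively", {
  withSeed(92, tr <- ape::rphylo(14, 1, 0))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  # trait defined by a deep clade: one change on a long internal edge
  rootKids <- tr$edge[tr$edge[, 1] == 15L, 2]
  clade <- ape::extract.clade(tr, max(rootKids))$tip.label
  traits <- TraitTable(taxon = tr$tip.label,
                       state = ifelse(tr$tip.label %in% clade, "b", "a"),
                       alphabet = c("a", "b"))
  rec <- mk1Reconstruct(tr, traits)
  expect_gte(mean(apply(rec@marginals, 1, max) > 0.95), 0.9)
  expect_lte(mean(rec@equivocal), 0.1)
  # recovered states match the defining clade
  est <- colnames(rec@marginals)[apply(rec@marginals, 1, which.max)]
  cladeNodes <- ape::getMRCA(tr, clade)
  expect_equal(est[as.integer(rownames(rec@marginals)) == cladeNodes], "b")
})
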