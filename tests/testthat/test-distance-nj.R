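test_that("Nei-Li distance follows the fragment-sharing formula", {
  # n_x = 3, n_y = 3, n_xy = 2 -> F = 2/3, D = 1/3
  expect_equal(neiLiDistance(c(1, 1, 0, 1), c(1, 0, 1, 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(neiLiDistance(c(1, 1, 0, 1), c(1, 1, 0, 1)), 0)
  expect_equal(neiLiDistance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(neiLiDistance(c(1, 1, 0, 1), c(1, 0, 1, 1), "log"),
               -log(2 / 3), tolerance = 1e-12)
  # symmetry
  withSeed(4, {
    for (i in 1:25) {
      x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.5)
      if (sum(x) == 0 || sum(y) == 0) next
      expect_equal(neiLiDistance(x, y), neiLiDistance(y, x))
    }
  })
  expect_error(neiLiDistance(c(0, 0, 0), c(1, 0, 1)), "zero bands")
  # shared absence contributes nothing: appending 0/0 loci changes nothing
  expect_equal(neiLiDistance(c(1, 1, 0, 1, 0, 0), c(1, 0, 1, 1, 0, 0)),
               neiLiDistance(c(1, 1, 0, 1), c(1, 0, 1, 1)))
  # missing cells deleted pairwise
  expect_equal(neiLiDistance(c(1, NA, 0, 1), c(1, 0, NA, 1)),
               neiLiDistance(c(1, 1), c(1, 1)))
})

test_that("the distance matrix agrees cell-by-cell with the pair oracle", {
  x <- randomAFLP(7, 60, seed = 5, pMissing = 0.05)
  D <- as.matrix(neiLiDistanceMatrix(x))
  m <- aflpCharacters(x)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(D[i, j], neiLiDistance(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # duplicate rows give zero distance
  m2 <- rbind(m, dup = m[1, ])
  D2 <- as.matrix(neiLiDistanceMatrix(AFLPMatrix(m2)))
  expect_equal(D2["t01", "dup"], 0)
  # zero-band taxon errors with the pair named
  m3 <- rbind(m, empty = rep(0L, ncol(m)))
  expect_error(neiLiDistanceMatrix(AFLPMatrix(m3)), "empty")
})

test_that("taxon permutation permutes the distance matrix consistently", {
  x <- randomAFLP(8, 50, seed = 6)
  D <- as.matrix(neiLiDistanceMatrix(x))
  withSeed(7, perm <- sample(taxonLabels(x)))
  D2 <- as.matrix(neiLiDistanceMatrix(x[perm, ]))
  expect_equal(D2, D[perm, perm], tolerance = 1e-12)
})

test_that("three-taxon neighbor joining solves the three-point formulas", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(DistanceMatrix(d))
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["A"]], 0.05, tolerance = 1e-12)
  expect_equal(len[["B"]], 0.15, tolerance = 1e-12)
  expect_equal(len[["C"]], 0.25, tolerance = 1e-12)
})

test_that("NJ recovers generating trees from additive matrices", {
  withSeed(10, {
    for (i in 1:25) {
      n <- sample(4:12, 1)
      tr <- ape::rtree(n)
      tr <- ape::unroot(tr)
      D <- additiveMatrix(tr)
      out <- neighborJoining(DistanceMatrix(D))
      expect_true(compareTopologies(out, tr)$identical, info = i)
      # branch lengths reproduced
      expect_equal(additiveMatrix(out)[rownames(D), colnames(D)], D,
                   tolerance = 1e-9)
    }
  })
})

test_that("NJ matches the reference implementation on noisy distances", {
  x <- simulatedMatrix(nSpecies = 10, nLoci = 300, seed = 21)$matrix
  D <- as.matrix(neiLiDistanceMatrix(x))
  mine <- neighborJoining(DistanceMatrix(D))
  ref <- ape::nj(as.dist(D))
  expect_true(compareTopologies(mine, ref)$identical)
})

test_that("a fully tied four-taxon case still returns a valid binary tree", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- neighborJoining(DistanceMatrix(d))
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(tr$Nnode, 2L)  # n - 2 internal vertices, unrooted binary
  expect_true(all(tr$edge.length >= 0))
  # deterministic tie-break: same input, same tree
  tr2 <- neighborJoining(DistanceMatrix(d))
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("NJ is equivariant under taxon relabeling", {
  x <- randomAFLP(8, 80, seed = 12)
  D <- neiLiDistanceMatrix(x)
  tr <- neighborJoining(D)
  withSeed(13, perm <- sample(taxonLabels(x)))
  tr2 <- neighborJoining(DistanceMatrix(as.matrix(D)[perm, perm]))
  expect_true(compareTopologies(tr, tr2)$identical)
})

test_that("the distance writer emits square PHYLIP readable values", {
  x <- randomAFLP(5, 40, seed = 8)
  d <- neiLiDistanceMatrix(x)
  path <- withr::local_tempfile(fileext = ".phy")
  writeDistanceMatrix(d, path)
  lines <- readLines(path)
  expect_equal(lines[1], "5")
  row2 <- strsplit(lines[2], " ")[[1]]
  expect_equal(row2[1], taxonLabels(x)[1])
  expect_equal(as.numeric(row2[-1]), unname(as.matrix(d)[1, ]),
               tolerance = 1e-6)
})

test_that("rooting places the root on the outgroup edge, split evenly", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):3);")
  tru <- ape::unroot(tr)
  r1 <- rootTree(tru, "C")
  expect_true(ape::is.rooted(r1))
  expect_true(ape::is.monophyletic(r1, c("A", "B")))
  r2 <- rootTree(tru, c("D", "E"))
  rootKids <- r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1L, 2]
  kidLens <- r2$edge.length[match(rootKids, r2$edge[, 2])]
  expect_equal(kidLens[1], kidLens[2])  # stem split evenly
  expect_error(rootTree(tru, c("A", "D")), "not monophyletic")
  expect_error(rootTree(tru, c("A", "Z")), "missing")
})
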