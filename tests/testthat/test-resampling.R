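test_that("a single bootstrap replicate gives all-or-nothing support", {
  x <- simulatedMatrix(nSpecies = 8, nLoci = 150, seed = 33)$matrix
  out <- bootstrapSupport(x, "nj", replicates = 1, seed = 1)
  sup <- splitSupport(out$profile)$support
  expect_true(all(sup %in% c(0, 100)))
})

test_that("compatible characters give full support on every split", {
  withSeed(44, tr <- ape::unroot(ape::rtree(8)))
  x <- compatibleMatrix(tr, perEdge = 6)
  out <- bootstrapSupport(x, "nj", replicates = 200, seed = 3)
  expect_true(compareTopologies(out$tree, tr)$identical)
  expect_gte(meanSupport(out$profile), 95)
  labs <- suppressWarnings(as.numeric(out$tree$node.label))
  expect_true(all(labs[!is.na(labs)] >= 95))
})

test_that("bootstrap support is seeded and reproducible", {
  x <- simulatedMatrix(nSpecies = 8, nLoci = 150, seed = 33)$matrix
  a <- bootstrapSupport(x, "nj", replicates = 50, seed = 7)
  b <- bootstrapSupport(x, "nj", replicates = 50, seed = 7)
  expect_identical(splitSupport(a$profile), splitSupport(b$profile))
  c_ <- bootstrapSupport(x, "nj", replicates = 50, seed = 8)
  expect_false(identical(splitSupport(a$profile)$support,
                         splitSupport(c_$profile)$support))
})

test_that("mp bootstrap runs and reports supports in range", {
  x <- simulatedMatrix(nSpecies = 7, nLoci = 120, seed = 35)$matrix
  out <- bootstrapSupport(x, "mp", replicates = 20, seed = 2)
  sup <- splitSupport(out$profile)$support
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(is.finite(meanSupport(out$profile)))
})

test_that("g1 skewness matches direct moment computation", {
  expect_equal(g1Skewness(c(1, 2, 3, 4, 5)), 0)
  expect_equal(g1Skewness(c(1, 1, 1, 5)), 6 / 3^1.5, tolerance = 1e-12)
  withSeed(50, {
    for (i in 1:1000) {
      v <- rnorm(sample(3:40, 1))
      if (stats::sd(v) == 0) next
      m <- mean(v)
      m2 <- mean((v - m)^2); m3 <- mean((v - m)^3)
      expect_equal(g1Skewness(v), m3 / m2^1.5, tolerance = 1e-12)
      expect_equal(g1Skewness(-v), -g1Skewness(v), tolerance = 1e-12)
    }
  })
  expect_error(g1Skewness(c(1, 2)), "size")
  expect_error(g1Skewness(c(2, 2, 2)), "zero variance")
})

test_that("random topologies are uniform over labeled topologies", {
  # n = 5: 15 unrooted labeled topologies, each ~ 1/15
  withSeed(51, {
    keys <- replicate(3000, {
      tr <- randomTopology(letters[1:5])
      paste(sort(treeSplits(tr, letters[1:5])), collapse = "|")
    })
  })
  tab <- table(keys)
  expect_equal(length(tab), 15L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("random tree lengths surface degenerate matrices through g1", {
  m0 <- AFLPMatrix(matrix(1L, 6, 10, dimnames = list(LETTERS[1:6], NULL)))
  tls <- randomTreeLengths(m0, nTrees = 50, seed = 1)
  expect_true(all(tls$lengths == 0L))
  expect_error(g1Skewness(tls), "zero variance")
  # determinism
  x <- simulatedMatrix(nSpecies = 8, nLoci = 150, seed = 33)$matrix
  expect_identical(randomTreeLengths(x, 100, seed = 4)$lengths,
                   randomTreeLengths(x, 100, seed = 4)$lengths)
})

test_that("SH self-comparison yields zero difference and p = 1", {
  x <- simulatedMatrix(nSpecies = 8, nLoci = 150, seed = 33)$matrix
  withSeed(52, tr <- randomTopology(taxonLabels(x)))
  res <- shTest(x, list(a = tr, b = tr), resamples = 200, seed = 1)
  expect_equal(res@table$delta, c(0, 0))
  expect_equal(res@table$p, c(1, 1))
  expect_error(shTest(x, list(tr)), "at least 2")
  tr2 <- tr; tr2$tip.label[1] <- "zzz"
  expect_error(shTest(x, list(tr, tr2), seed = 1), "mismatched")
})

test_that("SH distinguishes strongly contradicted topologies", {
  sim <- simulatedMatrix(nSpecies = 10, nLoci = 500, seed = 61, noise = 0)
  true <- ape::unroot(sim$tree)
  # break one well-supported clade by swapping two distant tips
  d <- additiveMatrix(true)
  pair <- which(d == max(d), arr.ind = TRUE)[1, ]
  broken <- true
  broken$tip.label[c(pair[1], pair[2])] <- broken$tip.label[c(pair[2],
                                                              pair[1])]
  res <- shTest(sim$matrix, list(true = true, broken = broken),
                resamples = 500, seed = 2)
  tb <- res@table
  expect_equal(tb$p[tb$topology == "true"], 1)
  expect_lt(tb$p[tb$topology == "broken"], 0.05)
})

test_that("SH on indistinguishable resolutions is insignificant", {
  # no-signal data: iid coin flips; two arbitrary topologies
  x <- randomAFLP(8, 200, seed = 62)
  withSeed(63, {
    t1 <- randomTopology(taxonLabels(x))
  })
  t2 <- phangorn::nni(t1)[[1]]
  res <- shTest(x, list(t1 = t1, t2 = t2), resamples = 500, seed = 3)
  expect_gt(min(res@table$p), 0.1)
})

test_that("the SH likelihood backend agrees on the ranking", {
  sim <- simulatedMatrix(nSpecies = 7, nLoci = 200, seed = 64, noise = 0)
  true <- sim$tree
  withSeed(65, wrong <- randomTopology(true$tip.label))
  # the random topology carries no branch lengths; unit lengths are
  # substituted with a warning by design
  res <- suppressWarnings(
    shTest(sim$matrix, list(true = ape::unroot(true), wrong = wrong),
           score = "mk1", resamples = 200, seed = 4))
  tb <- res@table
  expect_lt(tb$score[tb$topology == "true"],
            tb$score[tb$topology == "wrong"])
  expect_equal(tb$p[tb$topology == "true"], 1)
})

test_that("homoplasy excess warns on unstable replicate counts", {
  x <- simulatedMatrix(nSpecies = 6, nLoci = 100, seed = 71)$matrix
  expect_warning(
    het <- homoplasyExcessTest(x, "nj", replicates = 50, seed = 1),
    "unstable")
  expect_true(length(het@warnings) == 1L)
  expect_error(homoplasyExcessTest(x[1:4, ], replicates = 100, seed = 1),
               "at least 5")
})

test_that("support changes on clean data are centered near zero", {
  sim <- simulatedMatrix(nSpecies = 9, nLoci = 400, seed = 72)
  het <- suppressWarnings(
    homoplasyExcessTest(sim$matrix, "nj", replicates = 150, seed = 2))
  expect_lt(abs(median(het@delta$delta)), 2)
  expect_equal(nrow(het@flags), 0L)
})
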