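test_that("CSV parsing maps rows and symbols to the binary alphabet", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,L1,L2,L3,L4", "A,1,1,0,1", "B,1,0,1,1"), path)
  x <- readAFLPMatrix(path, "csv")
  expect_equal(nTaxa(x), 2L)
  expect_equal(nLoci(x), 4L)
  expect_equal(unname(aflpCharacters(x)["A", ]), c(1L, 1L, 0L, 1L))
  expect_equal(taxonLabels(x), c("A", "B"))
})

test_that("matrices round-trip through all three formats", {
  for (seed in 1:20) {
    x <- randomAFLP(nTaxa = 5 + seed %% 7, nLoci = 10 + seed,
                    seed = seed, pMissing = ifelse(seed %% 3 == 0, 0.1, 0))
    for (fmt in c("csv", "phylip", "nexus")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      writeAFLPMatrix(x, path, fmt)
      y <- readAFLPMatrix(path, fmt)
      expect_equal(aflpCharacters(y), aflpCharacters(x),
                   info = paste(fmt, seed))
    }
  }
})

test_that("Newick trees round-trip topology, lengths and support", {
  withSeed(42, {
    for (i in 1:20) {
      tr <- ape::rtree(4 + i %% 9)
      tr$node.label <- sprintf("%.1f", runif(tr$Nnode, 0, 100))
      path <- withr::local_tempfile(fileext = ".nwk")
      ape::write.tree(tr, path)
      tr2 <- ape::read.tree(path)
      expect_true(compareTopologies(tr, tr2)$identical)
      expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-6)
      expect_equal(tr2$node.label, tr$node.label)
    }
  })
})

test_that("a PHYLIP file at survey scale re-reads with its dimensions", {
  cfg <- simulationConfig(nSpecies = 16, nLoci = 2478, noise = 0,
                          sizeHomoplasyProb = 0, seed = 7)
  sim <- simulateTree(cfg)
  x <- simulateAFLP(sim$tree, cfg)$matrix
  expect_equal(nTaxa(x), 37L)
  path <- withr::local_tempfile(fileext = ".phy")
  writeAFLPMatrix(x, path, "phylip")
  expect_equal(strsplit(readLines(path, n = 1), " ")[[1]], c("37", "2478"))
  y <- readAFLPMatrix(path, "phylip")
  expect_equal(nTaxa(y), 37L)
  expect_equal(nLoci(y), 2478L)
  expect_equal(aflpCharacters(y), aflpCharacters(x))
})

test_that("parse and validation errors name the problem", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,L1,L2", "A,1,0", "A,0,1"), p)
  expect_error(readAFLPMatrix(p, "csv"), "duplicate taxon 'A'")
  writeLines(c("taxon,L1,L2", "A,1,2", "B,0,1"), p)
  expect_error(readAFLPMatrix(p, "csv"), "non-binary")
  p2 <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 3", "A 010", "B 01"), p2)
  expect_error(readAFLPMatrix(p2, "phylip"), "line 3")
  p3 <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("not nexus"), p3)
  expect_error(readAFLPMatrix(p3, "nexus"), "line 1")
  expect_error(AFLPMatrix(matrix(integer(0), 0, 0)), "at least 1 taxon")
})

test_that("missing cells are emitted as '?' in NEXUS output", {
  x <- AFLPMatrix(rbind(A = c(1L, NA, 0L), B = c(0L, 1L, 1L)))
  path <- withr::local_tempfile(fileext = ".nex")
  writeAFLPMatrix(x, path, "nexus")
  txt <- readLines(path)
  expect_true(any(grepl("A 1\\?0", txt)))
  expect_true(any(grepl("MISSING=\\?", txt)))
})

test_that("polymorphic and informative locus counts follow their definitions", {
  x <- AFLPMatrix(rbind(A = c(1L, 1L, 1L), B = c(1L, 1L, 1L)))
  expect_equal(nPolymorphic(x), 0L)
  y <- AFLPMatrix(rbind(A = c(0L, 1L, 0L), B = c(1L, 1L, 0L)))
  expect_equal(nPolymorphic(y), 1L)
  # informative needs >= 2 of each state
  z <- AFLPMatrix(matrix(c(0L, 0L, 1L, 1L,   # informative
                           0L, 1L, 1L, 1L,   # polymorphic only
                           1L, 1L, 1L, 1L),  # constant
                         nrow = 4,
                         dimnames = list(LETTERS[1:4], NULL)))
  expect_equal(nPolymorphic(z), 2L)
  expect_equal(nInformative(z), 1L)
})

test_that("polymorphic counts are invariant under row/column permutation", {
  x <- randomAFLP(8, 30, seed = 3, pMissing = 0.05)
  withSeed(9, {
    perm <- x[sample(nTaxa(x)), sample(nLoci(x))]
  })
  expect_equal(nPolymorphic(perm), nPolymorphic(x))
  expect_equal(nInformative(perm), nInformative(x))
})

test_that("realized polymorphic fraction matches the analytic expectation", {
  cfg <- simulationConfig(nSpecies = 10, individualsPerSpecies = 1,
                          nLoci = 300, gainRate = 1.2, lossRate = 2.4,
                          noise = 0, sizeHomoplasyProb = 0, seed = 1)
  sim <- simulateTree(cfg)
  expected <- expectedPolymorphicFraction(sim$tree, 1.2, 2.4)
  expect_gt(expected, 0.5)  # rates high enough that most sites vary
  fr <- vapply(1:20, function(s) {
    cfg$seed <- s
    x <- simulateAFLP(sim$tree, cfg)$matrix
    nPolymorphic(x) / nLoci(x)
  }, numeric(1))
  expect_lt(abs(mean(fr) - expected), 0.05)
})

test_that("the packaged care table matches the published sampling", {
  tab <- xenotilapiaCareTable()
  d <- traitData(tab)
  expect_equal(nrow(d), 37L)
  counts <- table(d$state)
  expect_equal(unname(counts[["Biparental Mouthbrooder"]]), 18L)
  expect_equal(unname(counts[["Maternal Mouthbrooder"]]), 19L)
  expect_true(all(d$state %in% c("Biparental Mouthbrooder",
                                 "Maternal Mouthbrooder")))
  expect_equal(length(unique(d$species)), 16L)
  # round trip through the TSV writer
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraitTable(tab, path)
  tab2 <- readTraitTable(path)
  expect_equal(traitData(tab2)$state, d$state)
})

test_that("split keys canonicalize a split and its complement identically", {
  withSeed(11, {
    for (i in 1:20) {
      tr <- ape::rtree(6 + i %% 8)
      taxa <- sort(tr$tip.label)
      pp <- ape::prop.part(tr)
      labs <- attr(pp, "labels")
      for (cl in pp) {
        members <- labs[cl]
        if (length(members) <= 1 || length(members) >= length(taxa) - 1) next
        k1 <- splitKey(members, taxa)
        k2 <- splitKey(setdiff(taxa, members), taxa)
        expect_identical(k1, k2)
        members2 <- taxa[strsplit(k1, "")[[1]] == "1"]
        expect_identical(splitKey(members2, taxa), k1)  # idempotent
      }
    }
  })
})

test_that("trivial splits are excluded from tree split sets", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  keys <- treeSplits(tr, sort(tr$tip.label))
  # splits: {A,B} and {D,E} (the root split {A,B} vs rest duplicates {A,B})
  expect_equal(length(keys), 2L)
})
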