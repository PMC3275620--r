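## Full analysis orchestration: matrix -> distances + NJ bootstrap -> MP
## search + bootstrap -> g1 randomization -> SH tests (NJ vs MP, plus
## care-state monophyly constraints when traits are available) -> homoplasy
## excess test -> collapse weak nodes -> ancestral reconstruction. One root
## seed fans out to per-stage seeds via deriveSeed() so stages can be rerun
## in isolation; identical configs give identical reports.

#' Pipeline configuration
#'
#' @param matrix path to an input matrix (csv/phylip/nexus), or `NULL` to
#'   simulate one.
#' @param matrixFormat format passed to [readAFLPMatrix()].
#' @param simulation a `SimulationConfig` (see [simulationConfig()]); used
#'   when `matrix` is `NULL`.
#' @param traits path to a trait TSV, or `NULL` (simulated traits are used
#'   for simulated input).
#' @param outgroup character vector of outgroup taxa for rooting; `NULL`
#'   uses midpoint rooting for the reconstruction stage.
#' @param locusGroups number of primer-pair groups, for the mean
#'   loci-per-group report line; `NULL` to skip.
#' @param njReplicates,mpReplicates bootstrap replicate counts.
#' @param mpStarts random-addition starts for parsimony searches.
#' @param g1Trees random topologies for the tree-length distribution.
#' @param shResamples RELL resamples.
#' @param het logical: run the homoplasy excess test.
#' @param hetReplicates bootstrap replicates per homoplasy-excess run.
#' @param minRise homoplasy-excess minimum support rise (points).
#' @param collapseThreshold support threshold for polytomy collapsing.
#' @param seed root seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(matrix = NULL, matrixFormat = "auto",
                           simulation = simulationConfig(),
                           traits = NULL, outgroup = NULL,
                           locusGroups = NULL,
                           njReplicates = 1000L, mpReplicates = 100L,
                           mpStarts = 2L, g1Trees = 10000L,
                           shResamples = 1000L, het = TRUE,
                           hetReplicates = 200L, minRise = 10,
                           collapseThreshold = 50, seed = 1L) {
  structure(list(matrix = matrix, matrixFormat = matrixFormat,
                 simulation = simulation, traits = traits,
                 outgroup = outgroup, locusGroups = locusGroups,
                 njReplicates = as.integer(njReplicates),
                 mpReplicates = as.integer(mpReplicates),
                 mpStarts = as.integer(mpStarts),
                 g1Trees = as.integer(g1Trees),
                 shResamples = as.integer(shResamples),
                 het = isTRUE(het),
                 hetReplicates = as.integer(hetReplicates),
                 minRise = minRise,
                 collapseThreshold = collapseThreshold,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments;
#'   `simulation` may be a nested map of [simulationConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulationConfig, y$simulation)
  do.call(pipelineConfig, y)
}

.monophylyConstraint <- function(taxa, group) {
  rest <- setdiff(taxa, group)
  ape::read.tree(text = sprintf("((%s),(%s));",
                                paste(group, collapse = ","),
                                paste(rest, collapse = ",")))
}

#' Run the full AFLP analysis pipeline
#'
#' Executes all stages in order, optionally persisting every intermediate
#' (matrix, distances, trees, support and test tables, report JSON) under
#' `outDir`. Any stage error aborts with the stage named; intermediates
#' written up to that point are retained.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]), or a path to
#'   a YAML file for [readPipelineConfig()].
#' @param outDir output directory for intermediates, or `NULL` to skip
#'   writing.
#' @return a list of class `PipelineReport`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(outDir)) writer(file.path(outDir, name))
    invisible(NULL)
  }
  stage <- "input"
  settings <- unclass(config)
  if (!is.null(settings$simulation))
    settings$simulation <- unclass(settings$simulation)
  report <- list(settings = settings)
  tryCatch({
    ## ---- input ----
    truth <- NULL; traits <- NULL; speciesMap <- NULL
    if (!is.null(config$matrix)) {
      x <- readAFLPMatrix(config$matrix, config$matrixFormat)
    } else {
      sim <- config$simulation
      sim$seed <- deriveSeed(config$seed, "simulate")
      st <- simulateTree(sim)
      sa <- simulateAFLP(st$tree, sim)
      x <- sa$matrix
      truth <- c(sa$groundTruth, st["speciesMap"])
      speciesMap <- st$speciesMap
      tsim <- simulateTrait(st$tree, sim$traitRate,
                            seed = deriveSeed(config$seed, "trait"))
      traits <- tsim$trait
      emit("true_tree.nwk", function(p) ape::write.tree(st$tree, p))
      emit("true_trait.tsv", function(p) writeTraitTable(traits, p))
    }
    if (!is.null(config$traits)) traits <- readTraitTable(config$traits)
    emit("matrix.nex", function(p) writeAFLPMatrix(x, p, "nexus"))
    report$counts <- list(
      taxa = nTaxa(x), loci = nLoci(x),
      polymorphic = nPolymorphic(x), informative = nInformative(x))
    if (!is.null(config$locusGroups))
      report$counts$meanPerGroup <-
        meanPerGroup(nLoci(x), config$locusGroups)

    ## ---- distance + NJ bootstrap ----
    stage <- "nj_bootstrap"
    d <- neiLiDistanceMatrix(x)
    emit("distances.phy", function(p) writeDistanceMatrix(d, p))
    njb <- bootstrapSupport(x, "nj", config$njReplicates,
                            seed = deriveSeed(config$seed, "njboot"))
    emit("nj_boot.nwk", function(p) ape::write.tree(njb$tree, p))
    emit("nj_support.tsv", function(p)
      utils::write.table(splitSupport(njb$profile), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
    report$njMeanSupport <- meanSupport(njb$profile)

    ## ---- MP search + bootstrap ----
    stage <- "mp_search"
    mp <- heuristicSearch(x, nStarts = config$mpStarts,
                          seed = deriveSeed(config$seed, "mpsearch"))
    report$mpScore <- mp$score
    report$mpTreeCount <- mp$nBest
    emit("mp_best.nwk", function(p) ape::write.tree(mp$trees[[1L]], p))
    mpb <- bootstrapSupport(x, "mp", config$mpReplicates,
                            seed = deriveSeed(config$seed, "mpboot"),
                            mpStarts = 1L)
    report$mpMeanSupport <- meanSupport(mpb$profile)
    cmp <- compareTopologies(njb$tree, mp$trees[[1L]])
    report$njMpIdentical <- cmp$identical
    report$njMpSharedSplits <- cmp$shared

    ## ---- g1 randomization ----
    stage <- "g1"
    tls <- randomTreeLengths(x, config$g1Trees,
                             seed = deriveSeed(config$seed, "g1"))
    report$g1 <- g1Skewness(tls)

    ## ---- SH tests ----
    stage <- "sh"
    topos <- list(nj = ape::unroot(njb$tree), mp = mp$trees[[1L]])
    if (!is.null(traits)) {
      st_ <- traitStates(traits)
      st_ <- st_[names(st_) %in% taxonLabels(x)]
      for (s in stateAlphabet(traits)) {
        grp <- names(st_)[st_ == s]
        if (length(grp) < 2L || length(grp) > nTaxa(x) - 2L) next
        cons <- .monophylyConstraint(taxonLabels(x), grp)
        fit <- heuristicSearch(x, constraint = cons,
                               nStarts = config$mpStarts,
                               seed = deriveSeed(config$seed,
                                                 paste0("cons_", s)))
        topos[[paste0("monophyletic_", gsub("\\s+", "_", s))]] <-
          fit$trees[[1L]]
      }
    }
    sh <- shTest(x, topos, resamples = config$shResamples,
                 seed = deriveSeed(config$seed, "sh"))
    report$sh <- sh@table
    emit("sh.tsv", function(p)
      utils::write.table(sh@table, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))

    ## ---- homoplasy excess ----
    if (config$het) {
      stage <- "het"
      het <- homoplasyExcessTest(x, "nj", config$hetReplicates,
                                 seed = deriveSeed(config$seed, "het"),
                                 minRise = config$minRise)
      report$hetFlags <- het@flags
      report$hetPairsExamined <- nrow(het@delta)
      emit("het_delta.tsv", function(p)
        utils::write.table(het@delta, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }

    ## ---- ancestral reconstruction ----
    if (!is.null(traits)) {
      stage <- "asr"
      rooted <- if (!is.null(config$outgroup)) {
        rootTree(ape::unroot(njb$tree), config$outgroup)
      } else {
        phangorn::midpoint(njb$tree)
      }
      collapsed <- collapseWeakNodes(rooted, config$collapseThreshold)
      asr <- fitchMPR(collapsed, traits)
      report$asrTransitions <- asr@transitions
      report$asrResolutions <- asr@nResolutions
      mk <- tryCatch(mk1Reconstruct(collapsed, traits),
                     error = function(e) NULL)
      if (!is.null(mk)) {
        report$mk1Alpha <- mk@alphaHat
        report$mk1Equivocal <- sum(mk@equivocal)
        report$mk1Nodes <- length(mk@equivocal)
      }
      emit("collapsed.nwk", function(p) ape::write.tree(collapsed, p))
    }

    class(report) <- "PipelineReport"
    emit("report.json", function(p) writePipelineReport(report, p))
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Write / read a pipeline report as JSON
#'
#' @param report a `PipelineReport`.
#' @param path JSON file path.
#' @export
writePipelineReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writePipelineReport
#' @export
readPipelineReport <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(r) <- "PipelineReport"
  r
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("AFLP pipeline report\n")
  cat(sprintf("  taxa %d, loci %d (%d polymorphic, %d informative)\n",
              x$counts$taxa, x$counts$loci, x$counts$polymorphic,
              x$counts$informative))
  if (!is.null(x$counts$meanPerGroup))
    cat(sprintf("  mean loci per primer-pair group: %.1f\n",
                x$counts$meanPerGroup))
  cat(sprintf("  g1 tree-length skewness: %.5f\n", x$g1))
  cat(sprintf("  mean bootstrap: NJ %.1f%%, MP %.1f%% (topologies %s)\n",
              x$njMeanSupport, x$mpMeanSupport,
              if (isTRUE(x$njMpIdentical)) "identical" else "different"))
  if (!is.null(x$sh)) {
    cat("  SH test:\n")
    print(x$sh, row.names = FALSE)
  }
  if (!is.null(x$hetPairsExamined))
    cat(sprintf("  homoplasy excess: %d flags over %d pairs\n",
                if (is.null(dim(x$hetFlags))) 0L else nrow(x$hetFlags),
                x$hetPairsExamined))
  if (!is.null(x$asrTransitions)) {
    cat("  ancestral-state transition ranges:\n")
    print(x$asrTransitions, row.names = FALSE)
  }
  invisible(x)
}
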