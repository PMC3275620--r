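## Core S4 containers. Trees are ape "phylo" objects throughout; the classes
## here hold the binary character matrix, per-taxon traits, distances and the
## bookkeeping objects produced by the resampling machinery.

#' AFLPMatrix: binary presence/absence character matrix
#'
#' Taxa in rows, loci in columns. Cells are 0 (band absent), 1 (band
#' present) or `NA` (missing / failed lane). Row names are the taxon labels
#' and must be unique and non-empty; column names are optional locus labels
#' (auto-filled as `L1..Ln`).
#'
#' @slot characters integer matrix of 0/1/NA values with dimnames.
#' @export
setClass("AFLPMatrix", slots = c(characters = "matrix"))

setValidity("AFLPMatrix", function(object) {
  m <- object@characters
  if (!is.matrix(m) || !is.integer(m))
    return("'characters' must be an integer matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    return("need at least 1 taxon and 1 locus")
  tl <- rownames(m)
  if (is.null(tl) || anyNA(tl) || any(!nzchar(tl)))
    return("taxon labels (rownames) must be present and non-empty")
  if (anyDuplicated(tl))
    return(paste0("duplicate taxon label: ", tl[duplicated(tl)][1L]))
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals == 0L | vals == 1L))
    return("all non-missing cells must be 0 or 1")
  if (is.null(colnames(m)))
    return("locus labels (colnames) must be present")
  TRUE
})

#' TraitTable: discrete per-taxon character states
#'
#' Maps taxa to a state drawn from a fixed alphabet, optionally carrying
#' species and collection-site metadata.
#'
#' @slot data data.frame with columns `taxon`, `state` and optionally
#'   `species`, `site`.
#' @slot alphabet character vector of allowed states, in display order.
#' @export
setClass("TraitTable", slots = c(data = "data.frame", alphabet = "character"))

setValidity("TraitTable", function(object) {
  d <- object@data
  if (!all(c("taxon", "state") %in% names(d)))
    return("data must have 'taxon' and 'state' columns")
  if (anyDuplicated(d$taxon))
    return("duplicate taxon in trait table")
  if (any(!nzchar(d$taxon)) || anyNA(d$taxon))
    return("taxon labels must be non-empty")
  if (length(object@alphabet) < 1L || anyDuplicated(object@alphabet))
    return("alphabet must be non-empty and unique")
  if (!all(d$state %in% object@alphabet))
    return(paste0("state outside alphabet: ",
                  d$state[!d$state %in% object@alphabet][1L]))
  TRUE
})

#' DistanceMatrix: symmetric pairwise taxon distances
#'
#' @slot values numeric symmetric matrix, zero diagonal, labelled dimnames.
#' @export
setClass("DistanceMatrix", slots = c(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (!is.matrix(v) || !is.numeric(v)) return("'values' must be numeric matrix")
  if (nrow(v) != ncol(v)) return("must be square")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("taxon labels must be present and unique")
  if (!identical(rownames(v), colnames(v)))
    return("row and column labels must agree")
  if (any(!is.finite(v))) return("all distances must be finite")
  if (any(v < 0)) return("distances must be nonnegative")
  if (any(diag(v) != 0)) return("diagonal must be exactly 0")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric (1e-12)")
  TRUE
})

#' SupportProfile: bipartition -> bootstrap support bookkeeping
#'
#' Canonical split keys (see [splitKey()]) mapped to percentage support.
#' Splits belonging to the reference (full-data) tree are flagged so that
#' [meanSupport()] averages over the reference tree's internal nodes only.
#'
#' @slot splits data.frame with columns `key`, `support`, `inReference`.
#' @slot taxa character; taxon ordering the keys are relative to.
#' @slot replicates integer; bootstrap replicate count.
#' @slot method character; tree method tag ("nj" or "mp").
#' @export
setClass("SupportProfile",
         slots = c(splits = "data.frame", taxa = "character",
                   replicates = "integer", method = "character"))

setValidity("SupportProfile", function(object) {
  s <- object@splits
  if (!all(c("key", "support", "inReference") %in% names(s)))
    return("splits needs key/support/inReference columns")
  if (nrow(s) && (any(s$support < 0) || any(s$support > 100)))
    return("support values must lie in [0, 100]")
  if (object@replicates < 1L) return("replicates must be >= 1")
  TRUE
})

#' SHResult: Shimodaira-Hasegawa topology test result
#'
#' @slot table data.frame with one row per topology: `topology`, `score`
#'   (total over loci; parsimony steps or negative log-likelihood),
#'   `delta` (difference from the best topology) and `p`.
#' @slot resamples integer RELL resample count.
#' @slot scoreType "parsimony" or "mk1".
#' @export
setClass("SHResult",
         slots = c(table = "data.frame", resamples = "integer",
                   scoreType = "character"))

setValidity("SHResult", function(object) {
  tb <- object@table
  if (!all(c("topology", "score", "delta", "p") %in% names(tb)))
    return("table needs topology/score/delta/p columns")
  if (any(tb$p < 0 | tb$p > 1)) return("p-values must lie in [0, 1]")
  if (min(tb$delta) < -1e-9) return("delta must be >= 0")
  TRUE
})

#' HETResult: homoplasy excess test result
#'
#' Per-(removed taxon, split) bootstrap support changes and the flagged
#' outlier pairs suggesting reticulation.
#'
#' @slot delta data.frame: `taxon`, `split` (canonical key on the full
#'   taxon set), `supportFull`, `supportWithout`, `delta`.
#' @slot flags data.frame subset of `delta` satisfying the outlier rule.
#' @slot replicates integer bootstrap replicates per run.
#' @slot method tree method used ("nj" or "mp").
#' @slot minRise minimum absolute support rise for flagging (points).
#' @slot taxa taxon ordering the split keys refer to.
#' @slot warnings character; stability warnings recorded during the run.
#' @export
setClass("HETResult",
         slots = c(delta = "data.frame", flags = "data.frame",
                   replicates = "integer", method = "character",
                   minRise = "numeric", taxa = "character",
                   warnings = "character"))

#' ParsimonyASR: unordered-parsimony ancestral state reconstruction
#'
#' Produced by [fitchMPR()]. State sets are unions over all enumerated
#' binary resolutions of polytomies; transition counts are reported both as
#' the range over resolutions of the per-resolution delayed-transformation
#' (DELTRAN) count of independent origins (`min`/`max`) and as the extremes
#' over all most-parsimonious assignments (`mprMin`/`mprMax`).
#'
#' @slot tree the (possibly multifurcating) input phylo object.
#' @slot stateSets named list: node id -> character vector of MPR states.
#' @slot transitions data.frame with columns `from`, `to`, `min`, `max`,
#'   `mprMin`, `mprMax`.
#' @slot minLength integer; parsimony length minimized over resolutions.
#' @slot nResolutions integer; number of resolved trees enumerated.
#' @slot witnesses list with `min` and `max` elements, each carrying the
#'   resolution (Newick) and a full node-state assignment achieving the
#'   range endpoint for the focal direction.
#' @slot focalDirection character(2): the (from, to) direction whose range
#'   endpoints the witnesses certify.
#' @export
setClass("ParsimonyASR",
         slots = c(tree = "ANY", stateSets = "list",
                   transitions = "data.frame", minLength = "integer",
                   nResolutions = "integer", witnesses = "list",
                   focalDirection = "character"))

#' Mk1ASR: maximum-likelihood ancestral reconstruction under Mk1
#'
#' Produced by [mk1Reconstruct()].
#'
#' @slot tree rooted phylo with branch lengths used for the fit.
#' @slot marginals numeric matrix (internal nodes x states), rows sum to 1.
#' @slot alphaHat fitted symmetric rate.
#' @slot logLik maximized log-likelihood.
#' @slot equivocal logical per internal node: max marginal below the
#'   decision threshold.
#' @slot threshold the decision threshold used.
#' @export
setClass("Mk1ASR",
         slots = c(tree = "ANY", marginals = "matrix", alphaHat = "numeric",
                   logLik = "numeric", equivocal = "logical",
                   threshold = "numeric"))
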