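#' Construct an AFLPMatrix
#'
#' @param characters matrix (numeric, integer or logical) of 0/1/NA values.
#' @param taxonLabels optional character vector overriding rownames.
#' @param locusLabels optional character vector overriding colnames.
#' @return a validated [AFLPMatrix-class] object.
#' @examples
#' m <- AFLPMatrix(rbind(A = c(1, 1, 0, 1), B = c(1, 0, 1, 1)))
#' nPolymorphic(m)
#' @export
AFLPMatrix <- function(characters, taxonLabels = NULL, locusLabels = NULL) {
  m <- as.matrix(characters)
  storage.mode(m) <- "integer"
  if (!is.null(taxonLabels)) rownames(m) <- taxonLabels
  if (!is.null(locusLabels)) colnames(m) <- locusLabels
  if (is.null(colnames(m)) && ncol(m) >= 1L)
    colnames(m) <- paste0("L", seq_len(ncol(m)))
  new("AFLPMatrix", characters = m)
}

#' @rdname AFLPMatrix-class
#' @aliases taxonLabels,AFLPMatrix-method
setMethod("taxonLabels", "AFLPMatrix", function(x) rownames(x@characters))

#' @rdname AFLPMatrix-class
setMethod("locusLabels", "AFLPMatrix", function(x) colnames(x@characters))

#' @rdname AFLPMatrix-class
setMethod("nTaxa", "AFLPMatrix", function(x) nrow(x@characters))

#' @rdname AFLPMatrix-class
setMethod("nLoci", "AFLPMatrix", function(x) ncol(x@characters))

#' @rdname AFLPMatrix-class
setMethod("aflpCharacters", "AFLPMatrix", function(x) x@characters)

#' @rdname nPolymorphic
setMethod("nPolymorphic", "AFLPMatrix", function(x) {
  m <- x@characters
  n1 <- colSums(m == 1L, na.rm = TRUE)
  n0 <- colSums(m == 0L, na.rm = TRUE)
  sum(n1 >= 1L & n0 >= 1L)
})

#' @rdname nInformative
setMethod("nInformative", "AFLPMatrix", function(x) {
  m <- x@characters
  n1 <- colSums(m == 1L, na.rm = TRUE)
  n0 <- colSums(m == 0L, na.rm = TRUE)
  sum(n1 >= 2L & n0 >= 2L)
})

setMethod("show", "AFLPMatrix", function(object) {
  cat("AFLPMatrix:", nTaxa(object), "taxa x", nLoci(object), "loci\n")
  cat("  polymorphic:", nPolymorphic(object),
      " informative:", nInformative(object),
      " missing cells:", sum(is.na(object@characters)), "\n")
  cat("  taxa:", paste(head(taxonLabels(object), 5L), collapse = ", "),
      if (nTaxa(object) > 5L) "..." else "", "\n")
})

#' Subset an AFLPMatrix
#'
#' @param x AFLPMatrix
#' @param i taxon index or labels
#' @param j locus index or labels
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "AFLPMatrix", function(x, i, j, ..., drop = FALSE) {
  m <- x@characters
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("AFLPMatrix", characters = m)
})

#' Drop one or more taxa from an AFLPMatrix
#'
#' @param x AFLPMatrix
#' @param taxa character labels to remove
#' @return AFLPMatrix without those rows
#' @export
dropTaxa <- function(x, taxa) {
  keep <- setdiff(taxonLabels(x), taxa)
  if (length(keep) == nTaxa(x))
    warning("none of the taxa to drop were present")
  x[keep, ]
}

#' Construct a TraitTable
#'
#' @param taxon character taxon labels (unique).
#' @param state character states, one per taxon.
#' @param alphabet allowed states; defaults to the sorted unique states.
#' @param species,site optional metadata vectors.
#' @return a validated [TraitTable-class] object.
#' @export
TraitTable <- function(taxon, state, alphabet = sort(unique(state)),
                       species = NULL, site = NULL) {
  d <- data.frame(taxon = as.character(taxon), state = as.character(state),
                  stringsAsFactors = FALSE)
  if (!is.null(species)) d$species <- as.character(species)
  if (!is.null(site)) d$site <- as.character(site)
  new("TraitTable", data = d, alphabet = as.character(alphabet))
}

#' @rdname TraitTable-class
setMethod("traitStates", "TraitTable", function(x) {
  stats::setNames(x@data$state, x@data$taxon)
})

#' @rdname TraitTable-class
setMethod("stateAlphabet", "TraitTable", function(x) x@alphabet)

#' @rdname TraitTable-class
#' @param object a TraitTable
#' @export
traitData <- function(object) object@data

setMethod("show", "TraitTable", function(object) {
  cat("TraitTable:", nrow(object@data), "taxa, states {",
      paste(object@alphabet, collapse = ", "), "}\n")
  print(table(object@data$state))
})

#' Construct a DistanceMatrix
#'
#' @param values symmetric nonnegative numeric matrix with zero diagonal
#'   and taxon labels as dimnames.
#' @return a validated [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values) {
  v <- as.matrix(values)
  # symmetrize away floating dust below the validity tolerance
  new("DistanceMatrix", values = v)
}

#' @rdname DistanceMatrix-class
setMethod("taxonLabels", "DistanceMatrix", function(x) rownames(x@values))

#' Extract the raw distance values
#' @param x a DistanceMatrix
#' @param ... ignored
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

setMethod("show", "DistanceMatrix", function(object) {
  v <- object@values
  cat("DistanceMatrix:", nrow(v), "taxa; range [",
      format(min(v[upper.tri(v)]), digits = 4), ",",
      format(max(v), digits = 4), "]\n")
})

#' @rdname SupportProfile-class
setMethod("meanSupport", "SupportProfile", function(x) {
  s <- x@splits
  mean(s$support[s$inReference])
})

#' @rdname SupportProfile-class
setMethod("splitSupport", "SupportProfile", function(x) x@splits)

setMethod("show", "SupportProfile", function(object) {
  cat("SupportProfile (", object@method, ", ", object@replicates,
      " replicates): ", sum(object@splits$inReference),
      " reference splits, mean support ",
      format(meanSupport(object), digits = 4), "%\n", sep = "")
})

setMethod("show", "SHResult", function(object) {
  cat("Shimodaira-Hasegawa test (", object@scoreType, " scores, ",
      object@resamples, " RELL resamples)\n", sep = "")
  print(object@table, row.names = FALSE)
})

setMethod("show", "ParsimonyASR", function(object) {
  cat("Unordered-parsimony ancestral reconstruction\n")
  cat("  resolutions enumerated:", object@nResolutions,
      " minimal length:", object@minLength, "\n")
  print(object@transitions, row.names = FALSE)
})

setMethod("show", "Mk1ASR", function(object) {
  cat("Mk1 ancestral reconstruction: alpha-hat =",
      format(object@alphaHat, digits = 5),
      " logLik =", format(object@logLik, digits = 6), "\n")
  cat("  equivocal nodes (max marginal <", object@threshold, "):",
      sum(object@equivocal), "of", length(object@equivocal), "\n")
})
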