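#' @rdname AFLPMatrix-class
#' @param x an object
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' @rdname AFLPMatrix-class
#' @export
setGeneric("locusLabels", function(x) standardGeneric("locusLabels"))

#' @rdname AFLPMatrix-class
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname AFLPMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname AFLPMatrix-class
#' @export
setGeneric("aflpCharacters", function(x) standardGeneric("aflpCharacters"))

#' Number of polymorphic loci
#'
#' A locus is polymorphic when its non-missing cells contain both a 0 and
#' a 1. See [nInformative()] for the parsimony-informative count.
#' @param x an [AFLPMatrix-class] object
#' @return integer count
#' @export
setGeneric("nPolymorphic", function(x) standardGeneric("nPolymorphic"))

#' Number of parsimony-informative loci
#'
#' A binary locus is parsimony informative when at least two taxa carry a 0
#' and at least two carry a 1 (among non-missing cells).
#' @param x an [AFLPMatrix-class] object
#' @return integer count
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))

#' @rdname TraitTable-class
#' @param x an object
#' @export
setGeneric("traitStates", function(x) standardGeneric("traitStates"))

#' @rdname TraitTable-class
#' @export
setGeneric("stateAlphabet", function(x) standardGeneric("stateAlphabet"))

#' @rdname SupportProfile-class
#' @param x an object
#' @export
setGeneric("meanSupport", function(x) standardGeneric("meanSupport"))

#' @rdname SupportProfile-class
#' @export
setGeneric("splitSupport", function(x) standardGeneric("splitSupport"))
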