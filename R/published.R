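## The species-level topology of the Xenotilapia-lineage AFLP phylogram, as
## described in words in the source study's results: nested outgroups
## (Ophthalmotilapia cherry, then Cyathopharynx, then the Callochromis
## pair), the (Asprotilapia leptura, Microdontochromis tenuidentata) clade
## sister to the remaining Xenotilapia, the (Enantiopus melanogenys,
## X. ochrogenys) pair grouping with the bathyphila/boulengeri/sima/
## flavipinnis assemblage (internal arrangement unresolved), and the
## less-resolved ornatipinnis/spiloptera/papilio lineage as its sister.
## The two unresolved regions are encoded as polytomies.

.speciesTipMap <- c(
  "Asprotilapia leptura" = "Asprotilapia_leptura",
  "Callochromis macrops" = "Callochromis_macrops",
  "Callochromis stappersii" = "Callochromis_stappersii",
  "Cyathopharynx furcifer" = "Cyathopharynx_furcifer",
  "Enantiopus melanogenys" = "Enantiopus_melanogenys",
  "Microdontochromis tenuidentata" = "Microdontochromis_tenuidentata",
  "Ophthalmotilapia nasuta" = "Ophthalmotilapia_nasuta",
  "Ophthalmotilapia ventralis" = "Ophthalmotilapia_ventralis",
  "Xenotilapia bathyphila" = "Xenotilapia_bathyphila",
  "Xenotilapia boulengeri" = "Xenotilapia_boulengeri",
  "Xenotilapia flavipinnis" = "Xenotilapia_flavipinnis",
  "Xenotilapia ochrogenys" = "Xenotilapia_ochrogenys",
  "Xenotilapia ornatipinnis" = "Xenotilapia_ornatipinnis",
  "Xenotilapia sima" = "Xenotilapia_sima",
  "Xenotilapia sp. \"papilio sunflower\"" = "Xenotilapia_papilio",
  "Xenotilapia spiloptera" = "Xenotilapia_spiloptera")

#' Published species topology of the Xenotilapia lineage
#'
#' Rooted 16-species tree with the two weakly resolved regions (the
#' melanogenys/ochrogenys + bathyphila/boulengeri/sima/flavipinnis
#' assemblage, and the ornatipinnis/spiloptera/papilio lineage) left as
#' polytomies, ready for [fitchMPR()] enumeration.
#'
#' @return rooted `phylo` with 16 species tips.
#' @export
xenotilapiaSpeciesTree <- function() {
  nwk <- paste0(
    "((Ophthalmotilapia_nasuta,Ophthalmotilapia_ventralis),",
    "(Cyathopharynx_furcifer,((Callochromis_macrops,",
    "Callochromis_stappersii),((Asprotilapia_leptura,",
    "Microdontochromis_tenuidentata),(((Enantiopus_melanogenys,",
    "Xenotilapia_ochrogenys),(Xenotilapia_bathyphila,",
    "Xenotilapia_boulengeri,Xenotilapia_sima,Xenotilapia_flavipinnis)),",
    "(Xenotilapia_ornatipinnis,Xenotilapia_spiloptera,",
    "Xenotilapia_papilio))))));")
  ape::read.tree(text = nwk)
}

#' Species-level parental-care states
#'
#' Collapses the packaged individual-level care table to one record per
#' species, keyed by the tip labels of [xenotilapiaSpeciesTree()].
#'
#' @return a [TraitTable-class] with 16 species.
#' @export
xenotilapiaSpeciesCareStates <- function() {
  tab <- traitData(xenotilapiaCareTable())
  perSpecies <- unique(tab[, c("species", "state")])
  if (anyDuplicated(perSpecies$species))
    stop("inconsistent care states within a species", call. = FALSE)
  TraitTable(taxon = unname(.speciesTipMap[perSpecies$species]),
             state = perSpecies$state,
             alphabet = c("Biparental Mouthbrooder",
                          "Maternal Mouthbrooder"),
             species = perSpecies$species)
}
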