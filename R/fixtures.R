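.extdata <- function(file) {
  path <- system.file("extdata", file, package = "allerGene")
  if (path == "") stop("packaged data file not found: ", file)
  path
}

#' Packaged gene architecture presets
#'
#' \code{derF1GeneSpec}: a Der f 1-like gene — 6 exons (966-nt CDS encoding
#' a 321-aa preproenzyme plus stop) and 5 introns at mRNA positions
#' 87, 291, 519, 600 and 760 with lengths 66, 78, 58, 66 and 60 nt. The
#' intron placements and lengths are chosen so that gene-alignment
#' coordinates of the documented polymorphic sites land on the correct
#' codons (e.g. alignment nt 1211 is the first base of the codon for mature
#' residue 197); see the methods vignette for why this coordinate-faithful
#' layout is preferred over the also-reported 1278-bp total length, which is
#' arithmetically incompatible with those site coordinates.
#'
#' \code{derP1GeneSpec}: a Der p 1-like gene — 5 exons (963-nt CDS, 320-aa
#' preproenzyme: one mature residue fewer) and 4 introns at mRNA positions
#' 87, 291, 600 and 760 (the Der f 1 intron 3 homolog is absent), with a
#' variable poly-T tract in intron 1 (10--12 nt per individual, spanning
#' the reported 3-state gene-length spread).
#'
#' @param seed integer seed for sequence generation.
#' @return A \linkS4class{GeneSpec}.
#' @export
derF1GeneSpec <- function(seed = 101L) {
  geneSpec(exonLengths = c(87L, 204L, 228L, 81L, 160L, 206L),
           intronLengths = c(66L, 78L, 58L, 66L, 60L),
           gcFraction = 0.4, seed = seed)
}

#' @rdname derF1GeneSpec
#' @export
derP1GeneSpec <- function(seed = 102L) {
  geneSpec(exonLengths = c(87L, 204L, 309L, 160L, 203L),
           intronLengths = c(69L, 78L, 123L, 61L),
           gcFraction = 0.4, polyTIntron = 1L, polyTRange = c(10L, 12L),
           seed = seed)
}

#' Preproenzyme coordinate map presets
#'
#' Der f 1-like segmentation: 18-aa signal peptide, 80-aa proenzyme,
#' 223-aa mature enzyme (321-aa preproenzyme); the partner species lacks
#' the residue at mature position 9, giving the dual numbering 100(99),
#' 216(215), ... Der p 1-like: mature enzyme 222 aa, no deletions recorded
#' towards its partner (the offset there is an insertion, not expressible
#' as a deletion set).
#'
#' @return A \linkS4class{PeptideCoordinateMap}.
#' @export
derF1CoordinateMap <- function() {
  buildCoordinateMap(18L, 80L, 223L, crossDeletions = 9L)
}

#' @rdname derF1CoordinateMap
#' @export
derP1CoordinateMap <- function() {
  buildCoordinateMap(18L, 80L, 222L)
}

#' Packaged genotype-table fixtures
#'
#' Curated transcriptions of the per-individual variant-site tables for the
#' 22 D. farinae and 12 D. pteronyssinus direct-sequenced group 1 allergen
#' amplicons, including the IUPAC heterozygote codes (and the
#' transcription's internal inconsistencies, which are preserved, not
#' corrected: phasing surfaces them as mismatch records).
#'
#' @return A \linkS4class{GenotypeMatrix} (all table columns; subset with
#'   \code{\link{variantSites}}).
#' @export
derF1Genotypes <- function() {
  readGenotypeTable(.extdata("derf1_genotypes.tsv"), gene = "DerF1")
}

#' @rdname derF1Genotypes
#' @export
derP1Genotypes <- function() {
  readGenotypeTable(.extdata("derp1_genotypes.tsv"), gene = "DerP1")
}

#' Packaged epitope residue-state matrices
#'
#' Residue states of eight mite group 1 allergens at the 14 positions of
#' the 4C1 antibody-binding epitope and the 4 positions of the
#' calcium-binding epitope (Der f 1 mature coordinates), as transcribed
#' from the published comparison; \code{"-"} is an alignment gap.
#'
#' @param epitope \code{"4C1"} or \code{"Ca"}.
#' @return Character matrix, rows = taxa, columns = positions.
#' @export
epitopeStates <- function(epitope = c("4C1", "Ca")) {
  epitope <- match.arg(epitope)
  file <- if (epitope == "4C1") "epitope_states_4c1.tsv" else
    "epitope_states_ca.tsv"
  tab <- read.delim(.extdata(file), check.names = FALSE, comment.char = "#",
                    colClasses = "character")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$taxon
  m
}

#' Packaged epitope definitions
#'
#' The 4C1 (14-residue) and calcium-binding (4-residue) epitopes of
#' Der f 1, read from the packaged YAML definition file.
#'
#' @param path optional path to an epitope YAML file with the same layout.
#' @return Named list of \linkS4class{EpitopeDefinition}s.
#' @export
epitopeDefinitions <- function(path = .extdata("epitopes.yaml")) {
  y <- yaml::read_yaml(path)
  out <- lapply(y$epitopes, function(e)
    epitopeDefinition(e$name, unlist(e$positions), unlist(e$residues)))
  setNames(out, vapply(y$epitopes, `[[`, "", "name"))
}

#' Published percent-identity matrix of group 1 allergens
#'
#' The printed pairwise identity matrix over the eight aligned mite group 1
#' allergen preproenzymes, as an \linkS4class{IdentityMatrix} (input for
#' distance-based tree building).
#'
#' @return An \linkS4class{IdentityMatrix}.
#' @export
publishedIdentityMatrix <- function() {
  tab <- read.delim(.extdata("group1_identity_published.tsv"),
                    check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1L])
  rownames(m) <- tab$taxon
  identityMatrix(m)
}
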