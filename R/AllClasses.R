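#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData rowData<- colData
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# GeneSpec / PopulationSpec: parameter objects for the synthetic generator
# ---------------------------------------------------------------------------

#' Specification of a synthetic allergen gene
#'
#' Describes the exon/intron architecture of a gene to be generated by
#' \code{\link{makeReferenceGene}}: exon lengths (whose sum is the CDS,
#' start and stop codons included), intron lengths, base composition and an
#' optional variable poly-T homopolymer embedded in one intron (the Der p 1
#' intron 1 situation, where allele-specific tract lengths make the gene
#' 1248--1250 bp long).
#'
#' @slot exonLengths integer vector of exon lengths (nt); the sum must be a
#'   multiple of 3 and at least 6 (start + stop codon).
#' @slot intronLengths integer vector of intron lengths, one fewer than the
#'   exons, each at least 20 nt.
#' @slot gcFraction GC proportion for i.i.d. base sampling.
#' @slot polyTIntron index of the intron carrying the poly-T tract
#'   (0 = none).
#' @slot polyTRange integer (min, max) tract length drawn per individual.
#' @slot seed integer seed driving all draws.
#' @exportClass GeneSpec
setClass("GeneSpec", representation(
  exonLengths = "integer",
  intronLengths = "integer",
  gcFraction = "numeric",
  polyTIntron = "integer",
  polyTRange = "integer",
  seed = "integer"
))

setValidity("GeneSpec", function(object) {
  msg <- character()
  if (length(object@exonLengths) < 1L || any(object@exonLengths < 1L))
    msg <- c(msg, "exonLengths must be positive")
  if (sum(object@exonLengths) %% 3L != 0L)
    msg <- c(msg, "sum of exonLengths must be divisible by 3")
  if (sum(object@exonLengths) < 6L)
    msg <- c(msg, "sum of exonLengths must be >= 6 (start + stop codon)")
  if (length(object@intronLengths) != length(object@exonLengths) - 1L)
    msg <- c(msg, "intron count must equal exon count - 1")
  if (length(object@intronLengths) && any(object@intronLengths < 20L))
    msg <- c(msg, "each intron must be >= 20 nt")
  if (object@gcFraction < 0 || object@gcFraction > 1)
    msg <- c(msg, "gcFraction must lie in [0, 1]")
  if (object@polyTIntron > length(object@intronLengths))
    msg <- c(msg, "polyTIntron exceeds the number of introns")
  if (object@polyTIntron > 0L) {
    # the tract plus splice dinucleotides must fit inside the intron
    if (max(object@polyTRange) + 8L > object@intronLengths[object@polyTIntron])
      msg <- c(msg, "poly-T tract does not fit inside the designated intron")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSpec
#'
#' @param exonLengths,intronLengths integer vectors (see
#'   \linkS4class{GeneSpec}).
#' @param gcFraction GC proportion in \code{[0,1]}.
#' @param polyTIntron index of the intron carrying a variable poly-T tract,
#'   or 0 for none.
#' @param polyTRange length-2 integer (min, max) poly-T tract length.
#' @param seed integer seed.
#' @return A \linkS4class{GeneSpec}.
#' @examples
#' geneSpec(c(9, 9), 30, seed = 1)
#' @export
geneSpec <- function(exonLengths, intronLengths = integer(), gcFraction = 0.4,
                     polyTIntron = 0L, polyTRange = c(10L, 12L), seed = 1L) {
  new("GeneSpec",
      exonLengths = as.integer(exonLengths),
      intronLengths = as.integer(intronLengths),
      gcFraction = as.numeric(gcFraction),
      polyTIntron = as.integer(polyTIntron),
      polyTRange = as.integer(polyTRange),
      seed = as.integer(seed))
}

#' Specification of a synthetic diploid population
#'
#' Parameters for \code{\link{makePopulation}}: a population of diploid
#' individuals drawn from two haplotypes under Hardy-Weinberg proportions
#' (\eqn{p^2}, \eqn{2p(1-p)}, \eqn{(1-p)^2}), plus private singleton
#' mutations, rendered as Sanger-style consensus sequences with IUPAC
#' ambiguity codes at heterozygous sites.
#'
#' @slot nIndividuals number of diploid individuals.
#' @slot h1Frequency allele frequency \eqn{p} of haplotype 1.
#' @slot nDiagnosticSites number of biallelic sites distinguishing the two
#'   haplotypes.
#' @slot singletonRate expected number of private mutations per individual.
#' @slot silentOnly if TRUE, private mutations are placed only at codon
#'   third positions.
#' @slot seed integer seed.
#' @exportClass PopulationSpec
setClass("PopulationSpec", representation(
  nIndividuals = "integer",
  h1Frequency = "numeric",
  nDiagnosticSites = "integer",
  singletonRate = "numeric",
  silentOnly = "logical",
  seed = "integer"
))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@h1Frequency < 0 || object@h1Frequency > 1)
    msg <- c(msg, "h1Frequency must lie in [0, 1]")
  if (object@nDiagnosticSites < 0L)
    msg <- c(msg, "nDiagnosticSites must be >= 0")
  if (object@singletonRate < 0) msg <- c(msg, "singletonRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationSpec
#'
#' Defaults reflect the Der f 1 study conditions: 22 sequenced individuals,
#' a haplotype-1 allele frequency of 0.73 (the frequency implied by the
#' reported diplotype counts), 9 diagnostic sites (the homozygote-segregating
#' columns of the published genotype table) and about 0.2 private mutations
#' per individual.
#'
#' @param nIndividuals,h1Frequency,nDiagnosticSites,singletonRate,silentOnly,seed
#'   see \linkS4class{PopulationSpec}.
#' @return A \linkS4class{PopulationSpec}.
#' @examples
#' populationSpec(nIndividuals = 10, h1Frequency = 0.5, seed = 7)
#' @export
populationSpec <- function(nIndividuals = 22L, h1Frequency = 0.73,
                           nDiagnosticSites = 9L, singletonRate = 0.2,
                           silentOnly = FALSE, seed = 1L) {
  new("PopulationSpec",
      nIndividuals = as.integer(nIndividuals),
      h1Frequency = as.numeric(h1Frequency),
      nDiagnosticSites = as.integer(nDiagnosticSites),
      singletonRate = as.numeric(singletonRate),
      silentOnly = as.logical(silentOnly),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# GeneModel
# ---------------------------------------------------------------------------

#' Exon/intron model of a genomic amplicon
#'
#' Coordinates are 1-based inclusive on the amplicon. Exons and introns
#' alternate, starting and ending with an exon, and tile the amplicon.
#' The concatenated exon sequence is the coding sequence; mRNA position 1 is
#' the first nucleotide of the start codon (the amplicons are assumed trimmed
#' to start..stop in coding orientation).
#'
#' @slot exons \code{IRanges} of exon intervals on the amplicon.
#' @slot introns \code{IRanges} of intron intervals.
#' @slot donor,acceptor splice dinucleotides (first/last two intron bases).
#' @slot cdnaAnchor identifier of the cDNA reference the model is anchored to.
#' @slot seqid identifier of the amplicon.
#' @slot flags character vector of warnings attached during inference
#'   (e.g. non-canonical splice sites under strict mode).
#' @exportClass GeneModel
setClass("GeneModel", representation(
  exons = "IRanges",
  introns = "IRanges",
  donor = "character",
  acceptor = "character",
  cdnaAnchor = "character",
  seqid = "character",
  flags = "character"
))

setValidity("GeneModel", function(object) {
  msg <- character()
  ne <- length(object@exons)
  ni <- length(object@introns)
  if (ne < 1L) msg <- c(msg, "a gene model needs at least one exon")
  if (ni != ne - 1L) msg <- c(msg, "intron count must equal exon count - 1")
  if (ni > 0L) {
    if (length(object@donor) != ni || length(object@acceptor) != ni)
      msg <- c(msg, "donor/acceptor must have one entry per intron")
    # alternation and tiling
    es <- start(object@exons); ee <- end(object@exons)
    is <- start(object@introns); ie <- end(object@introns)
    ok <- all(is == ee[-ne] + 1L) && all(es[-1L] == ie + 1L)
    if (!ok) msg <- c(msg, "exons and introns must alternate and tile the amplicon")
  }
  if (any(width(object@exons) < 1L)) msg <- c(msg, "empty exon")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel from exon intervals
#'
#' Introns are derived as the gaps between consecutive exons.
#'
#' @param exonStarts,exonEnds 1-based inclusive exon coordinates on the
#'   amplicon.
#' @param genomic optional amplicon sequence (character or
#'   \code{DNAString}); when given, splice dinucleotides are recorded.
#' @param cdnaAnchor,seqid identifiers.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' GeneModel(c(1, 40), c(10, 60))
#' @export
GeneModel <- function(exonStarts, exonEnds, genomic = NULL,
                      cdnaAnchor = NA_character_, seqid = "amplicon") {
  exons <- IRanges(start = as.integer(exonStarts), end = as.integer(exonEnds))
  ne <- length(exons)
  if (ne > 1L) {
    introns <- IRanges(start = end(exons)[-ne] + 1L,
                       end = start(exons)[-1L] - 1L)
  } else {
    introns <- IRanges()
  }
  donor <- acceptor <- character(length(introns))
  if (!is.null(genomic) && length(introns)) {
    g <- .chars(genomic)
    donor <- vapply(seq_along(introns), function(i)
      .collapse(g[start(introns)[i] + 0:1]), character(1))
    acceptor <- vapply(seq_along(introns), function(i)
      .collapse(g[end(introns)[i] - 1:0]), character(1))
  }
  new("GeneModel", exons = exons, introns = introns, donor = donor,
      acceptor = acceptor, cdnaAnchor = as.character(cdnaAnchor),
      seqid = as.character(seqid), flags = character())
}

# ---------------------------------------------------------------------------
# GenotypeMatrix
# ---------------------------------------------------------------------------

#' Per-individual allele states at variant sites
#'
#' A \code{SummarizedExperiment} whose single assay \code{"calls"} holds one
#' row per site and one column per individual. Cells are plain bases,
#' IUPAC ambiguity codes (heterozygotes in direct-sequenced diploids), or
#' full codon strings for exonic sites; \code{NA} marks a state not recorded
#' for that individual. \code{rowData} carries the site annotation
#' (\code{coordinate}: gene-alignment nt position with position 1 at the A of
#' ATG; \code{region}: \code{"exon_k"}/\code{"intron_k"}), \code{colData} the
#' individual ids and locality tags.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("coordinate", "region") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'coordinate' and 'region'")
  calls <- SummarizedExperiment::assay(object, "calls")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(grepl("^[ACGTRYSWKMBDHVN]+$", bad)))
    msg <- c(msg, "calls must be IUPAC nucleotide strings")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix, sites x individuals; bases, IUPAC codes or
#'   codon strings.
#' @param coordinate integer vector of gene-alignment nt positions (one per
#'   row).
#' @param region character vector, \code{"exon_k"} / \code{"intron_k"} per
#'   row.
#' @param individuals character vector of individual ids (one per column).
#' @param locality optional character vector of locality tags.
#' @param gene identifier of the gene/locus.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' GenotypeMatrix(matrix(c("A", "T", "W", "A"), nrow = 1,
#'                       dimnames = list(NULL, paste0("id", 1:4))),
#'                coordinate = 100, region = "intron_1",
#'                individuals = paste0("id", 1:4))
#' @export
GenotypeMatrix <- function(calls, coordinate, region, individuals = colnames(calls),
                           locality = NA_character_, gene = "gene") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  dimnames(calls) <- list(
    if (nrow(calls)) paste0("site_", coordinate),
    if (ncol(calls)) individuals)
  rd <- DataFrame(coordinate = as.integer(coordinate),
                  region = as.character(region))
  cd <- DataFrame(individual = as.character(individuals),
                  locality = rep_len(as.character(locality), ncol(calls)),
                  row.names = individuals)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rd, colData = cd)
  metadata(se)$gene <- gene
  new("GenotypeMatrix", se)
}

# ---------------------------------------------------------------------------
# HaplotypePair
# ---------------------------------------------------------------------------

#' Two inferred haplotypes with per-individual diplotype assignments
#'
#' @slot h1,h2 named allele vectors over the diagnostic sites; H1 is the
#'   haplotype with the larger homozygote count (ties broken towards the
#'   lexicographically smaller vector).
#' @slot assignments \code{DataFrame} with one row per individual:
#'   \code{diplotype} (\code{"H1/H1"}, \code{"H2/H2"}, \code{"H1/H2"} or
#'   \code{"inconsistent"}), \code{nMismatch}, \code{mismatchSites} and
#'   \code{consistency} (fraction of diagnostic sites explained).
#' @slot sites coordinates of the diagnostic sites used.
#' @exportClass HaplotypePair
setClass("HaplotypePair", representation(
  h1 = "character",
  h2 = "character",
  assignments = "DataFrame",
  sites = "integer"
))

# ---------------------------------------------------------------------------
# PeptideCoordinateMap
# ---------------------------------------------------------------------------

#' Signal/pro/mature segmentation of a preproenzyme
#'
#' The preproenzyme is numbered so that position 1 is the first residue of
#' the mature enzyme; signal-peptide and proenzyme residues carry negative
#' positions \eqn{-(signal+pro) \ldots -1}; there is no position 0.
#' \code{crossDeletions} lists mature positions (in this species' numbering)
#' that are deleted in a partner species, defining the cross-species offset
#' used in dual numbering such as "100(99)".
#'
#' @slot signalLength,proLength,matureLength segment lengths (aa).
#' @slot crossDeletions integer vector of deleted mature positions.
#' @exportClass PeptideCoordinateMap
setClass("PeptideCoordinateMap", representation(
  signalLength = "integer",
  proLength = "integer",
  matureLength = "integer",
  crossDeletions = "integer"
))

setValidity("PeptideCoordinateMap", function(object) {
  msg <- character()
  if (object@signalLength < 0L || object@proLength < 0L ||
      object@matureLength < 0L)
    msg <- c(msg, "segment lengths must be >= 0")
  if (length(object@crossDeletions)) {
    if (any(object@crossDeletions < 1L |
            object@crossDeletions > object@matureLength))
      msg <- c(msg, "crossDeletions must be valid mature positions")
    if (anyDuplicated(object@crossDeletions))
      msg <- c(msg, "crossDeletions must be distinct")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EpitopeDefinition
# ---------------------------------------------------------------------------

#' A named epitope as a set of (mature position, reference residue) pairs
#'
#' @slot name epitope label (e.g. \code{"4C1"} or \code{"Ca"}).
#' @slot positions strictly increasing mature-coordinate positions.
#' @slot residues reference residues (single letters) at those positions.
#' @exportClass EpitopeDefinition
setClass("EpitopeDefinition", representation(
  name = "character",
  positions = "integer",
  residues = "character"
))

setValidity("EpitopeDefinition", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@residues))
    msg <- c(msg, "positions and residues must have equal length")
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (!all(object@residues %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    msg <- c(msg, "residues must be standard amino-acid letters")
  if (length(msg)) msg else TRUE
})

#' Construct an EpitopeDefinition
#'
#' @param name label.
#' @param positions mature-coordinate positions (strictly increasing).
#' @param residues reference residues at those positions.
#' @return An \linkS4class{EpitopeDefinition}.
#' @examples
#' epitopeDefinition("Ca", c(57, 58, 60, 92), c("D", "L", "E", "E"))
#' @export
epitopeDefinition <- function(name, positions, residues) {
  new("EpitopeDefinition", name = as.character(name),
      positions = as.integer(positions), residues = as.character(residues))
}

# ---------------------------------------------------------------------------
# IdentityMatrix
# ---------------------------------------------------------------------------

#' Pairwise percent-identity matrix
#'
#' A symmetric numeric matrix of pairwise identity percentages with a 100
#' diagonal, as produced by \code{\link{percentIdentity}}.
#'
#' @exportClass IdentityMatrix
setClass("IdentityMatrix", contains = "matrix")

setValidity("IdentityMatrix", function(object) {
  m <- object@.Data
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
  vals <- m[!is.na(m)]
  if (length(vals) && (any(vals < 0) || any(vals > 100)))
    msg <- c(msg, "values must lie in [0, 100]")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "must be symmetric")
  if (nrow(m) && !isTRUE(all.equal(unname(diag(m)), rep(100, nrow(m)))))
    msg <- c(msg, "diagonal must be 100")
  if (length(msg)) msg else TRUE
})

#' Construct an IdentityMatrix
#'
#' @param m square symmetric numeric matrix of percentages with 100 diagonal.
#' @return An \linkS4class{IdentityMatrix}.
#' @export
identityMatrix <- function(m) new("IdentityMatrix", as.matrix(m))
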