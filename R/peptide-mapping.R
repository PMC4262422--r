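#' Translate a coding sequence
#'
#' Standard genetic code; the CDS must start with ATG, end with a single
#' terminal stop codon and contain no internal stop.
#'
#' @param cds character or \code{DNAString} coding sequence.
#' @return \code{AAString} of length \code{nchar(cds)/3 - 1} (the stop is
#'   not represented).
#' @examples
#' translateCDS("ATGTGGTAA")  # MW
#' @export
translateCDS <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L)
    stop("CDS length ", nchar(s), " is not divisible by 3")
  if (substr(s, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  codons <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
  ncod <- length(codons)
  if (!(codons[ncod] %in% .STOP_CODONS))
    stop("CDS does not end with a stop codon")
  aa <- vapply(codons[-ncod], .translateCodon, character(1))
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon index ", internal[1L])
  AAString(.collapse(aa))
}

#' Build a preproenzyme coordinate map
#'
#' Defines the signal/pro/mature segmentation of a preproenzyme: mature
#' residues are numbered 1..\code{matureLength}; signal-peptide and
#' proenzyme residues take negative positions
#' \eqn{-(signal+pro) \ldots -1}; there is no position 0.
#' \code{crossDeletions} lists the mature positions deleted in a partner
#' species, from which \code{\link{crossSpeciesPosition}} derives the
#' partner numbering.
#'
#' @param signalLength,proLength,matureLength segment lengths in aa
#'   (each \eqn{\ge 0}).
#' @param crossDeletions integer vector of deleted mature positions.
#' @return A \linkS4class{PeptideCoordinateMap}.
#' @examples
#' buildCoordinateMap(18, 80, 223, crossDeletions = 9)
#' @export
buildCoordinateMap <- function(signalLength, proLength, matureLength,
                               crossDeletions = integer()) {
  if (any(c(signalLength, proLength, matureLength) < 0))
    stop("segment lengths must be >= 0")
  new("PeptideCoordinateMap",
      signalLength = as.integer(signalLength),
      proLength = as.integer(proLength),
      matureLength = as.integer(matureLength),
      crossDeletions = sort(as.integer(crossDeletions)))
}

#' Total preproenzyme length of a coordinate map
#'
#' @param map a \linkS4class{PeptideCoordinateMap}.
#' @return Integer: signal + pro + mature lengths.
#' @export
preproLength <- function(map) {
  stopifnot(is(map, "PeptideCoordinateMap"))
  map@signalLength + map@proLength + map@matureLength
}

#' Convert between preproenzyme and mature-signed coordinates
#'
#' \code{preproToMature}: 1-based position along the preproenzyme to the
#' signed mature coordinate (negative in the signal/pro segments, positive
#' in the mature enzyme, never 0). \code{matureToPrepro} is its inverse.
#'
#' @param map a \linkS4class{PeptideCoordinateMap}.
#' @param position integer position(s); preproenzyme coordinates for
#'   \code{preproToMature}, signed mature coordinates for
#'   \code{matureToPrepro}.
#' @return Integer vector of converted positions.
#' @examples
#' m <- buildCoordinateMap(18, 80, 223)
#' preproToMature(m, 98)   # -1
#' preproToMature(m, 99)   # 1
#' matureToPrepro(m, 197)  # 295
#' @export
preproToMature <- function(map, position) {
  stopifnot(is(map, "PeptideCoordinateMap"))
  position <- as.integer(position)
  total <- preproLength(map)
  prePro <- map@signalLength + map@proLength
  if (any(position < 1L | position > total))
    stop("preproenzyme position out of range 1..", total)
  ifelse(position <= prePro, position - prePro - 1L, position - prePro)
}

#' @rdname preproToMature
#' @export
matureToPrepro <- function(map, position) {
  stopifnot(is(map, "PeptideCoordinateMap"))
  position <- as.integer(position)
  prePro <- map@signalLength + map@proLength
  if (any(position == 0L))
    stop("position 0 does not exist in mature-signed coordinates")
  if (any(position < -prePro | position > map@matureLength))
    stop("signed position out of range -", prePro, "..", map@matureLength)
  ifelse(position < 0L, position + prePro + 1L, position + prePro)
}

#' Corresponding mature position in a partner species
#'
#' Under a set of single-residue deletions in the partner, the partner
#' position of a mature position \eqn{p} is \eqn{p} minus the number of
#' deleted positions \eqn{\le p} (the dual numbering of variant tables,
#' e.g. "100(99)" when position 9 is deleted in the partner).
#'
#' @param map a \linkS4class{PeptideCoordinateMap} carrying
#'   \code{crossDeletions}.
#' @param maturePosition mature position(s) in this species; querying a
#'   deleted position is an error.
#' @return Integer partner position(s).
#' @examples
#' m <- buildCoordinateMap(18, 80, 223, crossDeletions = 9)
#' crossSpeciesPosition(m, 100)  # 99
#' @export
crossSpeciesPosition <- function(map, maturePosition) {
  stopifnot(is(map, "PeptideCoordinateMap"))
  maturePosition <- as.integer(maturePosition)
  if (any(maturePosition < 1L | maturePosition > map@matureLength))
    stop("mature position out of range 1..", map@matureLength)
  if (any(maturePosition %in% map@crossDeletions))
    stop("position ", maturePosition[maturePosition %in% map@crossDeletions][1L],
         " is deleted in the partner species")
  vapply(maturePosition, function(p)
    p - sum(map@crossDeletions <= p), integer(1))
}

#' Map a gene-alignment nucleotide position to amino-acid coordinates
#'
#' For an exonic position, subtracts the upstream intron lengths to obtain
#' the CDS position, derives the (1-based) preproenzyme residue index as
#' \code{ceiling(cds/3)} with the within-codon offset, and converts to the
#' signed mature coordinate through the map. Intronic positions return a
#' non-coding record (\code{region = "intron_k"}, amino-acid fields
#' \code{NA}) rather than an error, so callers can label intronic variants.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param map a \linkS4class{PeptideCoordinateMap}.
#' @param position gene-alignment nt coordinate (1 = first nt of the start
#'   codon; introns counted).
#' @return List: \code{region}, \code{cdsPosition}, \code{preproPosition},
#'   \code{codonOffset} (1..3), \code{matureSignedPosition}.
#' @examples
#' g <- makeReferenceGene(geneSpec(c(30, 30), 30, seed = 1))
#' m <- buildCoordinateMap(0, 0, 19)
#' ntToAA(g$model, m, 4)
#' @export
ntToAA <- function(model, map, position) {
  stopifnot(is(model, "GeneModel"), is(map, "PeptideCoordinateMap"))
  position <- as.integer(position)
  if (length(position) != 1L) stop("one position at a time")
  region <- .regionOf(model, position)
  if (grepl("^intron", region))
    return(list(region = region, cdsPosition = NA_integer_,
                preproPosition = NA_integer_, codonOffset = NA_integer_,
                matureSignedPosition = NA_integer_))
  cds <- .genomicToCds(model, position)
  prepro <- as.integer(ceiling(cds / 3))
  offset <- as.integer((cds - 1L) %% 3L + 1L)
  total <- preproLength(map)
  mature <- if (prepro >= 1L && prepro <= total)
    preproToMature(map, prepro) else NA_integer_
  list(region = region, cdsPosition = cds, preproPosition = prepro,
       codonOffset = offset, matureSignedPosition = mature)
}
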