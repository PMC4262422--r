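#' Accessors for gene models and coordinate maps
#'
#' @param x a \linkS4class{GeneModel}, \linkS4class{PeptideCoordinateMap},
#'   \linkS4class{HaplotypePair} or \linkS4class{EpitopeDefinition}.
#' @return \code{exons}/\code{introns}: \code{IRanges};
#'   \code{intronMrnaPositions}: for each intron, the cDNA position of the
#'   last exonic nucleotide upstream of it (the "mRNA position" convention
#'   used for introns); \code{segmentLengths}: named integer vector
#'   (signal, pro, mature); \code{haplotypes}: 2-row character matrix;
#'   \code{assignments}: \code{DataFrame} of diplotype assignments;
#'   \code{epitopePositions}/\code{epitopeResidues}: the epitope definition
#'   columns.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname accessors
#' @export
setGeneric("intronMrnaPositions", function(x) standardGeneric("intronMrnaPositions"))

#' @rdname accessors
#' @export
setGeneric("segmentLengths", function(x) standardGeneric("segmentLengths"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("epitopePositions", function(x) standardGeneric("epitopePositions"))

#' @rdname accessors
#' @export
setGeneric("epitopeResidues", function(x) standardGeneric("epitopeResidues"))

#' @rdname accessors
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("introns", "GeneModel", function(x) x@introns)

#' @rdname accessors
#' @export
setMethod("intronMrnaPositions", "GeneModel", function(x) {
  if (length(x@introns) == 0L) return(integer())
  cumsum(IRanges::width(x@exons))[seq_along(x@introns)]
})

#' @rdname accessors
#' @export
setMethod("segmentLengths", "PeptideCoordinateMap", function(x) {
  c(signal = x@signalLength, pro = x@proLength, mature = x@matureLength)
})

#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypePair", function(x) {
  rbind(H1 = x@h1, H2 = x@h2)
})

#' @rdname accessors
#' @export
setMethod("assignments", "HaplotypePair", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("epitopePositions", "EpitopeDefinition", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("epitopeResidues", "EpitopeDefinition", function(x) x@residues)

setMethod("show", "GeneSpec", function(object) {
  cat("GeneSpec:", length(object@exonLengths), "exon(s) /",
      length(object@intronLengths), "intron(s); CDS",
      sum(object@exonLengths), "nt; genomic",
      sum(object@exonLengths) + sum(object@intronLengths), "nt\n")
  if (object@polyTIntron > 0L)
    cat("  poly-T tract in intron", object@polyTIntron, "length",
        paste(object@polyTRange, collapse = "-"), "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel on '", object@seqid, "' (cDNA anchor: ",
      object@cdnaAnchor, ")\n", sep = "")
  cat("  ", length(object@exons), " exon(s), ", length(object@introns),
      " intron(s); amplicon span ", max(end(object@exons)), " nt; CDS ",
      sum(width(object@exons)), " nt\n", sep = "")
  if (length(object@introns)) {
    mp <- intronMrnaPositions(object)
    for (i in seq_along(object@introns)) {
      cat(sprintf("  intron %d: %d-%d (%d nt) %s..%s, mRNA pos %d\n",
                  i, start(object@introns)[i], end(object@introns)[i],
                  width(object@introns)[i],
                  object@donor[i], object@acceptor[i], mp[i]))
    }
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "HaplotypePair", function(object) {
  tab <- table(factor(object@assignments$diplotype,
                      levels = c("H1/H1", "H2/H2", "H1/H2", "inconsistent")))
  cat("HaplotypePair over", length(object@sites), "diagnostic site(s)\n")
  cat("  H1:", .collapse(object@h1), "\n  H2:", .collapse(object@h2), "\n")
  cat("  assignments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PeptideCoordinateMap", function(object) {
  cat(sprintf(paste0("PeptideCoordinateMap: signal %d aa, pro %d aa, ",
                     "mature %d aa (preproenzyme %d aa)\n"),
              object@signalLength, object@proLength, object@matureLength,
              object@signalLength + object@proLength + object@matureLength))
  if (length(object@crossDeletions))
    cat("  deleted in partner at mature position(s):",
        paste(object@crossDeletions, collapse = ", "), "\n")
})

setMethod("show", "EpitopeDefinition", function(object) {
  cat("EpitopeDefinition '", object@name, "': ", length(object@positions),
      " residue(s): ",
      paste0(object@residues, object@positions, collapse = " "), "\n", sep = "")
})
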