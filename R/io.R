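#' Read and write FASTA
#'
#' Thin wrappers over Biostrings with 70-column wrapping on output.
#'
#' @param x \code{DNAStringSet}/\code{AAStringSet} (or named character
#'   vector, with \code{type} deciding the class).
#' @param path file path.
#' @param type sequence type for \code{readFasta} / character input.
#' @return \code{writeFasta}: the path, invisibly. \code{readFasta}: a
#'   \code{DNAStringSet} or \code{AAStringSet}.
#' @export
writeFasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x))
    x <- if (type == "DNA") DNAStringSet(x) else AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname writeFasta
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (type == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
}

#' Write a gene model as GFF3
#'
#' Emits gene, exon, intron and CDS features (1-based inclusive) on the
#' model's amplicon sequence.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeGeneModelGFF3 <- function(model, path) {
  stopifnot(is(model, "GeneModel"))
  span <- max(end(model@exons))
  feats <- c("gene", rep("exon", length(model@exons)),
             rep("intron", length(model@introns)),
             rep("CDS", length(model@exons)))
  starts <- c(1L, start(model@exons), start(model@introns), start(model@exons))
  ends <- c(span, end(model@exons), end(model@introns), end(model@exons))
  ids <- c("gene1",
           paste0("exon", seq_along(model@exons)),
           if (length(model@introns)) paste0("intron", seq_along(model@introns)),
           paste0("cds", seq_along(model@exons)))
  # CDS phase: bases to skip to reach the next codon start
  cumBefore <- c(0L, cumsum(width(model@exons)))[seq_along(model@exons)]
  phase <- rep(NA_integer_, length(feats))
  phase[feats == "CDS"] <- (3L - cumBefore %% 3L) %% 3L
  gr <- GenomicRanges::GRanges(
    seqnames = model@seqid,
    ranges = IRanges(start = starts, end = ends),
    strand = "+", type = feats, ID = ids, phase = phase,
    source = "allerGene")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genotype table
#'
#' Tab-separated transcription of a per-individual variant-site table: one
#' row per individual, columns \code{individual}, \code{locality}, then one
#' column per site named by its gene-alignment nt coordinate. Cells hold
#' plain bases, IUPAC ambiguity codes or codon strings; \code{"-"} marks a
#' site not varying in (or not applicable to) that individual's species and
#' is read as \code{NA}. Following the presentation convention of such
#' tables, codon-valued columns are exonic and single-base columns
#' intronic.
#'
#' @param path TSV file.
#' @param gene gene identifier recorded in the result.
#' @return A \linkS4class{GenotypeMatrix} (all columns, invariant ones
#'   included; see \code{\link{variantSites}}).
#' @export
readGenotypeTable <- function(path, gene = basename(path)) {
  tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                    colClasses = "character")
  if (!all(c("individual", "locality") %in% colnames(tab)))
    stop("genotype table needs 'individual' and 'locality' columns")
  siteCols <- setdiff(colnames(tab), c("individual", "locality"))
  calls <- t(as.matrix(tab[, siteCols, drop = FALSE]))
  calls[calls == "-"] <- NA_character_
  colnames(calls) <- tab$individual
  region <- apply(calls, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) && all(nchar(x) == 3L)) "exon" else "intron"
  })
  GenotypeMatrix(calls, coordinate = as.integer(siteCols), region = region,
                 individuals = tab$individual, locality = tab$locality,
                 gene = gene)
}

#' Restrict a genotype matrix to its variant sites
#'
#' A site is variant iff at least two distinct alleles are observed across
#' individuals after IUPAC expansion.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return The matrix subset to variant rows, ordered by coordinate.
#' @export
variantSites <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  calls <- SummarizedExperiment::assay(gm, "calls")
  keep <- vapply(seq_len(nrow(calls)), function(i)
    length(observedAlleles(calls[i, ])) >= 2L, logical(1))
  out <- gm[keep, ]
  out[order(SummarizedExperiment::rowData(out)$coordinate), ]
}

#' Write a variant table (VCF-like TSV)
#'
#' One row per site: gene id, mRNA coordinate, reference allele (the
#' majority allele), alternate alleles, region/classification annotation
#' and the per-individual calls.
#'
#' @param gm a \linkS4class{GenotypeMatrix}, ideally after
#'   \code{\link{classifyVariants}}.
#' @param path output file.
#' @param header optional comment lines (each written with a leading
#'   \code{#}).
#' @return The path, invisibly.
#' @export
writeVariantTable <- function(gm, path, header = character()) {
  stopifnot(is(gm, "GenotypeMatrix"))
  rd <- SummarizedExperiment::rowData(gm)
  calls <- SummarizedExperiment::assay(gm, "calls")
  ref <- character(nrow(gm)); alt <- character(nrow(gm))
  for (i in seq_len(nrow(gm))) {
    alleles <- observedAlleles(calls[i, ])
    counts <- vapply(alleles, function(a)
      sum(vapply(calls[i, !is.na(calls[i, ])], function(s)
        a %in% .expandString(s), logical(1))), integer(1))
    ref[i] <- alleles[which.max(counts)]
    alt[i] <- paste(setdiff(alleles, ref[i]), collapse = ",")
  }
  info <- paste0("region=", rd$region,
                 if (!is.null(rd$classification))
                   paste0(";class=", rd$classification) else "",
                 if (!is.null(rd$aaChange) && any(nzchar(rd$aaChange)))
                   ifelse(nzchar(rd$aaChange),
                          paste0(";aa=", rd$aaChange), "") else "")
  out <- data.frame(CHROM = metadata(gm)$gene, POS = rd$coordinate,
                    REF = ref, ALT = alt, INFO = info,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(calls))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = ".")
  invisible(path)
}

# comment header stamped into pipeline outputs (no timestamps: outputs must
# be byte-identical across re-runs)
.stamp <- function(seed) {
  c(paste0(" allerGene ", as.character(packageVersion("allerGene"))),
    paste0(" seed: ", seed))
}
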