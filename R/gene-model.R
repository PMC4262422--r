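#' Infer exon/intron structure by spliced comparison against a cDNA
#'
#' Finds the maximal-scoring decomposition of a genomic amplicon into
#' alternating exons and introns such that the concatenated exons align to
#' the cDNA reference with substitutions only (the substitutions are the
#' polymorphisms under study; indels within exons are not modelled). Introns
#' are the genomic-only gaps; canonical GT..AG introns are favoured, and
#' among equal-scoring placements of a junction the leftmost placement that
#' yields GT..AG is chosen (leftmost overall if none is canonical). The
#' amplicon is assumed trimmed to the start..stop interval in coding
#' orientation, so mRNA position 1 is the first nucleotide of the start
#' codon.
#'
#' @param genomic amplicon sequence (character or \code{DNAString}).
#' @param cdna cDNA reference sequence; must not be longer than the genomic
#'   sequence.
#' @param strictSplice if TRUE (default), non-GT..AG introns are flagged in
#'   the model and raise a warning; if FALSE they are accepted silently.
#' @param minIntron minimum intron length (nt).
#' @param identityThreshold minimum per-exon identity between amplicon exon
#'   and cDNA; below it the sequences are declared unalignable.
#' @param cdnaAnchor,seqid identifiers recorded in the model.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' g <- makeReferenceGene(geneSpec(c(9, 9), 30, seed = 1))
#' inferGeneModel(g$genomic, g$cdna)
#' @export
inferGeneModel <- function(genomic, cdna, strictSplice = TRUE, minIntron = 20L,
                           identityThreshold = 0.9,
                           cdnaAnchor = "cdna", seqid = "amplicon") {
  g <- toupper(as.character(genomic))
  cd <- toupper(as.character(cdna))
  if (nchar(g) == 0L || nchar(cd) == 0L) stop("empty sequence")
  if (nchar(cd) > nchar(g))
    stop("cDNA reference is longer than the genomic sequence")
  res <- cpp_spliced_align(g, cd, as.integer(minIntron))
  if (is.na(res$score))
    stop("unalignable: no spliced decomposition exists (cDNA/genomic ",
         "length difference cannot be tiled by introns >= ", minIntron, " nt)")
  gch <- .chars(g)
  placements <- .normalisePlacements(gch, res$intron_start, res$intron_end)
  exonBounds <- .exonBoundsFromIntrons(nchar(g), placements)
  model <- GeneModel(exonBounds$start, exonBounds$end, g,
                     cdnaAnchor = cdnaAnchor, seqid = seqid)
  # exon-level identity against the cDNA
  cdch <- .chars(cd)
  off <- 0L
  for (i in seq_along(model@exons)) {
    w <- width(model@exons)[i]
    exSeq <- gch[seq(start(model@exons)[i], end(model@exons)[i])]
    refSeq <- cdch[off + seq_len(w)]
    ident <- mean(exSeq == refSeq)
    if (ident < identityThreshold)
      stop(sprintf("unalignable: exon %d identity %.3f below threshold %.2f",
                   i, ident, identityThreshold))
    off <- off + w
  }
  canon <- model@donor == "GT" & model@acceptor == "AG"
  if (any(!canon)) {
    msgs <- sprintf("intron %d non-canonical splice sites %s..%s",
                    which(!canon), model@donor[!canon], model@acceptor[!canon])
    if (strictSplice) {
      model@flags <- msgs
      for (m in msgs) warning(m, call. = FALSE)
    }
  }
  model
}

# choose, per intron, the leftmost equal-scoring placement, canonical ones
# first; shifts are valid iff they preserve the exon concatenation exactly
.normalisePlacements <- function(g, istart, iend) {
  n <- length(g)
  if (length(istart) == 0L)
    return(data.frame(start = integer(), end = integer()))
  for (idx in seq_along(istart)) {
    s <- istart[idx]; e <- iend[idx]
    lo <- if (idx == 1L) 1L else iend[idx - 1L] + 1L        # previous exon floor
    hi <- if (idx == length(istart)) n else istart[idx + 1L] - 1L
    KL <- 0L
    while (s - KL - 1L >= lo &&
           g[s - KL - 1L] == g[e - KL]) KL <- KL + 1L
    KR <- 0L
    while (e + KR + 1L <= hi &&
           g[e + KR + 1L] == g[s + KR]) KR <- KR + 1L
    shifts <- seq(-KL, KR)  # placement: intron at (s+k, e+k)
    canonical <- vapply(shifts, function(k)
      g[s + k] == "G" && g[s + k + 1L] == "T" &&
        g[e + k - 1L] == "A" && g[e + k] == "G", logical(1))
    k <- if (any(canonical)) shifts[which(canonical)[1L]] else shifts[1L]
    istart[idx] <- s + k
    iend[idx] <- e + k
  }
  data.frame(start = istart, end = iend)
}

.exonBoundsFromIntrons <- function(n, placements) {
  if (nrow(placements) == 0L)
    return(list(start = 1L, end = n))
  list(start = c(1L, placements$end + 1L),
       end = c(placements$start - 1L, n))
}

#' Table view of a gene model
#'
#' One row per intron: genomic interval, length, splice dinucleotides and
#' the mRNA position (cDNA coordinate of the last exonic nucleotide upstream
#' of the intron, with mRNA position 1 at the A of ATG).
#'
#' @param model a \linkS4class{GeneModel}.
#' @return \code{DataFrame}.
#' @export
geneModelTable <- function(model) {
  stopifnot(is(model, "GeneModel"))
  if (length(model@introns) == 0L)
    return(DataFrame(intron = integer(), genomicStart = integer(),
                     genomicEnd = integer(), length = integer(),
                     donor = character(), acceptor = character(),
                     mrnaPosition = integer()))
  DataFrame(intron = seq_along(model@introns),
            genomicStart = start(model@introns),
            genomicEnd = end(model@introns),
            length = width(model@introns),
            donor = model@donor,
            acceptor = model@acceptor,
            mrnaPosition = intronMrnaPositions(model))
}

#' Extract the coding sequence defined by a gene model
#'
#' Concatenates the exonic segments and validates that the result is a
#' well-formed CDS: starts with ATG, length divisible by 3, single terminal
#' stop codon and no internal stop.
#'
#' @param genomic amplicon sequence.
#' @param model a \linkS4class{GeneModel} valid for that sequence.
#' @return \code{DNAString} coding sequence (start codon through stop
#'   codon).
#' @examples
#' g <- makeReferenceGene(geneSpec(c(9, 9), 30, seed = 1))
#' extractCDS(g$genomic, g$model)
#' @export
extractCDS <- function(genomic, model) {
  stopifnot(is(model, "GeneModel"))
  g <- toupper(as.character(genomic))
  if (max(end(model@exons)) > nchar(g))
    stop("gene model extends beyond the sequence")
  cds <- .collapse(vapply(seq_along(model@exons), function(i)
    substr(g, start(model@exons)[i], end(model@exons)[i]), character(1)))
  if (substr(cds, 1L, 3L) != "ATG")
    stop("missing start codon: CDS begins '", substr(cds, 1, 3),
         "' at genomic coordinate ", start(model@exons)[1L])
  if (nchar(cds) %% 3L != 0L)
    stop("frame error: CDS length ", nchar(cds), " is not divisible by 3")
  codons <- substring(cds, seq(1L, nchar(cds) - 2L, by = 3L),
                      seq(3L, nchar(cds), by = 3L))
  ncod <- length(codons)
  if (!(codons[ncod] %in% .STOP_CODONS))
    stop("missing stop codon: CDS ends '", codons[ncod], "'")
  internal <- which(codons[-ncod] %in% .STOP_CODONS)
  if (length(internal))
    stop("internal stop codon '", codons[internal[1L]], "' at codon ",
         internal[1L], " (CDS position ", 3L * internal[1L] - 2L, ")")
  DNAString(cds)
}

#' Structural comparison of two gene models
#'
#' Matches introns across two models by their mRNA position (the flanking
#' exonic context in cDNA coordinates) and reports introns present in one
#' model but absent in the other, and matched introns whose lengths differ.
#' An empty result means the intron structures agree.
#'
#' @param modelA,modelB \linkS4class{GeneModel}s anchored to alignable
#'   cDNAs.
#' @param tolerance maximum mRNA-position difference (nt) for two introns to
#'   be considered homologous.
#' @param maxCdsDifference maximum CDS length difference (nt) before the
#'   anchors are declared unalignable.
#' @return \code{DataFrame} with one row per structural difference:
#'   \code{status} (\code{"absent_in_a"}, \code{"absent_in_b"},
#'   \code{"length_change"}), the intron indices in each model (NA where
#'   absent), mRNA positions and lengths.
#' @examples
#' a <- makeReferenceGene(geneSpec(c(9, 9), 30, seed = 1))$model
#' compareGeneModels(a, a)
#' @export
compareGeneModels <- function(modelA, modelB, tolerance = 15L,
                              maxCdsDifference = 30L) {
  stopifnot(is(modelA, "GeneModel"), is(modelB, "GeneModel"))
  cdsA <- sum(width(modelA@exons)); cdsB <- sum(width(modelB@exons))
  if (abs(cdsA - cdsB) > maxCdsDifference)
    stop("unalignable anchors: CDS lengths differ by ", abs(cdsA - cdsB),
         " nt (> ", maxCdsDifference, ")")
  mpA <- intronMrnaPositions(modelA)
  mpB <- intronMrnaPositions(modelB)
  wA <- width(modelA@introns); wB <- width(modelB@introns)
  usedB <- logical(length(mpB))
  rows <- list()
  for (i in seq_along(mpA)) {
    cand <- which(!usedB & abs(mpB - mpA[i]) <= tolerance)
    if (length(cand)) {
      j <- cand[which.min(abs(mpB[cand] - mpA[i]))]
      usedB[j] <- TRUE
      if (wA[i] != wB[j])
        rows[[length(rows) + 1L]] <- DataFrame(
          status = "length_change", intronA = i, intronB = j,
          mrnaA = mpA[i], mrnaB = mpB[j], lengthA = wA[i], lengthB = wB[j])
    } else {
      rows[[length(rows) + 1L]] <- DataFrame(
        status = "absent_in_b", intronA = i, intronB = NA_integer_,
        mrnaA = mpA[i], mrnaB = NA_integer_, lengthA = wA[i],
        lengthB = NA_integer_)
    }
  }
  for (j in which(!usedB)) {
    rows[[length(rows) + 1L]] <- DataFrame(
      status = "absent_in_a", intronA = NA_integer_, intronB = j,
      mrnaA = NA_integer_, mrnaB = mpB[j], lengthA = NA_integer_,
      lengthB = wB[j])
  }
  if (length(rows)) do.call(rbind, rows) else
    DataFrame(status = character(), intronA = integer(), intronB = integer(),
              mrnaA = integer(), mrnaB = integer(), lengthA = integer(),
              lengthB = integer())
}

#' Patch a partial 5' end with a reference prefix
#'
#' Direct-sequenced amplicons can miss a few 5' nucleotides relative to the
#' annotated start codon. This splices the first \code{n} nucleotides of a
#' reference sequence onto the amplicon and records the provenance of the
#' patched positions.
#'
#' @param genomic partial amplicon sequence.
#' @param reference reference sequence supplying the prefix.
#' @param n number of missing 5' nucleotides.
#' @param source label recorded as the provenance of the patch.
#' @return List: \code{sequence} (\code{DNAString}), \code{patched}
#'   (\code{IRanges} of positions taken from the reference), \code{source}.
#' @examples
#' spliceReferencePrefix("GAAATTC", "ATGAAATTC", 2)
#' @export
spliceReferencePrefix <- function(genomic, reference, n, source = "reference") {
  n <- as.integer(n)
  ref <- toupper(as.character(reference))
  if (n < 0L || n > nchar(ref)) stop("invalid prefix length")
  seq <- paste0(substr(ref, 1L, n), toupper(as.character(genomic)))
  list(sequence = DNAString(seq),
       patched = IRanges(start = if (n > 0L) 1L else integer(),
                         end = if (n > 0L) n else integer()),
       source = source)
}
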