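# translation helper used across modules: plain (unambiguous) codon -> residue
.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a plain codon: '", codon, "'", call. = FALSE)
  aa
}

#' Call variant sites from aligned consensus sequences
#'
#' Stacks same-locus diploid consensus sequences on common coordinates and
#' returns the positions at which two or more distinct alleles are observed
#' after IUPAC expansion. Heterozygous sites (ambiguity letters) contribute
#' both alleles. Each site is annotated with its exon/intron context from
#' the gene model; for exonic sites the per-individual call is the full
#' codon string (which may itself contain one ambiguity letter).
#'
#' Sequences must be indel-free on the common coordinate system; a declared
#' variable poly-T tract is length-normalised first (see \code{polyT}).
#'
#' @param sequences named \code{DNAStringSet} (or character vector) of
#'   consensus sequences.
#' @param model \linkS4class{GeneModel} for the common coordinates.
#' @param polyT optional integer \code{c(start, end)}: the reference
#'   interval of a variable poly-T tract; per-sequence tract-length
#'   differences are normalised to the reference length before stacking.
#' @param locality optional character vector of locality tags.
#' @param gene gene identifier recorded in the result.
#' @return A \linkS4class{GenotypeMatrix} with one row per variant site,
#'   ordered by coordinate. Exonic rows carry codon-string calls and the
#'   extra \code{rowData} columns \code{codonStart} (genomic coordinate of
#'   the codon's first base) and \code{cdsPosition}.
#' @examples
#' g <- makeReferenceGene(geneSpec(c(60, 60), 40, seed = 1))
#' p <- makePopulation(g, populationSpec(nIndividuals = 6, seed = 2))
#' callVariantSites(p$consensus, g$model)
#' @export
callVariantSites <- function(sequences, model, polyT = NULL,
                             locality = NA_character_, gene = "gene") {
  seqs <- .upperNamed(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%02d", seq_along(seqs))
  refLen <- max(end(model@exons))
  if (!is.null(polyT)) seqs <- .normalisePolyT(seqs, polyT, refLen)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths after poly-T normalisation: ",
         paste(unique(nchar(seqs)), collapse = ", "))
  if (nchar(seqs[1L]) != refLen)
    stop("sequence length ", nchar(seqs[1L]),
         " does not match the gene model span ", refLen)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  nAlleles <- apply(mat, 2L, function(col)
    length(unique(unlist(lapply(unique(col), expandIUPAC)))))
  variant <- which(nAlleles >= 2L)
  region <- .regionOf(model, variant)
  exonic <- grepl("^exon", region)
  calls <- matrix(NA_character_, nrow = length(variant), ncol = length(seqs))
  codonStart <- rep(NA_integer_, length(variant))
  cdsPos <- rep(NA_integer_, length(variant))
  for (k in seq_along(variant)) {
    pos <- variant[k]
    if (exonic[k]) {
      cp <- .genomicToCds(model, pos)
      cdsPos[k] <- cp
      codonCds <- cp - (cp - 1L) %% 3L
      codonPos <- .cdsToGenomic(model, codonCds + 0:2)
      codonStart[k] <- codonPos[1L]
      calls[k, ] <- apply(mat[, codonPos, drop = FALSE], 1L, .collapse)
    } else {
      calls[k, ] <- mat[, pos]
    }
  }
  gm <- GenotypeMatrix(calls, coordinate = variant, region = region,
                       individuals = ids, locality = locality, gene = gene)
  SummarizedExperiment::rowData(gm)$codonStart <- codonStart
  SummarizedExperiment::rowData(gm)$cdsPosition <- cdsPos
  gm
}

# collapse each sequence's poly-T tract to the reference length
.normalisePolyT <- function(seqs, polyT, refLen) {
  refTract <- polyT[2L] - polyT[1L] + 1L
  vapply(seqs, function(s) {
    delta <- nchar(s) - refLen
    tractLen <- refTract + delta
    if (tractLen < 1L)
      stop("poly-T normalisation failed: tract length ", tractLen)
    tract <- substr(s, polyT[1L], polyT[1L] + tractLen - 1L)
    if (!grepl("^T+$", tract))
      stop("declared poly-T interval is not a T homopolymer: '", tract, "'")
    paste0(substr(s, 1L, polyT[1L] - 1L), strrep("T", refTract),
           substr(s, polyT[1L] + tractLen, nchar(s)))
  }, character(1), USE.NAMES = TRUE)
}

.regionOf <- function(model, positions) {
  vapply(positions, function(p) {
    k <- which(p >= start(model@exons) & p <= end(model@exons))
    if (length(k)) return(paste0("exon_", k))
    k <- which(p >= start(model@introns) & p <= end(model@introns))
    if (length(k)) return(paste0("intron_", k))
    stop("position ", p, " outside the gene model")
  }, character(1))
}

.genomicToCds <- function(model, pos) {
  k <- which(pos >= start(model@exons) & pos <= end(model@exons))
  if (length(k) != 1L) return(NA_integer_)
  prev <- if (k == 1L) 0L else cumsum(width(model@exons))[k - 1L]
  prev + (pos - start(model@exons)[k]) + 1L
}

#' Expand the allele set observed at one site
#'
#' Expands every distinct observed state (base, IUPAC code or codon string,
#' \code{NA} ignored) into the plain-base strings consistent with it and
#' returns the union.
#'
#' @param states character vector of per-individual states.
#' @return Sorted character vector of distinct plain alleles.
#' @examples
#' observedAlleles(c("ACG", "ACT", "ACK"))
#' @export
observedAlleles <- function(states) {
  states <- states[!is.na(states)]
  sort(unique(unlist(lapply(unique(states), .expandString))))
}

#' Classify a variant site as synonymous or non-synonymous
#'
#' Expands the observed codon states (codons with a single ambiguity letter
#' expand to the two codons consistent with it; codons with more than one
#' ambiguity position are phase-ambiguous under direct sequencing and are
#' expanded to all consistent codons, with a flag) and compares the encoded
#' residues: the site is non-synonymous iff at least one pair of observed
#' codons translates to different residues.
#'
#' @param codons character vector of observed codon states (3-letter
#'   strings, IUPAC letters allowed; \code{NA} ignored). Single bases are
#'   rejected: intronic sites are classified \code{"intronic"} upstream.
#' @return List: \code{classification} (\code{"synonymous"} or
#'   \code{"non_synonymous"}), \code{codons} (expanded codon set),
#'   \code{residues} (encoded residue set), \code{aaChanges} (character,
#'   e.g. \code{"W->R"}; empty if synonymous), \code{phaseAmbiguous}.
#' @examples
#' classifySite(c("TGG", "CGG"))  # non-synonymous, W->R
#' classifySite(c("GCA", "GCT"))  # synonymous (Ala)
#' @export
classifySite <- function(codons) {
  codons <- codons[!is.na(codons)]
  if (!length(codons)) stop("no codon states supplied")
  if (any(nchar(codons) != 3L))
    stop("codon states must be 3-letter strings")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(codons))
  if (any(bad))
    stop("codon contains a gap or non-IUPAC symbol: '", codons[bad][1L], "'")
  phaseAmbiguous <- any(vapply(codons, function(cd)
    sum(!.chars(cd) %in% c("A", "C", "G", "T")) > 1L, logical(1)))
  expanded <- sort(unique(unlist(lapply(unique(toupper(codons)),
                                        .expandString))))
  residues <- vapply(expanded, .translateCodon, character(1))
  # order residues by how often individuals carry them (major allele first)
  perInd <- unlist(lapply(toupper(codons), function(cd)
    unique(vapply(.expandString(cd), .translateCodon, character(1)))))
  lev <- unique(perInd)
  ures <- lev[order(-tabulate(match(perInd, lev)))]
  if (length(ures) > 1L) {
    changes <- apply(combn(ures, 2L), 2L, paste, collapse = "->")
    list(classification = "non_synonymous", codons = expanded,
         residues = residues, aaChanges = changes,
         phaseAmbiguous = phaseAmbiguous)
  } else {
    list(classification = "synonymous", codons = expanded,
         residues = residues, aaChanges = character(),
         phaseAmbiguous = phaseAmbiguous)
  }
}

#' Annotate every site of a genotype matrix with its classification
#'
#' Intronic rows are classified \code{"intronic"}; exonic rows through
#' \code{\link{classifySite}}. When a \linkS4class{PeptideCoordinateMap} and
#' \linkS4class{GeneModel} are supplied, exonic rows additionally get native
#' and partner-species mature positions (the dual numbering of variant
#' tables such as "100(99)").
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param model optional \linkS4class{GeneModel} (needed for aa positions).
#' @param map optional \linkS4class{PeptideCoordinateMap}.
#' @return The matrix with \code{rowData} columns \code{classification},
#'   \code{aaChange}, \code{phaseAmbiguous} and (when mappable)
#'   \code{aaPositionNative}, \code{aaPositionCross}.
#' @export
classifyVariants <- function(gm, model = NULL, map = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  rd <- SummarizedExperiment::rowData(gm)
  calls <- SummarizedExperiment::assay(gm, "calls")
  n <- nrow(gm)
  cls <- character(n)
  aaChange <- character(n)
  phase <- logical(n)
  for (i in seq_len(n)) {
    if (grepl("^intron", rd$region[i])) {
      cls[i] <- "intronic"
      aaChange[i] <- ""
    } else {
      res <- classifySite(calls[i, ])
      cls[i] <- res$classification
      aaChange[i] <- paste(res$aaChanges, collapse = ",")
      phase[i] <- res$phaseAmbiguous
    }
  }
  rd$classification <- cls
  rd$aaChange <- aaChange
  rd$phaseAmbiguous <- phase
  if (!is.null(model) && !is.null(map)) {
    native <- rep(NA_integer_, n)
    cross <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (grepl("^exon", rd$region[i])) {
        m <- ntToAA(model, map, rd$coordinate[i])
        native[i] <- m$matureSignedPosition
        if (!is.na(native[i]) && native[i] >= 1L &&
            !(native[i] %in% map@crossDeletions))
          cross[i] <- crossSpeciesPosition(map, native[i])
      }
    }
    rd$aaPositionNative <- native
    rd$aaPositionCross <- cross
  }
  SummarizedExperiment::rowData(gm) <- rd
  gm
}

#' Polymorphism density of a genotype matrix
#'
#' The percentage of mutations per sequenced nucleotide, under one of four
#' explicit definitions of numerator and denominator (the quantity is often
#' reported without stating either, so all four are available and the
#' numerator and denominator are returned alongside the percentage):
#' \describe{
#'   \item{\code{sites_per_gene}}{variant sites / gene length (default).}
#'   \item{\code{sites_per_sequenced_nt}}{variant sites / (gene length x
#'     individuals).}
#'   \item{\code{mismatches_per_sequenced_nt}}{allele calls differing from
#'     the matrix consensus, summed over individuals and sites / (gene
#'     length x individuals).}
#'   \item{\code{coding_sites_per_cds}}{exonic variant sites / CDS length.}
#' }
#'
#' @param gm a \linkS4class{GenotypeMatrix} of variant sites.
#' @param geneLength gene (amplicon) length in nt.
#' @param cdsLength CDS length in nt (needed for
#'   \code{coding_sites_per_cds}).
#' @param mode one of the four modes above.
#' @return List: \code{percentage}, \code{numerator}, \code{denominator},
#'   \code{mode}.
#' @examples
#' gm <- GenotypeMatrix(matrix(c("A", "T"), 1, dimnames = list(NULL, c("a", "b"))),
#'                      coordinate = 10, region = "intron_1",
#'                      individuals = c("a", "b"))
#' polymorphismDensity(gm, geneLength = 100)
#' @export
polymorphismDensity <- function(gm, geneLength, cdsLength = NULL,
                                mode = c("sites_per_gene",
                                         "sites_per_sequenced_nt",
                                         "mismatches_per_sequenced_nt",
                                         "coding_sites_per_cds")) {
  stopifnot(is(gm, "GenotypeMatrix"))
  mode <- match.arg(mode)
  calls <- SummarizedExperiment::assay(gm, "calls")
  rd <- SummarizedExperiment::rowData(gm)
  nInd <- ncol(calls)
  nSites <- nrow(calls)
  num <- switch(mode,
    sites_per_gene = nSites,
    sites_per_sequenced_nt = nSites,
    mismatches_per_sequenced_nt = {
      mism <- 0L
      for (i in seq_len(nSites)) {
        states <- calls[i, ]
        states <- states[!is.na(states)]
        consensus <- names(sort(table(states), decreasing = TRUE))[1L]
        mism <- mism + sum(states != consensus)
      }
      mism
    },
    coding_sites_per_cds = sum(grepl("^exon", rd$region)))
  den <- switch(mode,
    sites_per_gene = geneLength,
    sites_per_sequenced_nt = geneLength * nInd,
    mismatches_per_sequenced_nt = geneLength * nInd,
    coding_sites_per_cds = {
      if (is.null(cdsLength)) stop("cdsLength required for this mode")
      cdsLength
    })
  if (is.null(den) || den == 0) stop("zero denominator")
  list(percentage = 100 * num / den, numerator = num, denominator = den,
       mode = mode)
}

#' All four polymorphism-density definitions at once
#'
#' @inheritParams polymorphismDensity
#' @return \code{DataFrame} with one row per mode.
#' @export
polymorphismDensityTable <- function(gm, geneLength, cdsLength = NULL) {
  modes <- c("sites_per_gene", "sites_per_sequenced_nt",
             "mismatches_per_sequenced_nt")
  if (!is.null(cdsLength)) modes <- c(modes, "coding_sites_per_cds")
  rows <- lapply(modes, function(m) {
    d <- polymorphismDensity(gm, geneLength, cdsLength, mode = m)
    DataFrame(mode = m, numerator = d$numerator,
              denominator = d$denominator, percentage = d$percentage)
  })
  do.call(rbind, rows)
}
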