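#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
NULL

# ---------------------------------------------------------------------------
# reference gene
# ---------------------------------------------------------------------------

#' Generate a reference gene with known exon/intron structure
#'
#' Builds a genomic amplicon from a \linkS4class{GeneSpec}: a CDS with an ATG
#' start, no internal stop codon and a terminal stop, cut into exons, with
#' canonical GT..AG introns between them. The cDNA equals the concatenated
#' exons by construction, so the returned model is the ground truth for
#' \code{\link{inferGeneModel}}. Intron interiors are resampled where
#' necessary so that no intron admits an alternative equal-scoring canonical
#' placement (junction shifts), keeping the true model uniquely recoverable.
#' Deterministic for a fixed \code{spec@seed}.
#'
#' @param spec a \linkS4class{GeneSpec}.
#' @return List with elements \code{genomic} (\code{DNAString}),
#'   \code{cdna} (\code{DNAString}), \code{model}
#'   (\linkS4class{GeneModel}) and \code{polyT} (NULL, or the 1-based
#'   genomic interval of the reference poly-T tract).
#' @examples
#' g <- makeReferenceGene(geneSpec(c(9, 9), 30, seed = 1))
#' g$model
#' @export
makeReferenceGene <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    cds <- .randomCDS(sum(spec@exonLengths), spec@gcFraction)
    exL <- spec@exonLengths
    inL <- spec@intronLengths
    exEnd <- cumsum(exL)
    exStart <- exEnd - exL + 1L
    exonSeq <- lapply(seq_along(exL), function(i)
      substr(cds, exStart[i], exEnd[i]))
    polyT <- NULL
    intronSeq <- lapply(seq_along(inL), function(i) {
      s <- .randomIntron(inL[i], spec@gcFraction)
      if (spec@polyTIntron == i) {
        tract <- max(spec@polyTRange)
        # embed the reference-length tract mid-intron, clear of GT/AG
        at <- 3L + (inL[i] - 4L - tract) %/% 2L
        substr(s, at + 1L, at + tract) <- strrep("T", tract)
        polyT <<- c(offset = at)  # offset within intron, resolved below
      }
      s
    })
    pieces <- character(2L * length(exL) - 1L)
    pieces[seq(1L, by = 2L, length.out = length(exL))] <- unlist(exonSeq)
    if (length(inL))
      pieces[seq(2L, by = 2L, length.out = length(inL))] <- unlist(intronSeq)
    genomic <- .collapse(pieces)
    gStart <- integer(length(exL))
    off <- 0L
    for (i in seq_along(exL)) {
      gStart[i] <- off + 1L
      off <- off + exL[i] + if (i <= length(inL)) inL[i] else 0L
    }
    model <- GeneModel(gStart, gStart + exL - 1L, genomic,
                       cdnaAnchor = "synthetic_cdna", seqid = "synthetic_gene")
    genomic <- .breakJunctionAmbiguity(genomic, model, spec@gcFraction)
    if (!is.null(polyT)) {
      is <- start(model@introns)[spec@polyTIntron]
      polyT <- c(start = is + polyT[["offset"]],
                 end = is + polyT[["offset"]] + max(spec@polyTRange) - 1L)
    }
    list(genomic = DNAString(genomic), cdna = DNAString(cds),
         model = model, polyT = polyT)
  })
}

# CDS of length n (multiple of 3): ATG + non-stop codons + stop
.randomCDS <- function(n, gc) {
  ncod <- n %/% 3L - 2L
  codons <- character(ncod)
  i <- 1L
  while (i <= ncod) {
    cod <- .collapse(.sampleBases(3L, gc))
    if (!(cod %in% .STOP_CODONS)) {
      codons[i] <- cod
      i <- i + 1L
    }
  }
  paste0("ATG", .collapse(codons), sample(.STOP_CODONS, 1L))
}

.randomIntron <- function(len, gc) {
  paste0("GT", .collapse(.sampleBases(len - 4L, gc)), "AG")
}

# An intron placement can be shifted by k while preserving the exon
# concatenation iff the k bases before the intron equal its last k bases
# (left shift) or the k bases after it equal its first k (right shift).
# Such a shifted placement ties the true one in score only when it is also
# GT..AG; resample the offending interior base to remove the tie.
.breakJunctionAmbiguity <- function(genomic, model, gc) {
  g <- .chars(genomic)
  for (i in seq_along(model@introns)) {
    s <- start(model@introns)[i]
    e <- end(model@introns)[i]
    repeat {
      amb <- FALSE
      maxk <- min(20L, e - s - 3L)
      for (k in seq_len(maxk)) {
        # left shift by k: new intron (s-k, e-k)
        if (s - k >= 1L &&
            identical(g[(s - k):(s - 1L)], g[(e - k + 1L):e]) &&
            g[s - k] == "G" && g[s - k + 1L] == "T" &&
            g[e - k - 1L] == "A" && g[e - k] == "G") {
          g[e - k] <- sample(setdiff(c("A", "C", "T"), g[e - k]), 1L)
          amb <- TRUE; break
        }
        # right shift by k: new intron (s+k, e+k)
        if (e + k <= length(g) &&
            identical(g[(e + 1L):(e + k)], g[s:(s + k - 1L)]) &&
            g[s + k] == "G" && g[s + k + 1L] == "T" &&
            g[e + k - 1L] == "A" && g[e + k] == "G") {
          g[s + k] <- sample(setdiff(c("A", "C", "T"), g[s + k]), 1L)
          amb <- TRUE; break
        }
      }
      if (!amb) break
    }
  }
  .collapse(g)
}

# ---------------------------------------------------------------------------
# diploid population
# ---------------------------------------------------------------------------

#' Generate a diploid population from two haplotypes
#'
#' Plants \code{pop@nDiagnosticSites} biallelic sites on the reference gene
#' (avoiding the start and stop codons, splice dinucleotides and any poly-T
#' tract), defining haplotype H2 against the reference haplotype H1. Each
#' individual draws two haplotypes independently with
#' \eqn{P(H1) = p}, giving Hardy-Weinberg diplotype proportions, plus a
#' Poisson(\code{singletonRate}) number of private heterozygous mutations.
#' Individuals are rendered as Sanger-style consensus sequences: homozygous
#' positions as plain bases, heterozygous positions as the two-base IUPAC
#' code. With a poly-T intron, each individual draws one tract length
#' uniformly from the spec range (both chromosome copies alike), so sequence
#' lengths vary across the population.
#'
#' @param gene result of \code{\link{makeReferenceGene}} (or a list with
#'   \code{genomic}, \code{model} and optionally \code{polyT}).
#' @param pop a \linkS4class{PopulationSpec}.
#' @param polyTRange optional length-2 integer range for the per-individual
#'   poly-T draw; defaults to the tract length of the reference.
#' @return List with \code{consensus} (\code{DNAStringSet}, one record per
#'   individual), \code{truth} (\code{DataFrame}: individual, diplotype,
#'   private mutations as \code{"site:allele"} strings, poly-T length),
#'   \code{sites} (\code{DataFrame}: coordinate, h1 and h2 alleles) and
#'   \code{h1}/\code{h2} haplotype sequences.
#' @examples
#' g <- makeReferenceGene(geneSpec(c(60, 60), 40, seed = 1))
#' p <- makePopulation(g, populationSpec(nIndividuals = 4, seed = 2))
#' p$truth
#' @export
makePopulation <- function(gene, pop, polyTRange = NULL) {
  validObject(pop)
  genomic <- .chars(gene$genomic)
  model <- gene$model
  n <- length(genomic)
  withSeed(pop@seed, {
    forbidden <- .forbiddenPositions(model, n, gene$polyT)
    candidates <- setdiff(seq_len(n), forbidden)
    if (length(candidates) < pop@nDiagnosticSites)
      stop("gene too small for the requested number of diagnostic sites")
    # diagnostic sites fall at distinct coordinates and in distinct codons
    # (a codon carrying two heterozygous sites cannot be phased from a
    # consensus sequence, and its codon call would not be biallelic)
    sites <- integer(0)
    usedCodons <- integer(0)
    pool <- sample(candidates)
    for (s in pool) {
      if (length(sites) >= pop@nDiagnosticSites) break
      cp <- .genomicToCds(gene$model, s)
      codon <- if (is.na(cp)) -s else (cp - 1L) %/% 3L
      if (!is.na(cp) && codon %in% usedCodons) next
      sites <- c(sites, s)
      usedCodons <- c(usedCodons, codon)
    }
    if (length(sites) < pop@nDiagnosticSites)
      stop("gene too small for the requested number of diagnostic sites")
    sites <- sort(sites)
    h1 <- genomic
    h2 <- genomic
    for (s in sites)
      h2[s] <- sample(setdiff(c("A", "C", "G", "T"), h1[s]), 1L)

    ids <- sprintf("ind%02d", seq_len(pop@nIndividuals))
    copyA <- rbinom(pop@nIndividuals, 1L, pop@h1Frequency)  # 1 = H1
    copyB <- rbinom(pop@nIndividuals, 1L, pop@h1Frequency)
    diplo <- ifelse(copyA + copyB == 2L, "H1/H1",
                    ifelse(copyA + copyB == 0L, "H2/H2", "H1/H2"))

    # keep private mutations out of the diagnostic sites' codons, so a
    # diagnostic codon stays biallelic across the population
    diagCodon <- unlist(lapply(sites, function(s) {
      cp <- .genomicToCds(gene$model, s)
      if (is.na(cp)) return(s)
      .cdsToGenomic(gene$model, cp - (cp - 1L) %% 3L + 0:2)
    }))
    privateCandidates <- setdiff(candidates, diagCodon)
    if (pop@silentOnly)
      privateCandidates <- intersect(privateCandidates,
                                     .thirdPositions(model, n))
    consensus <- character(pop@nIndividuals)
    privates <- character(pop@nIndividuals)
    polyTLen <- rep(NA_integer_, pop@nIndividuals)
    for (i in seq_len(pop@nIndividuals)) {
      a <- if (copyA[i] == 1L) h1 else h2
      b <- if (copyB[i] == 1L) h1 else h2
      nPriv <- rpois(1L, pop@singletonRate)
      privList <- character(0)
      if (nPriv > 0L && length(privateCandidates)) {
        pos <- sample(privateCandidates, min(nPriv, length(privateCandidates)))
        for (s in pos) {
          alt <- if (pop@silentOnly)
            .silentAlternative(a, model, s) else
              sample(setdiff(c("A", "C", "G", "T"), a[s]), 1L)
          if (is.na(alt)) next
          a[s] <- alt  # private mutations ride on one chromosome copy
          privList <- c(privList, paste0(s, ":", alt))
        }
      }
      privates[i] <- paste(privList, collapse = ";")
      cons <- a
      het <- which(a != b)
      for (s in het) cons[s] <- iupacCode(c(a[s], b[s]))
      if (!is.null(gene$polyT)) {
        rng <- if (is.null(polyTRange))
          c(gene$polyT[["end"]] - gene$polyT[["start"]] + 1L,
            gene$polyT[["end"]] - gene$polyT[["start"]] + 1L) else polyTRange
        polyTLen[i] <- sample(seq(rng[1L], rng[2L]), 1L)
        cons <- c(cons[seq_len(gene$polyT[["start"]] - 1L)],
                  rep("T", polyTLen[i]),
                  cons[seq(gene$polyT[["end"]] + 1L, length(cons))])
      }
      consensus[i] <- .collapse(cons)
    }
    truth <- DataFrame(individual = ids, diplotype = diplo,
                       privates = privates, polyTLength = polyTLen)
    siteTab <- DataFrame(coordinate = sites,
                         h1 = h1[sites], h2 = h2[sites])
    list(consensus = setNames(DNAStringSet(consensus), ids),
         truth = truth, sites = siteTab,
         h1 = .collapse(h1), h2 = .collapse(h2))
  })
}

# positions where a planted polymorphism would break gene structure
.forbiddenPositions <- function(model, n, polyT = NULL) {
  ex <- model@exons
  cdsLen <- sum(width(ex))
  startCodon <- .cdsToGenomic(model, 1:3)
  stopCodon <- .cdsToGenomic(model, (cdsLen - 2L):cdsLen)
  splice <- integer()
  for (i in seq_along(model@introns)) {
    s <- start(model@introns)[i]; e <- end(model@introns)[i]
    splice <- c(splice, s, s + 1L, e - 1L, e)
  }
  pt <- if (!is.null(polyT))
    seq(polyT[["start"]] - 1L, polyT[["end"]] + 1L) else integer()
  unique(c(startCodon, stopCodon, splice, pt))
}

# genomic coordinates of given CDS positions
.cdsToGenomic <- function(model, cdsPos) {
  exStart <- start(model@exons)
  exW <- width(model@exons)
  cumW <- cumsum(exW)
  vapply(cdsPos, function(p) {
    k <- which(p <= cumW)[1L]
    prev <- if (k == 1L) 0L else cumW[k - 1L]
    exStart[k] + (p - prev) - 1L
  }, integer(1))
}

# genomic positions that are third codon positions
.thirdPositions <- function(model, n) {
  cdsLen <- sum(width(model@exons))
  .cdsToGenomic(model, seq(3L, cdsLen, by = 3L))
}

# synonymous alternative base at genomic position s (third codon positions
# only); NA if none exists
.silentAlternative <- function(hap, model, s) {
  exStart <- start(model@exons); exEnd <- end(model@exons)
  k <- which(s >= exStart & s <= exEnd)
  if (length(k) != 1L) return(NA_character_)
  cumW <- cumsum(width(model@exons))
  prev <- if (k == 1L) 0L else cumW[k - 1L]
  cdsPos <- prev + (s - exStart[k]) + 1L
  if (cdsPos %% 3L != 0L) return(NA_character_)
  codonPos <- .cdsToGenomic(model, (cdsPos - 2L):cdsPos)
  codon <- hap[codonPos]
  aa <- .translateCodon(.collapse(codon))
  alts <- setdiff(c("A", "C", "G", "T"), codon[3L])
  syn <- alts[vapply(alts, function(b)
    .translateCodon(.collapse(c(codon[1:2], b))) == aa, logical(1))]
  if (length(syn)) sample(syn, 1L) else NA_character_
}

# ---------------------------------------------------------------------------
# homolog family
# ---------------------------------------------------------------------------

#' Generate a family of divergent protein homologs
#'
#' Derives \code{nTaxa} homologs from a reference protein by substituting a
#' controlled fraction of residues; positions in \code{constrainedSites} are
#' never mutated, so conservation can be planted at, for example, epitope
#' positions.
#'
#' @param referenceProtein character or \code{AAString}.
#' @param nTaxa number of derived taxa.
#' @param divergence numeric vector (length 1 or \code{nTaxa}) of target
#'   per-taxon divergences from the reference, in \code{[0, 1]}.
#' @param constrainedSites integer positions never mutated.
#' @param seed integer seed.
#' @param taxa optional names for the derived taxa.
#' @return \code{AAStringSet} of \code{nTaxa + 1} sequences, the reference
#'   (named \code{"reference"} unless it has a name) first.
#' @examples
#' fam <- makeHomologFamily(strrep("ACDEFGHIKL", 4), 3, c(0, 0.1, 0.3),
#'                          constrainedSites = 1:5, seed = 1)
#' @export
makeHomologFamily <- function(referenceProtein, nTaxa,
                              divergence, constrainedSites = integer(),
                              seed = 1L, taxa = NULL) {
  ref <- .chars(referenceProtein)
  L <- length(ref)
  divergence <- rep_len(divergence, nTaxa)
  if (any(divergence < 0 | divergence > 1))
    stop("divergence must lie in [0, 1]")
  constrainedSites <- as.integer(constrainedSites)
  if (length(constrainedSites) && any(constrainedSites < 1L | constrainedSites > L))
    stop("constrainedSites outside the protein")
  mutable <- setdiff(seq_len(L), constrainedSites)
  nmut <- round(divergence * L)
  if (any(nmut > length(mutable)))
    stop("divergence target unsatisfiable under the site constraints")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withSeed(seed, {
    seqs <- vapply(seq_len(nTaxa), function(i) {
      s <- ref
      if (nmut[i] > 0L) {
        pos <- sample(mutable, nmut[i])
        for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1L)
      }
      .collapse(s)
    }, character(1))
    nm <- if (is.null(taxa)) sprintf("taxon%02d", seq_len(nTaxa)) else taxa
    out <- AAStringSet(c(.collapse(ref), seqs))
    names(out) <- c("reference", nm)
    out
  })
}
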