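# a state string is homozygous iff it contains no ambiguity letter
.isHomozygousState <- function(x) !is.na(x) & !grepl("[RYSWKMBDHVN]", x)

#' Find diagnostic sites of a genotype matrix
#'
#' Diagnostic sites are the biallelic sites at which both alleles are
#' observed in homozygous state and the minor allele is carried by at least
#' two individuals; they define the recurring haplotypes. Singleton/private
#' sites (minor allele in a single individual) are excluded.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return Integer vector of site coordinates (possibly empty).
#' @export
findDiagnosticSites <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (ncol(gm) < 2L) stop("need at least two individuals")
  calls <- SummarizedExperiment::assay(gm, "calls")
  rd <- SummarizedExperiment::rowData(gm)
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    states <- calls[i, ]
    states <- states[!is.na(states)]
    alleles <- observedAlleles(states)
    if (length(alleles) != 2L) return(FALSE)
    hom <- states[.isHomozygousState(states)]
    if (!all(alleles %in% hom)) return(FALSE)
    carriers <- vapply(alleles, function(a)
      sum(vapply(states, function(s) a %in% .expandString(s), logical(1))),
      integer(1))
    min(carriers) >= 2L
  }, logical(1))
  rd$coordinate[keep]
}

#' Resolve the two-haplotype structure of a diploid population
#'
#' Clark-style phasing restricted to a two-haplotype model: homozygous
#' individuals (no ambiguity letter at any diagnostic site) define candidate
#' haplotypes; near-identical homozygote patterns (within
#' \code{tolerance} mismatching sites) are clustered together, and more than
#' two resulting clusters is an error. H1 is the haplotype with the larger
#' homozygote count (ties towards the lexicographically smaller allele
#' vector). Every individual is then assigned the diplotype (H1/H1, H2/H2
#' or H1/H2) whose expected consensus state — the site-wise IUPAC union of
#' the two haplotypes — matches its observed states best; individuals with
#' more than \code{tolerance} mismatches are marked \code{"inconsistent"}
#' with their mismatch sites listed, and matches with 1..\code{tolerance}
#' mismatches are assigned with a warning flag.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param diagnosticSites integer coordinates, typically from
#'   \code{\link{findDiagnosticSites}}; must be non-empty.
#' @param tolerance maximum mismatching sites for an assignment (default 1).
#' @return A \linkS4class{HaplotypePair}.
#' @export
phaseTwoHaplotypes <- function(gm, diagnosticSites, tolerance = 1L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (length(diagnosticSites) == 0L) stop("diagnosticSites is empty")
  rd <- SummarizedExperiment::rowData(gm)
  rows <- match(diagnosticSites, rd$coordinate)
  if (anyNA(rows)) stop("diagnostic site(s) not in the matrix: ",
                        paste(diagnosticSites[is.na(rows)], collapse = ", "))
  calls <- SummarizedExperiment::assay(gm, "calls")[rows, , drop = FALSE]
  sites <- as.integer(diagnosticSites)
  ids <- colnames(calls)
  nS <- length(sites)

  homIdx <- which(apply(calls, 2L, function(x) all(.isHomozygousState(x))))
  if (!length(homIdx))
    stop("no fully homozygous individual; candidate haplotypes undefined")
  patterns <- apply(calls[, homIdx, drop = FALSE], 2L, paste, collapse = "|")
  patTab <- sort(table(patterns), decreasing = TRUE)
  patKey <- names(patTab)
  # cluster homozygote patterns: walk in decreasing frequency, attach a
  # pattern to an existing cluster when within tolerance
  clusters <- list()
  for (pk in patKey) {
    vec <- strsplit(pk, "|", fixed = TRUE)[[1L]]
    attached <- FALSE
    for (ci in seq_along(clusters)) {
      if (sum(vec != clusters[[ci]]$seedVec) <= tolerance) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members,
                                    homIdx[patterns == pk])
        attached <- TRUE
        break
      }
    }
    if (!attached)
      clusters[[length(clusters) + 1L]] <- list(seedVec = vec,
                                                members = homIdx[patterns == pk])
  }
  if (length(clusters) > 2L) {
    third <- paste(clusters[[3L]]$seedVec, collapse = "|")
    stop("exceeds two-haplotype model: third homozygote pattern '", third, "'")
  }
  # cluster haplotype: site-wise majority over member individuals
  hapOf <- function(cl) {
    m <- calls[, cl$members, drop = FALSE]
    apply(m, 1L, function(x) names(sort(table(x), decreasing = TRUE))[1L])
  }
  hA <- hapOf(clusters[[1L]])
  nA <- length(clusters[[1L]]$members)
  if (length(clusters) == 2L) {
    hB <- hapOf(clusters[[2L]])
    nB <- length(clusters[[2L]]$members)
  } else {
    # only one homozygote pattern: if heterozygotes exist, peel the known
    # haplotype from the modal heterozygote pattern (Clark-style) to get
    # the second candidate; otherwise the population is monomorphic
    hetIdx <- setdiff(seq_along(ids), homIdx)
    if (length(hetIdx)) {
      partners <- vapply(hetIdx, function(j)
        paste(vapply(seq_len(nS), function(i)
          .peelPartner(calls[i, j], hA[i]), character(1)), collapse = "|"),
        character(1))
      modal <- names(sort(table(partners), decreasing = TRUE))[1L]
      hB <- strsplit(modal, "|", fixed = TRUE)[[1L]]
    } else {
      hB <- hA
    }
    nB <- 0L
  }
  swap <- nB > nA || (nB == nA && .collapse(hB) < .collapse(hA))
  h1 <- if (swap) hB else hA
  h2 <- if (swap) hA else hB
  names(h1) <- names(h2) <- as.character(sites)

  hetExpected <- vapply(seq_len(nS), function(i)
    .unionState(h1[i], h2[i]), character(1))
  expected <- list("H1/H1" = unname(h1), "H2/H2" = unname(h2),
                   "H1/H2" = hetExpected)
  diplo <- character(length(ids))
  nMis <- integer(length(ids))
  misSites <- character(length(ids))
  flagged <- logical(length(ids))
  for (j in seq_along(ids)) {
    obs <- calls[, j]
    mism <- vapply(expected, function(e) sum(obs != e, na.rm = TRUE),
                   integer(1))
    best <- which.min(mism)  # ties resolve in H1/H1, H2/H2, H1/H2 order
    if (mism[best] <= tolerance) {
      diplo[j] <- names(expected)[best]
      flagged[j] <- mism[best] > 0L
    } else {
      diplo[j] <- "inconsistent"
    }
    nMis[j] <- mism[best]
    bad <- which(obs != expected[[best]])
    misSites[j] <- paste(sites[bad], collapse = ";")
  }
  assign <- DataFrame(individual = ids, diplotype = diplo,
                      nMismatch = nMis, mismatchSites = misSites,
                      flagged = flagged,
                      consistency = 1 - nMis / nS,
                      row.names = ids)
  new("HaplotypePair", h1 = h1, h2 = h2, assignments = assign, sites = sites)
}

# partner allele string implied by a heterozygous observation given one
# known haplotype allele: at each position, remove the known base from the
# observed expansion; unpeelable positions keep the observed character
.peelPartner <- function(obs, known) {
  co <- .chars(obs); ck <- .chars(known)
  .collapse(vapply(seq_along(co), function(i) {
    if (co[i] == ck[i]) return(ck[i])
    exp <- expandIUPAC(co[i])
    rest <- setdiff(exp, expandIUPAC(ck[i]))
    if (length(rest) == 1L) rest else co[i]
  }, character(1)))
}

# consensus state of a heterozygote carrying the two allele strings:
# per-position IUPAC union
.unionState <- function(a, b) {
  ca <- .chars(a); cb <- .chars(b)
  if (length(ca) != length(cb)) stop("allele strings of unequal length")
  .collapse(vapply(seq_along(ca), function(i) {
    if (ca[i] == cb[i]) ca[i] else
      iupacCode(c(expandIUPAC(ca[i]), expandIUPAC(cb[i])))
  }, character(1)))
}

#' Diplotype and allele frequencies of a phased population
#'
#' @param pair a \linkS4class{HaplotypePair}.
#' @return List: \code{counts} and \code{percentages} (named: H1/H1, H2/H2,
#'   H1/H2, inconsistent), \code{n}, and \code{h1AlleleFrequency}
#'   \eqn{= (2 n_{H1/H1} + n_{het}) / (2 n_{consistent})}.
#' @export
haplotypeFrequencies <- function(pair) {
  stopifnot(is(pair, "HaplotypePair"))
  lv <- c("H1/H1", "H2/H2", "H1/H2", "inconsistent")
  counts <- table(factor(pair@assignments$diplotype, levels = lv))
  n <- sum(counts)
  consistent <- sum(counts[c("H1/H1", "H2/H2", "H1/H2")])
  p <- if (consistent > 0)
    (2 * counts[["H1/H1"]] + counts[["H1/H2"]]) / (2 * consistent) else NA_real_
  list(counts = setNames(as.integer(counts), lv),
       percentages = setNames(100 * as.numeric(counts) / n, lv),
       n = n,
       h1AlleleFrequency = p)
}
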