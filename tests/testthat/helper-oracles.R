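# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / textbook recursions, sharing no code with the
# package internals they check.

# -- spliced decomposition ---------------------------------------------------

# score a decomposition under the documented convention:
# match +1, mismatch -1, intron opening -8, +4 if the intron is GT..AG
oracleScoreDecomposition <- function(g, cd, starts, ends) {
  gch <- strsplit(g, "")[[1]]
  cch <- strsplit(cd, "")[[1]]
  keep <- rep(TRUE, nchar(g))
  score <- 0
  for (k in seq_along(starts)) {
    keep[starts[k]:ends[k]] <- FALSE
    score <- score - 8
    if (gch[starts[k]] == "G" && gch[starts[k] + 1] == "T" &&
        gch[ends[k] - 1] == "A" && gch[ends[k]] == "G")
      score <- score + 4
  }
  ex <- gch[keep]
  if (length(ex) != length(cch)) return(NA_real_)
  score + sum(ex == cch) - sum(ex != cch)
}

# exhaustively enumerate all decompositions with at most two introns
# (each >= minIntron, flanked by non-empty exons); returns the list of
# decompositions achieving the maximum score
oracleBestDecompositions <- function(g, cd, minIntron) {
  n <- nchar(g); m <- nchar(cd)
  D <- n - m
  best <- -Inf
  argmax <- list()
  consider <- function(starts, ends) {
    sc <- oracleScoreDecomposition(g, cd, starts, ends)
    if (is.na(sc)) return()
    if (sc > best + 1e-9) {
      best <<- sc
      argmax <<- list(list(starts = starts, ends = ends, score = sc))
    } else if (abs(sc - best) < 1e-9) {
      argmax[[length(argmax) + 1]] <<- list(starts = starts, ends = ends,
                                            score = sc)
    }
  }
  if (D == 0) consider(integer(0), integer(0))
  if (D >= minIntron) {
    for (s in 2:(n - D)) consider(s, s + D - 1)  # exons non-empty both sides
  }
  if (D >= 2 * minIntron) {
    for (l1 in minIntron:(D - minIntron)) {
      l2 <- D - l1
      for (s1 in 2:(n - D)) {
        e1 <- s1 + l1 - 1
        for (s2 in (e1 + 2):(n - l2)) {  # at least one exon nt between
          consider(c(s1, s2), c(e1, s2 + l2 - 1))
        }
      }
    }
  }
  list(score = best, argmax = argmax)
}

# -- global affine alignment -------------------------------------------------

# textbook Gotoh three-state recursion; the first gap residue costs `open`,
# each further residue `ext`; terminal gaps are penalised
oracleAffineScore <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # gap in b
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1, 1] <- -open - (i - 1) * ext
  for (j in seq_len(lb)) Y[1, j + 1] <- -open - (j - 1) * ext
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub[A[i], B[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext)
  }
  max(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# -- translation -------------------------------------------------------------

# codon -> residue via seqinr (independent code path from the package)
oracleTranslateCodon <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], ambiguous = FALSE)
}

allCodons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               c("A", "C", "G", "T"),
                               stringsAsFactors = FALSE),
                   1, paste0, collapse = "")

# -- misc --------------------------------------------------------------------

randomCds <- function(nCodons) {
  stops <- c("TAA", "TAG", "TGA")
  body <- character(nCodons)
  i <- 1
  while (i <= nCodons) {
    cod <- paste0(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
    if (!(cod %in% stops)) { body[i] <- cod; i <- i + 1 }
  }
  paste0("ATG", paste0(body, collapse = ""), sample(stops, 1))
}

stripGaps <- function(x) gsub("-", "", as.character(x), fixed = TRUE)

# gauge-fix haplotype labels against the generator truth: the phaser labels
# the commoner homozygote H1, which at intermediate frequencies can be
# either planted haplotype
alignDiplotypes <- function(got, truth) {
  swap <- c("H1/H1" = "H2/H2", "H2/H2" = "H1/H1", "H1/H2" = "H1/H2",
            "inconsistent" = "inconsistent")
  swapped <- sum(got == truth) < sum(unname(swap[got]) == truth)
  list(diplotypes = if (swapped) unname(swap[got]) else got,
       swapped = swapped)
}

# does either side of any internal-edge bipartition equal `tips`?
hasSplit <- function(tree, tips) {
  all_tips <- sort(tree$tip.label)
  tips <- sort(tips)
  comp <- setdiff(all_tips, tips)
  any(vapply(treeSplits(tree), function(s)
    identical(s, tips) || identical(s, sort(comp)), logical(1)))
}
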