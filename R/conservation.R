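.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.ALPHA <- c(.AA20, "-")

# Clustal residue groups used for the ':' / '.' column symbols
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")

# BLOSUM62 over .ALPHA, gap row/column zero
.substitutionMatrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()))
    m <- matrix(0, length(.ALPHA), length(.ALPHA),
                dimnames = list(.ALPHA, .ALPHA))
    m[.AA20, .AA20] <- b62[.AA20, .AA20]
    cache <<- m
    m
  }
})

.checkProteins <- function(seqs) {
  s <- .upperNamed(seqs)
  if (length(s) < 2L) stop("need at least two sequences")
  if (any(nchar(s) == 0L)) stop("empty sequence")
  bad <- grepl(paste0("[^", .collapse(.AA20), "]"), s)
  if (any(bad))
    stop("non-standard residue in sequence ",
         if (!is.null(names(s))) names(s)[bad][1L] else which(bad)[1L])
  if (is.null(names(s))) names(s) <- sprintf("seq%02d", seq_along(s))
  s
}

# one column-frequency profile (alphabet x columns) per alignment row set
.profileOf <- function(rows) {
  L <- nchar(rows[1L])
  m <- matrix(0, length(.ALPHA), L, dimnames = list(.ALPHA, NULL))
  for (r in rows) {
    ch <- .chars(r)
    for (j in seq_len(L)) m[ch[j], j] <- m[ch[j], j] + 1
  }
  m / length(rows)
}

.mergeByPath <- function(rowsA, rowsB, path) {
  chA <- lapply(rowsA, .chars)
  chB <- lapply(rowsB, .chars)
  la <- 0L; lb <- 0L
  outA <- vector("list", length(path)); outB <- vector("list", length(path))
  ia <- 0L; ib <- 0L
  colsA <- character(length(path)); colsB <- character(length(path))
  resA <- matrix("-", length(rowsA), length(path))
  resB <- matrix("-", length(rowsB), length(path))
  for (k in seq_along(path)) {
    if (path[k] != 3L) { ia <- ia + 1L
      for (r in seq_along(chA)) resA[r, k] <- chA[[r]][ia] }
    if (path[k] != 2L) { ib <- ib + 1L
      for (r in seq_along(chB)) resB[r, k] <- chB[[r]][ib] }
  }
  c(apply(resA, 1L, .collapse), apply(resB, 1L, .collapse))
}

#' Progressive multiple alignment of protein sequences
#'
#' Deterministic progressive alignment: all pairwise global alignments
#' (affine gaps, BLOSUM62, gap open 10, extension 0.5) give a distance
#' matrix (1 - fractional identity); a UPGMA guide tree orders profile
#' merges; each merge is a global profile-profile alignment under the same
#' scoring. Removing gaps from any output row recovers the input sequence
#' exactly.
#'
#' @param sequences named \code{AAStringSet} or character vector (>= 2).
#' @param gapOpen,gapExtension affine gap penalties.
#' @return \code{AAStringSet} of equal-length gapped rows, in input order.
#' @examples
#' alignProteins(c(a = "HEAGAWGHEE", b = "PAWHEAE"))
#' @export
alignProteins <- function(sequences, gapOpen = 10, gapExtension = 0.5) {
  s <- .checkProteins(sequences)
  n <- length(s)
  sub <- .substitutionMatrix()
  profiles <- lapply(s, function(x) .profileOf(x))
  pairAln <- function(a, b) cpp_profile_align(a, b, sub, gapOpen, gapExtension)
  if (n == 2L) {
    merged <- .mergeByPath(s[1L], s[2L], pairAln(profiles[[1L]],
                                                 profiles[[2L]])$path)
    return(setNames(AAStringSet(merged), names(s)))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    merged <- .mergeByPath(s[i], s[j], pairAln(profiles[[i]],
                                               profiles[[j]])$path)
    ci <- .chars(merged[1L]); cj <- .chars(merged[2L])
    comp <- ci != "-" & cj != "-"
    id <- if (any(comp)) mean(ci[comp] == cj[comp]) else 0
    D[i, j] <- D[j, i] <- 1 - id
  }
  hc <- hclust(as.dist(D), method = "average")
  # walk the merge table; clusters hold gapped rows + their member indices
  nodes <- vector("list", nrow(hc$merge))
  getCluster <- function(k) {
    if (k < 0L) list(rows = s[-k], members = -k) else nodes[[k]]
  }
  for (step in seq_len(nrow(hc$merge))) {
    a <- getCluster(hc$merge[step, 1L])
    b <- getCluster(hc$merge[step, 2L])
    path <- pairAln(.profileOf(a$rows), .profileOf(b$rows))$path
    nodes[[step]] <- list(rows = .mergeByPath(a$rows, b$rows, path),
                          members = c(a$members, b$members))
  }
  final <- nodes[[nrow(hc$merge)]]
  out <- final$rows[order(final$members)]
  setNames(AAStringSet(out), names(s))
}

#' Pairwise percent identity of an alignment
#'
#' For each pair of rows: 100 x identical columns / columns in which
#' neither row has a gap. A pair with no comparable column gets \code{NA}
#' with a warning.
#'
#' @param alignment equal-length gapped sequences (\code{AAStringSet} or
#'   character).
#' @return An \linkS4class{IdentityMatrix}.
#' @examples
#' percentIdentity(c(a = "AAAA", b = "AAAT"))
#' @export
percentIdentity <- function(alignment) {
  s <- .upperNamed(alignment)
  if (length(unique(nchar(s))) != 1L) stop("rows have unequal lengths")
  nm <- names(s)
  if (is.null(nm)) nm <- sprintf("seq%02d", seq_along(s))
  n <- length(s)
  ch <- lapply(s, .chars)
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    comp <- ch[[i]] != "-" & ch[[j]] != "-"
    if (!any(comp)) {
      warning("no comparable columns for pair ", nm[i], "/", nm[j])
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      m[i, j] <- m[j, i] <- 100 * mean(ch[[i]][comp] == ch[[j]][comp])
    }
  }
  identityMatrix(m)
}

#' Clustal-style column conservation symbols
#'
#' Per alignment column: \code{"*"} if all residues are identical and no
#' row has a gap; \code{":"} if all residues (no gap) belong to one strong
#' Clustal group; \code{"."} if all belong to one weak group; \code{" "}
#' otherwise.
#'
#' @param alignment equal-length gapped sequences.
#' @return Character vector of one symbol per column (collapsed string in
#'   attribute \code{"line"}).
#' @examples
#' columnConservation(c("GIV", "GLV", "GVV"))
#' @export
columnConservation <- function(alignment) {
  s <- .upperNamed(alignment)
  if (length(unique(nchar(s))) != 1L) stop("rows have unequal lengths")
  mat <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  inOneGroup <- function(res, groups) {
    any(vapply(groups, function(g)
      all(res %in% strsplit(g, "")[[1]]), logical(1)))
  }
  sym <- apply(mat, 2L, function(col) {
    if (any(col == "-")) return(" ")
    u <- unique(col)
    if (length(u) == 1L) return("*")
    if (inOneGroup(u, .STRONG_GROUPS)) return(":")
    if (inOneGroup(u, .WEAK_GROUPS)) return(".")
    " "
  })
  attr(sym, "line") <- .collapse(sym)
  sym
}

#' Epitope identity score
#'
#' Fraction of epitope residues conserved in a query relative to the
#' reference, as a percentage rounded half-up to 2 decimals.
#'
#' Two input forms are supported. (a) A residue-state matrix (rows = taxa,
#' columns = epitope positions, entries single residues or \code{"-"}), as
#' transcribed from a published epitope table. (b) A multiple alignment of
#' preproenzymes plus the reference's \linkS4class{PeptideCoordinateMap}:
#' each epitope position (mature coordinate of the reference) is projected
#' through the reference row onto an alignment column and the query residue
#' is read there; a gapped query position counts as non-conserved and is
#' flagged.
#'
#' @param x residue-state matrix or alignment (\code{AAStringSet} /
#'   character).
#' @param query taxon (row) name of the query.
#' @param epitope an \linkS4class{EpitopeDefinition}; its reference
#'   residues must match the reference taxon at the stated positions.
#' @param reference taxon name of the reference (alignment form; defaults
#'   to the first row).
#' @param map the reference's \linkS4class{PeptideCoordinateMap}
#'   (alignment form).
#' @return List: \code{score} (percentage, 2 decimals, half-up),
#'   \code{matches} (logical per residue), \code{table} (\code{DataFrame}:
#'   position, reference and query residues, conserved, gapped).
#' @examples
#' states <- rbind(DerF1 = c("D", "L", "E", "E"),
#'                 TyrP1 = c("H", "L", "R", "D"))
#' colnames(states) <- c(57, 58, 60, 92)
#' ep <- epitopeDefinition("Ca", c(57, 58, 60, 92), c("D", "L", "E", "E"))
#' epitopeIdentity(states, "TyrP1", ep)$score  # 25
#' @export
epitopeIdentity <- function(x, query, epitope, reference = NULL, map = NULL) {
  stopifnot(is(epitope, "EpitopeDefinition"))
  if (is.matrix(x)) {
    if (!query %in% rownames(x)) stop("query taxon '", query, "' not found")
    cols <- match(as.character(epitope@positions), colnames(x))
    if (anyNA(cols))
      stop("epitope position(s) missing from the state matrix: ",
           paste(epitope@positions[is.na(cols)], collapse = ", "))
    refRes <- epitope@residues
    if (!is.null(reference)) {
      obs <- unname(x[reference, cols])
      if (!identical(obs, refRes))
        stop("reference taxon residues disagree with the epitope definition")
    }
    qRes <- unname(x[query, cols])
  } else {
    s <- .upperNamed(x)
    nm <- names(s)
    if (is.null(reference)) reference <- nm[1L]
    if (is.null(map)) stop("the alignment form needs the reference's map")
    if (!query %in% nm || !reference %in% nm)
      stop("query or reference taxon not in the alignment")
    refCh <- .chars(s[[reference]])
    qCh <- .chars(s[[query]])
    unGapped <- which(refCh != "-")
    refRes <- character(length(epitope@positions))
    qRes <- character(length(epitope@positions))
    for (k in seq_along(epitope@positions)) {
      idx <- matureToPrepro(map, epitope@positions[k])
      if (idx > length(unGapped))
        stop("epitope position ", epitope@positions[k],
             " beyond the reference sequence")
      col <- unGapped[idx]
      refRes[k] <- refCh[col]
      qRes[k] <- qCh[col]
    }
    if (!identical(refRes, epitope@residues))
      stop("reference residues at the epitope positions (",
           .collapse(refRes), ") disagree with the definition (",
           .collapse(epitope@residues), ")")
  }
  gapped <- qRes == "-"
  matches <- !gapped & qRes == refRes
  score <- roundHalfUp(100 * sum(matches) / length(matches), 2L)
  list(score = score, matches = matches,
       table = DataFrame(position = epitope@positions,
                         reference = refRes, query = qRes,
                         conserved = matches, gapped = gapped))
}

#' Mean pairwise similarity over a mature-coordinate region
#'
#' Maps a region given in the reference's mature coordinates onto the
#' alignment (the contiguous column span between the reference's first and
#' last region residues, insertion columns included) and returns the mean,
#' over the region's columns, of the fraction of sequence pairs with
#' identical residues in that column (gap positions never count as
#' identical), as a percentage.
#'
#' @param alignment equal-length gapped preproenzyme sequences.
#' @param startMature,endMature region bounds in reference mature
#'   coordinates (inclusive).
#' @param map the reference's \linkS4class{PeptideCoordinateMap}.
#' @param reference reference row name (default: first row).
#' @return Numeric percentage.
#' @export
regionMeanSimilarity <- function(alignment, startMature, endMature, map,
                                 reference = NULL) {
  s <- .upperNamed(alignment)
  if (length(unique(nchar(s))) != 1L) stop("rows have unequal lengths")
  nm <- names(s)
  if (is.null(reference)) reference <- if (is.null(nm)) 1L else nm[1L]
  if (startMature > endMature) stop("empty region")
  refCh <- .chars(s[[reference]])
  unGapped <- which(refCh != "-")
  i1 <- matureToPrepro(map, as.integer(startMature))
  i2 <- matureToPrepro(map, as.integer(endMature))
  if (i2 > length(unGapped)) stop("region extends beyond the reference")
  cols <- seq(unGapped[i1], unGapped[i2])
  mat <- do.call(rbind, strsplit(s, "", fixed = TRUE))[, cols, drop = FALSE]
  n <- nrow(mat)
  pairs <- combn(n, 2L)
  colScore <- apply(mat, 2L, function(col) {
    same <- col[pairs[1L, ]] == col[pairs[2L, ]] &
      col[pairs[1L, ]] != "-"
    mean(same)
  })
  100 * mean(colScore)
}
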