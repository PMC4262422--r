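test_that("identical sequences align without gaps", {
  s <- strrep("ACDEFGHIKL", 3)
  aln <- alignProteins(c(a = s, b = s))
  expect_identical(as.character(aln), c(a = s, b = s))
})

test_that("pairwise alignment score matches a textbook DP oracle", {
  sub <- blosum62
  for (pair in list(c("HEAGAWGHEE", "PAWHEAE"),
                    c("MKVLAA", "MKLAA"),
                    c("ACDEFGHIK", "ACDFGIK"))) {
    aln <- alignProteins(setNames(pair, c("a", "b")))
    a <- strsplit(as.character(aln)[1], "")[[1]]
    b <- strsplit(as.character(aln)[2], "")[[1]]
    # score the produced alignment and compare with the optimal DP score
    score <- 0
    state <- "M"
    for (k in seq_along(a)) {
      if (a[k] != "-" && b[k] != "-") {
        score <- score + sub[a[k], b[k]]; state <- "M"
      } else {
        gs <- if (a[k] == "-") "Y" else "X"
        score <- score + if (state == gs) -0.5 else -10
        state <- gs
      }
    }
    expect_equal(score, oracleAffineScore(pair[1], pair[2], sub, 10, 0.5))
  }
})

test_that("removing gaps from an alignment recovers the inputs exactly", {
  fam <- makeHomologFamily(strrep("MKVIFLACDEGHQRSTWYNP", 15), 6,
                           c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), seed = 31)
  aln <- alignProteins(fam)
  expect_equal(length(unique(nchar(as.character(aln)))), 1L)
  expect_identical(stripGaps(aln), as.character(fam))
  expect_identical(names(aln), names(fam))
})

test_that("percent identity counts identical columns over gap-free columns", {
  expect_equal(percentIdentity(c(a = "AAAA", b = "AAAT"))@.Data["a", "b"], 75)
  m <- percentIdentity(c(a = "AAAA", b = "AAAA"))
  expect_equal(m@.Data["a", "b"], 100)
  # invariant to appending gap-only columns
  base <- c(a = "ACDE-FG", b = "ACDEKF-")
  padded <- c(a = "ACDE-FG--", b = "ACDEKF---")
  expect_identical(percentIdentity(base)@.Data, percentIdentity(padded)@.Data)
  # matrix invariants
  fam <- makeHomologFamily(strrep("ACDEFGHIKL", 20), 5,
                           c(0.1, 0.2, 0.3, 0.4, 0.5), seed = 8)
  pm <- percentIdentity(alignProteins(fam))@.Data
  expect_equal(unname(diag(pm)), rep(100, 6))
  expect_equal(pm, t(pm))
  expect_true(all(pm >= 0 & pm <= 100))
  expect_warning(percentIdentity(c(a = "A-", b = "-A")), "no comparable")
})

test_that("column conservation symbols follow the Clustal group rules", {
  expect_identical(columnConservation(c("G", "G", "G"))[[1]], "*")
  expect_identical(columnConservation(c("I", "L", "V"))[[1]], ":")
  expect_identical(columnConservation(c("G", "R"))[[1]], " ")
  expect_identical(columnConservation(c("S", "A", "G"))[[1]], ".")
  expect_identical(columnConservation(c("G", "-", "G"))[[1]], " ")
  expect_identical(attr(columnConservation(c("GIV", "GLV", "GVV")), "line"),
                   "*:*")
})

test_that("epitope identity equals brute-force residue counting", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (trial in 1:200) {
    k <- sample(3:20, 1)
    pos <- sort(sample(1:300, k))
    refRes <- sample(aa, k, replace = TRUE)
    ep <- epitopeDefinition("e", pos, refRes)
    qRes <- refRes
    flip <- runif(k) < 0.4
    qRes[flip] <- vapply(which(flip), function(i)
      sample(c(setdiff(aa, refRes[i]), "-"), 1), "")
    states <- rbind(ref = refRes, q = qRes)
    colnames(states) <- pos
    got <- epitopeIdentity(states, "q", ep, reference = "ref")
    manual <- 100 * sum(qRes == refRes) / k
    expect_equal(got$score, round(manual * 100 + 1e-9) / 100)
    expect_identical(sum(got$matches), sum(qRes == refRes))
    expect_identical(got$table$gapped, qRes == "-")
  }
})

test_that("epitope scoring through an alignment projects reference positions", {
  ref <- strrep("MKVIFLACDEGHQRSTWYNP", 12)  # 240 aa, treated as all-mature
  epPos <- c(14, 16, 18, 19, 21, 156, 157, 159, 181, 182, 186, 199, 202, 204)
  refCh <- strsplit(ref, "")[[1]]
  ep <- epitopeDefinition("4C1-like", epPos, refCh[epPos])
  map <- buildCoordinateMap(0, 0, 240)
  fam <- makeHomologFamily(ref, 4, c(0.05, 0.1, 0.15, 0.2),
                           constrainedSites = epPos, seed = 13)
  aln <- alignProteins(fam)
  for (tx in names(fam)[-1]) {
    got <- epitopeIdentity(aln, tx, ep, reference = "reference", map = map)
    expect_equal(got$score, 100)  # constrained sites never mutate
  }
  # a mismatching reference definition is rejected
  bad <- epitopeDefinition("bad", epPos,
                           rep(setdiff(c("W", "A"), refCh[epPos[1]])[1],
                               length(epPos)))
  expect_error(epitopeIdentity(aln, names(fam)[2], bad,
                               reference = "reference", map = map),
               "disagree")
})

test_that("region mean similarity averages pairwise column identity", {
  fam <- c(a = strrep("ACDEFGHIKL", 10), b = strrep("ACDEFGHIKL", 10))
  map <- buildCoordinateMap(0, 0, 100)
  expect_equal(regionMeanSimilarity(fam, 29, 40, map), 100)
  two <- c(a = "AAAAAAAA", b = "AAAATTTT")
  expect_equal(regionMeanSimilarity(two, 1, 8, buildCoordinateMap(0, 0, 8)),
               50)
  # brute force on a generated family
  fam2 <- makeHomologFamily(strrep("ACDEFGHIKL", 12), 5,
                            c(0.1, 0.2, 0.3, 0.4, 0.5), seed = 3)
  aln <- alignProteins(fam2)
  map2 <- buildCoordinateMap(0, 0, 120)
  got <- regionMeanSimilarity(aln, 10, 40, map2)
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  refUngapped <- which(mat[1, ] != "-")
  cols <- seq(refUngapped[10], refUngapped[40])
  pairs <- combn(nrow(mat), 2)
  manual <- mean(apply(mat[, cols], 2, function(col)
    mean(col[pairs[1, ]] == col[pairs[2, ]] & col[pairs[1, ]] != "-")))
  expect_equal(got, 100 * manual)
  expect_error(regionMeanSimilarity(fam, 40, 29, map), "empty region")
})
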