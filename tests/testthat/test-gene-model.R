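test_that("a genomic sequence equal to the cDNA is a single exon", {
  cds <- randomCds(20)
  m <- inferGeneModel(cds, cds)
  expect_equal(length(exons(m)), 1L)
  expect_equal(length(introns(m)), 0L)
  expect_equal(IRanges::width(exons(m)), nchar(cds))
})

test_that("the Der f 1-like gene reports introns at mRNA positions 87 and 291", {
  g <- makeReferenceGene(derF1GeneSpec())
  m <- inferGeneModel(g$genomic, g$cdna)
  mp <- intronMrnaPositions(m)
  expect_true(all(c(87, 291) %in% mp))
  expect_equal(mp, c(87L, 291L, 519L, 600L, 760L))
  expect_equal(IRanges::width(introns(m)), c(66L, 78L, 58L, 66L, 60L))
})

test_that("inference recovers the planted model exactly on random genes", {
  for (seed in 1:100) {
    ne <- 2 + seed %% 4
    spec <- geneSpec(exonLengths = c(30, sample(seq(21, 120, 3), ne - 1,
                                                replace = TRUE)),
                     intronLengths = sample(20:70, ne - 1, replace = TRUE),
                     seed = seed)
    g <- makeReferenceGene(spec)
    m <- inferGeneModel(g$genomic, g$cdna)
    expect_identical(as.vector(IRanges::start(introns(m))),
                     as.vector(IRanges::start(introns(g$model))))
    expect_identical(as.vector(IRanges::end(introns(m))),
                     as.vector(IRanges::end(introns(g$model))))
  }
})

test_that("inference matches the exhaustive oracle on small instances", {
  set.seed(404)
  nChecked <- 0
  for (trial in 1:40) {
    # small random gene: 1 or 2 short introns in a short cDNA
    m <- sample(18:36, 1)
    cd <- paste0(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                 collapse = "")
    k <- sample(1:2, 1)
    lens <- sample(5:9, k, replace = TRUE)
    cut <- sort(sample(seq(2, m - 2), k))
    if (k == 2 && diff(cut) < 1) next
    gch <- strsplit(cd, "")[[1]]
    out <- character(0)
    prev <- 1
    for (i in seq_len(k)) {
      out <- c(out, gch[prev:cut[i]],
               c("G", "T", sample(c("A", "C", "G", "T"), lens[i] - 4,
                                  replace = TRUE), "A", "G"))
      prev <- cut[i] + 1
    }
    g <- paste0(c(out, gch[prev:m]), collapse = "")
    inferred <- inferGeneModel(g, cd, minIntron = 5, strictSplice = FALSE)
    oracle <- oracleBestDecompositions(g, cd, minIntron = 5)
    got <- oracleScoreDecomposition(g, cd,
                                    IRanges::start(introns(inferred)),
                                    IRanges::end(introns(inferred)))
    expect_equal(got, oracle$score)
    inArgmax <- any(vapply(oracle$argmax, function(a)
      identical(as.integer(a$starts),
                as.vector(IRanges::start(introns(inferred)))) &&
        identical(as.integer(a$ends),
                  as.vector(IRanges::end(introns(inferred)))),
      logical(1)))
    expect_true(inArgmax)
    nChecked <- nChecked + 1
  }
  expect_gt(nChecked, 30)
})

test_that("extractCDS reconstructs the generator's CDS and validates frame", {
  spec <- geneSpec(c(87, 204, 228, 81, 160, 206), c(66, 78, 58, 66, 44),
                   seed = 11)
  g <- makeReferenceGene(spec)
  expect_equal(length(g$genomic), 1278L)
  cds <- extractCDS(g$genomic, g$model)
  expect_equal(length(cds), 966L)
  expect_identical(as.character(cds), as.character(g$cdna))
  prot <- translateCDS(cds)
  expect_equal(length(prot), 321L)

  single <- randomCds(10)
  m1 <- GeneModel(1, nchar(single))
  expect_identical(as.character(extractCDS(single, m1)), single)

  # exon 2 shifted by one base breaks the reading frame
  shifted <- GeneModel(c(IRanges::start(exons(g$model))[1],
                         IRanges::start(exons(g$model))[-1] + c(1, 0, 0, 0, 0)),
                       IRanges::end(exons(g$model)))
  expect_error(extractCDS(g$genomic, shifted), "frame|divisible|stop")
})

test_that("CDS defects are reported with their coordinates", {
  expect_error(extractCDS("TTGAAATAA", GeneModel(1, 9)), "start codon")
  expect_error(extractCDS("ATGTAACCCTAA", GeneModel(1, 12)),
               "internal stop codon 'TAA' at codon 2")
  expect_error(extractCDS("ATGAAACCC", GeneModel(1, 9)), "stop")
})

test_that("comparing gene models finds the missing intron and length changes", {
  df <- makeReferenceGene(derF1GeneSpec())$model
  dp <- makeReferenceGene(derP1GeneSpec())$model
  expect_equal(nrow(compareGeneModels(df, df)), 0L)

  diff <- compareGeneModels(df, dp)
  absent <- diff[diff$status %in% c("absent_in_a", "absent_in_b"), ]
  expect_equal(nrow(absent), 1L)       # exactly one intron is missing
  expect_equal(absent$status, "absent_in_b")
  expect_equal(absent$intronA, 3L)     # the intron 3 homolog
  expect_equal(absent$lengthA, 58L)
  expect_equal(absent$mrnaA, 519L)
  # the shared introns differ only in length, never in presence
  expect_true(all(diff$status[diff$status != "absent_in_b"] ==
                    "length_change"))

  # same model with one intron length changed: a length record, no
  # presence/absence record
  spec2 <- geneSpec(c(87, 204, 228, 81, 160, 206), c(66, 78, 58, 66, 44),
                    seed = 101)
  other <- makeReferenceGene(spec2)$model
  diff2 <- compareGeneModels(df, other)
  expect_true(all(diff2$status == "length_change"))
  expect_equal(nrow(diff2), 1L)
  expect_equal(diff2$lengthA, 60L)
  expect_equal(diff2$lengthB, 44L)

  tiny <- makeReferenceGene(geneSpec(c(30, 30), 25, seed = 1))$model
  expect_error(compareGeneModels(df, tiny), "unalignable anchors")
})

test_that("non-canonical splice sites are flagged under strict mode only", {
  g <- makeReferenceGene(geneSpec(c(60, 60), 40, seed = 17))
  gch <- strsplit(as.character(g$genomic), "")[[1]]
  gch[IRanges::start(introns(g$model))[1] + 1] <- "C"  # GT -> GC donor
  broken <- paste0(gch, collapse = "")
  expect_warning(m <- inferGeneModel(broken, g$cdna), "non-canonical")
  expect_true(length(m@flags) > 0)
  expect_silent(m2 <- inferGeneModel(broken, g$cdna, strictSplice = FALSE))
  expect_length(m2@flags, 0)
})

test_that("unalignable inputs raise structured errors", {
  g <- makeReferenceGene(geneSpec(c(60, 60), 40, seed = 23))
  expect_error(inferGeneModel(as.character(g$cdna), as.character(g$genomic)),
               "longer than")
  # corrupt most of exon 1: identity falls below the threshold
  gch <- strsplit(as.character(g$genomic), "")[[1]]
  idx <- 4:40
  gch[idx] <- vapply(gch[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  expect_error(
    suppressWarnings(inferGeneModel(paste0(gch, collapse = ""), g$cdna)),
    "unalignable")
  expect_error(inferGeneModel("", "A"), "empty")
})

test_that("a reference prefix can be spliced onto a partial 5' end", {
  full <- randomCds(12)
  partial <- substr(full, 5, nchar(full))
  patched <- spliceReferencePrefix(partial, full, 4, source = "refA")
  expect_identical(as.character(patched$sequence), full)
  expect_equal(IRanges::width(patched$patched), 4L)
  expect_identical(patched$source, "refA")
})
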