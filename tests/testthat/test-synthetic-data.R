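test_that("generated genes keep the declared length bookkeeping", {
  # 6 exons summing to a 966-nt CDS plus introns summing to 312 nt gives a
  # 1278-nt amplicon whose cDNA is the 966-nt CDS
  spec <- geneSpec(c(87, 204, 228, 81, 160, 206), c(66, 78, 58, 66, 44),
                   seed = 7)
  g <- makeReferenceGene(spec)
  expect_equal(length(g$genomic), 1278L)
  expect_equal(length(g$cdna), 966L)
  expect_equal(length(introns(g$model)), 5L)

  single <- makeReferenceGene(geneSpec(60, seed = 3))
  expect_equal(as.character(single$genomic), as.character(single$cdna))
  expect_equal(length(introns(single$model)), 0L)
})

test_that("the cDNA is the concatenated exons and the CDS is well-formed", {
  for (seed in 1:10) {
    ne <- sample(2:5, 1)
    spec <- geneSpec(exonLengths = c(30, sample(seq(21, 90, 3), ne - 1)),
                     intronLengths = sample(20:60, ne - 1), seed = seed)
    g <- makeReferenceGene(spec)
    gch <- strsplit(as.character(g$genomic), "")[[1]]
    ex <- unlist(lapply(seq_along(exons(g$model)), function(i)
      gch[IRanges::start(exons(g$model))[i]:IRanges::end(exons(g$model))[i]]))
    expect_equal(paste0(ex, collapse = ""), as.character(g$cdna))
    cds <- as.character(g$cdna)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("every generated intron is canonical GT..AG", {
  for (seed in 1:100) {
    spec <- geneSpec(c(45, 45, 45), sample(20:50, 2), seed = seed)
    g <- makeReferenceGene(spec)
    expect_true(all(g$model@donor == "GT"))
    expect_true(all(g$model@acceptor == "AG"))
  }
})

test_that("generation is byte-identical for a fixed seed", {
  for (seed in c(1, 19, 463)) {
    spec <- geneSpec(c(90, 90), 35, seed = seed)
    a <- makeReferenceGene(spec)
    b <- makeReferenceGene(spec)
    expect_identical(as.character(a$genomic), as.character(b$genomic))
    pop <- populationSpec(nIndividuals = 8, seed = seed + 1)
    pa <- makePopulation(a, pop)
    pb <- makePopulation(b, pop)
    expect_identical(as.character(pa$consensus), as.character(pb$consensus))
    f1 <- tempfile(); f2 <- tempfile()
    writeFasta(pa$consensus, f1)
    writeFasta(pb$consensus, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("an infeasible gene spec names the violated invariant", {
  expect_error(geneSpec(c(10, 10), 30), "divisible by 3")
  expect_error(geneSpec(c(9, 9), 10), ">= 20")
  expect_error(geneSpec(c(9, 9, 9), 30), "intron count")
  expect_error(populationSpec(h1Frequency = 1.2), "h1Frequency")
})

test_that("a monomorphic population carries no ambiguity codes", {
  g <- makeReferenceGene(geneSpec(c(60, 60), 30, seed = 2))
  p <- makePopulation(g, populationSpec(nIndividuals = 6, h1Frequency = 1,
                                        nDiagnosticSites = 4,
                                        singletonRate = 0, seed = 5))
  expect_true(all(p$truth$diplotype == "H1/H1"))
  expect_false(any(grepl("[RYSWKMBDHVN]", as.character(p$consensus))))
  expect_true(all(as.character(p$consensus) == p$h1))
})

test_that("heterozygous sites render as the IUPAC union of the two alleles", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 8))
  p <- makePopulation(g, populationSpec(nIndividuals = 30, h1Frequency = 0.5,
                                        nDiagnosticSites = 6,
                                        singletonRate = 0, seed = 9))
  hets <- which(p$truth$diplotype == "H1/H2")
  expect_gt(length(hets), 0)
  for (i in hets) {
    cons <- strsplit(as.character(p$consensus)[i], "")[[1]]
    for (k in seq_len(nrow(p$sites))) {
      s <- p$sites$coordinate[k]
      expected <- iupacCode(c(p$sites$h1[k], p$sites$h2[k]))
      expect_identical(cons[s], expected)
    }
  }
  # the canonical worked case: alleles A and T give consensus W
  expect_identical(iupacCode(c("A", "T")), "W")
})

test_that("diplotype sampling follows Hardy-Weinberg proportions", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 21))
  p <- 0.7
  n <- 500
  pop <- makePopulation(g, populationSpec(nIndividuals = n, h1Frequency = p,
                                          nDiagnosticSites = 5,
                                          singletonRate = 0, seed = 22))
  counts <- table(factor(pop$truth$diplotype,
                         levels = c("H1/H1", "H1/H2", "H2/H2")))
  phat <- (2 * counts[["H1/H1"]] + counts[["H1/H2"]]) / (2 * n)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / (2 * n)))
  exp_props <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  for (k in 1:3) {
    se <- sqrt(exp_props[k] * (1 - exp_props[k]) / n)
    expect_lt(abs(counts[[k]] / n - exp_props[k]), 3 * se)
  }
})

test_that("silent-only private mutations never change the protein", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 31))
  pop <- makePopulation(g, populationSpec(nIndividuals = 40, h1Frequency = 1,
                                          nDiagnosticSites = 0,
                                          singletonRate = 1.5,
                                          silentOnly = TRUE, seed = 32))
  refProt <- as.character(translateCDS(extractCDS(g$genomic, g$model)))
  withPriv <- which(nchar(pop$truth$privates) > 0)
  expect_gt(length(withPriv), 0)
  for (i in withPriv) {
    # resolve each heterozygous consensus to the mutated copy and translate
    cons <- strsplit(as.character(pop$consensus)[i], "")[[1]]
    for (pv in strsplit(pop$truth$privates[i], ";")[[1]]) {
      parts <- strsplit(pv, ":")[[1]]
      cons[as.integer(parts[1])] <- parts[2]
    }
    prot <- as.character(translateCDS(extractCDS(paste0(cons, collapse = ""),
                                                 g$model)))
    expect_identical(prot, refProt)
  }
})

test_that("homolog families respect constraints and divergence ordering", {
  ref <- strrep("ACDEFGHIKLMNPQRSTVWY", 16)  # 320 aa
  fam <- makeHomologFamily(ref, 4, 0, seed = 1)
  expect_true(all(as.character(fam) == ref))
  expect_true(all(percentIdentity(fam)@.Data == 100))

  constrained <- c(14, 16, 18, 19, 21, 57, 58, 60, 92)
  div <- c(0.05, 0.15, 0.30, 0.45)
  fam <- makeHomologFamily(ref, 4, div, constrainedSites = constrained,
                           seed = 2)
  refCh <- strsplit(ref, "")[[1]]
  for (i in 2:5) {
    ch <- strsplit(as.character(fam)[i], "")[[1]]
    expect_true(all(ch[constrained] == refCh[constrained]))
    # realised divergence equals the target to rounding
    expect_equal(mean(ch != refCh), round(div[i - 1] * 320) / 320,
                 tolerance = 1e-9)
  }
  # ungapped comparison to the reference reproduces the requested ladder
  ids <- vapply(2:5, function(i) {
    ch <- strsplit(as.character(fam)[i], "")[[1]]
    100 * mean(ch == refCh)
  }, numeric(1))
  expect_identical(order(ids), 4:1)

  expect_error(makeHomologFamily(ref, 2, 1, constrainedSites = 1:100,
                                 seed = 1), "unsatisfiable")
  expect_error(makeHomologFamily(ref, 2, 1.5, seed = 1), "divergence")
})
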