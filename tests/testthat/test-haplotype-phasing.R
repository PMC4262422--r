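makeToyMatrix <- function(states, coords = NULL,
                          region = NULL) {
  # states: individuals x sites character matrix
  n <- ncol(states)
  if (is.null(coords)) coords <- seq(10, by = 10, length.out = n)
  if (is.null(region)) region <- rep("intron_1", n)
  ids <- rownames(states)
  if (is.null(ids)) ids <- sprintf("id%02d", seq_len(nrow(states)))
  GenotypeMatrix(t(states), coordinate = coords, region = region,
                 individuals = ids)
}

test_that("an invariant matrix has no diagnostic sites", {
  states <- matrix("A", nrow = 4, ncol = 3)
  gm <- makeToyMatrix(states)
  expect_length(findDiagnosticSites(gm), 0L)
})

test_that("diagnostic sites require both alleles homozygous and non-private", {
  states <- rbind(
    c("A", "T", "ACG"),
    c("A", "T", "ACG"),
    c("T", "C", "ACG"),   # site 1 minor allele T: two homozygous carriers
    c("T", "W", "ACT"))   # site 2 C private; site 3 ACT private
  gm <- makeToyMatrix(states, coords = c(5, 15, 25),
                      region = c("intron_1", "intron_1", "exon_1"))
  expect_identical(findDiagnosticSites(gm), 5L)
})

test_that("a single homozygote phases to its own haplotype duplicated", {
  states <- matrix(c("A", "T", "G"), nrow = 1)
  gm <- makeToyMatrix(states)
  ph <- phaseTwoHaplotypes(gm, c(10, 20, 30))
  expect_identical(ph@h1, ph@h2)
  expect_identical(assignments(ph)$diplotype, "H1/H1")
})

test_that("phasing recovers the generator truth and surfaces frequencies", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 55))
  p <- makePopulation(g, populationSpec(nIndividuals = 200,
                                        h1Frequency = 0.7,
                                        nDiagnosticSites = 6,
                                        singletonRate = 0.2, seed = 56))
  gm <- callVariantSites(p$consensus, g$model)
  diag <- findDiagnosticSites(gm)
  expect_setequal(diag, p$sites$coordinate)
  ph <- phaseTwoHaplotypes(gm, diag)
  al <- alignDiplotypes(assignments(ph)$diplotype, p$truth$diplotype)
  expect_identical(al$diplotypes, p$truth$diplotype)
  fr <- haplotypeFrequencies(ph)
  phat <- if (al$swapped) 1 - fr$h1AlleleFrequency else fr$h1AlleleFrequency
  se <- sqrt(0.7 * 0.3 / (2 * 200))
  expect_lt(abs(phat - 0.7), 3 * se)
})

test_that("consistent assignments reproduce the observed IUPAC genotypes", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 61))
  p <- makePopulation(g, populationSpec(nIndividuals = 60,
                                        h1Frequency = 0.5,
                                        nDiagnosticSites = 5,
                                        singletonRate = 0, seed = 62))
  gm <- callVariantSites(p$consensus, g$model)
  diag <- findDiagnosticSites(gm)
  ph <- phaseTwoHaplotypes(gm, diag)
  hap <- haplotypes(ph)
  rd <- SummarizedExperiment::rowData(gm)
  calls <- SummarizedExperiment::assay(gm, "calls")[match(diag, rd$coordinate), ,
                                                    drop = FALSE]
  a <- assignments(ph)
  for (j in seq_len(ncol(calls))) {
    expected <- switch(a$diplotype[j],
      "H1/H1" = hap["H1", ],
      "H2/H2" = hap["H2", ],
      "H1/H2" = vapply(seq_along(diag), function(i) {
        a <- strsplit(hap["H1", i], "")[[1]]
        b <- strsplit(hap["H2", i], "")[[1]]
        paste(mapply(function(x, y) if (x == y) x else
          allerGene::iupacCode(c(x, y)), a, b), collapse = "")
      }, character(1)))
    expect_identical(unname(calls[, j]), unname(expected))
  }
})

test_that("permuting individuals permutes assignments identically", {
  g <- makeReferenceGene(geneSpec(c(120, 120), 40, seed = 71))
  p <- makePopulation(g, populationSpec(nIndividuals = 30, seed = 72))
  gm <- callVariantSites(p$consensus, g$model)
  diag <- findDiagnosticSites(gm)
  ph1 <- phaseTwoHaplotypes(gm, diag)
  set.seed(1)
  perm <- sample(ncol(gm))
  ph2 <- phaseTwoHaplotypes(gm[, perm], diag)
  expect_identical(ph1@h1, ph2@h1)
  expect_identical(assignments(ph2)$diplotype,
                   assignments(ph1)$diplotype[perm])
})

test_that("a third homozygote pattern beyond tolerance is an error", {
  states <- rbind(
    c("A", "A", "A", "A"),
    c("A", "A", "A", "A"),
    c("T", "T", "T", "T"),
    c("T", "T", "T", "T"),
    c("A", "T", "T", "A"))  # two sites away from both patterns
  gm <- makeToyMatrix(states)
  expect_error(phaseTwoHaplotypes(gm, c(10, 20, 30, 40), tolerance = 1),
               "exceeds two-haplotype model")
  # with a larger tolerance the stray pattern is absorbed
  ph <- phaseTwoHaplotypes(gm, c(10, 20, 30, 40), tolerance = 2)
  expect_identical(assignments(ph)$diplotype[5], "H1/H1")
  expect_true(assignments(ph)$flagged[5])
})

test_that("near-consistent individuals are assigned with mismatches listed", {
  states <- rbind(
    c("A", "A", "A"),
    c("A", "A", "A"),
    c("T", "T", "T"),
    c("T", "T", "T"),
    c("W", "W", "A"),   # het but plain A at the last site: 1 mismatch
    c("W", "T", "A"))   # 2 mismatches from every diplotype: inconsistent
  gm <- makeToyMatrix(states)
  ph <- phaseTwoHaplotypes(gm, c(10, 20, 30), tolerance = 1)
  a <- assignments(ph)
  expect_identical(a$diplotype[5], "H1/H2")
  expect_true(a$flagged[5])
  expect_identical(a$mismatchSites[5], "30")
  expect_identical(a$diplotype[6], "inconsistent")
  expect_equal(a$nMismatch[6], 2)
  expect_equal(a$consistency[6], 1 - 2 / 3)
})

test_that("frequencies follow the printed-count arithmetic", {
  # 14 + 4 + 4 individuals of 22: 63.6 / 18.2 / 18.2 after rounding
  states <- rbind(
    matrix(rep(c("A", "A"), 14), ncol = 2, byrow = TRUE),
    matrix(rep(c("T", "T"), 4), ncol = 2, byrow = TRUE),
    matrix(rep(c("W", "W"), 4), ncol = 2, byrow = TRUE))
  gm <- makeToyMatrix(states)
  ph <- phaseTwoHaplotypes(gm, c(10, 20))
  fr <- haplotypeFrequencies(ph)
  expect_identical(unname(fr$counts), c(14L, 4L, 4L, 0L))
  expect_equal(round(unname(fr$percentages)[1:3], 1), c(63.6, 18.2, 18.2))
  expect_equal(fr$h1AlleleFrequency, (2 * 14 + 4) / 44)

  ten <- makeToyMatrix(matrix("A", nrow = 10, ncol = 2))
  ph10 <- phaseTwoHaplotypes(ten, c(10, 20))
  expect_equal(haplotypeFrequencies(ph10)$h1AlleleFrequency, 1)
})

test_that("estimated haplotype frequency is unbiased across seeds", {
  for (p in c(0.5, 0.9)) {
    errs <- vapply(1:6, function(seed) {
      g <- makeReferenceGene(geneSpec(c(90, 90), 40, seed = seed))
      pop <- makePopulation(g, populationSpec(nIndividuals = 200,
                                              h1Frequency = p,
                                              nDiagnosticSites = 5,
                                              singletonRate = 0.2,
                                              seed = seed + 1000))
      gm <- callVariantSites(pop$consensus, g$model)
      ph <- phaseTwoHaplotypes(gm, pop$sites$coordinate)
      al <- alignDiplotypes(assignments(ph)$diplotype, pop$truth$diplotype)
      phat <- haplotypeFrequencies(ph)$h1AlleleFrequency
      (if (al$swapped) 1 - phat else phat) - p
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.03)
  }
})
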