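#' Run the full allergen-gene analysis pipeline
#'
#' Orchestrates the analysis end-to-end and writes a reproducible report
#' bundle. Two input modes:
#' \describe{
#'   \item{genotype table}{\code{config$genotypeTable}: a curated
#'     variant-site table (see \code{\link{readGenotypeTable}}); sites are
#'     filtered to variant columns, classified, phased and summarised.}
#'   \item{sequences}{\code{config$consensusFasta} +
#'     \code{config$cdnaFasta}: consensus amplicons and a cDNA reference;
#'     the gene model is inferred from the first consensus record, variants
#'     are called against it, then classified and phased.}
#' }
#' Optionally, epitope residue-state matrices are scored against the
#' packaged epitope definitions, and an identity matrix is turned into a
#' neighbor-joining tree. All outputs are deterministic for fixed inputs
#' and seed; every table carries a header stamping the package version and
#' seed.
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   \code{genotypeTable}, \code{consensusFasta}, \code{cdnaFasta},
#'   \code{gene}, \code{segments} (signal/pro/mature aa lengths),
#'   \code{crossDeletions}, \code{phasingTolerance} (default 1),
#'   \code{geneLength}, \code{cdsLength}, \code{polyT} (c(start,end)),
#'   \code{epitopeStates} (named list of TSV paths or matrices),
#'   \code{identityMatrix} (TSV path or matrix), \code{seed} (default 1),
#'   \code{outDir} (default: no files written).
#' @param outDir output directory (overrides \code{config$outDir}).
#' @return Invisibly, a list: \code{variants}
#'   (\linkS4class{GenotypeMatrix}), \code{phasing}
#'   (\linkS4class{HaplotypePair} or NULL), \code{frequencies},
#'   \code{densities}, \code{epitopeScores}, \code{tree}, \code{model},
#'   and \code{summary} (the flat summary written to
#'   \code{summary.json}).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(outDir)) outDir <- config$outDir
  tol <- if (is.null(config$phasingTolerance)) 1L else
    as.integer(config$phasingTolerance)
  log <- character()
  say <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    log <<- c(log, line)
    message(line)
  }

  map <- if (!is.null(config$segments)) {
    s <- as.integer(unlist(config$segments))
    buildCoordinateMap(s[1L], s[2L], s[3L],
                       crossDeletions = as.integer(
                         unlist(config$crossDeletions)))
  } else NULL

  model <- NULL
  if (!is.null(config$genotypeTable)) {
    gene <- if (is.null(config$gene)) basename(config$genotypeTable) else
      config$gene
    say("input", "genotype table ", config$genotypeTable)
    gmAll <- readGenotypeTable(config$genotypeTable, gene = gene)
    gm <- variantSites(gmAll)
  } else if (!is.null(config$consensusFasta)) {
    say("input", "consensus FASTA ", config$consensusFasta)
    cons <- readFasta(config$consensusFasta)
    cdna <- readFasta(config$cdnaFasta)[[1L]]
    model <- tryCatch(
      inferGeneModel(cons[[1L]], cdna,
                     cdnaAnchor = names(readFasta(config$cdnaFasta))[1L],
                     seqid = names(cons)[1L]),
      error = function(e) stop("stage 'annotate' (", config$consensusFasta,
                               "): ", conditionMessage(e), call. = FALSE))
    say("annotate", length(model@exons), " exons / ",
        length(model@introns), " introns")
    polyT <- if (length(config$polyT)) as.integer(unlist(config$polyT))
    gm <- callVariantSites(cons, model, polyT = polyT,
                           gene = if (is.null(config$gene)) "gene" else
                             config$gene)
  } else {
    stop("config must provide 'genotypeTable' or 'consensusFasta'")
  }

  gm <- classifyVariants(gm, model = model, map = map)
  rd <- SummarizedExperiment::rowData(gm)
  say("variants", nrow(gm), " variant sites (",
      sum(grepl("^intron", rd$region)), " intronic)")

  phasing <- NULL
  freqs <- NULL
  diag <- findDiagnosticSites(gm)
  if (length(diag) > 0L) {
    phasing <- phaseTwoHaplotypes(gm, diag, tolerance = tol)
    freqs <- haplotypeFrequencies(phasing)
    say("phase", length(diag), " diagnostic sites; diplotypes ",
        paste(names(freqs$counts), freqs$counts, sep = "=", collapse = ", "))
  } else {
    say("phase", "no diagnostic sites; phasing skipped")
  }

  densities <- NULL
  if (!is.null(config$geneLength)) {
    densities <- polymorphismDensityTable(gm, as.integer(config$geneLength),
                                          cdsLength = config$cdsLength)
    say("density", "tabulated ", nrow(densities),
        " candidate density definitions")
  }

  epitopeScores <- NULL
  if (!is.null(config$epitopeStates)) {
    defs <- epitopeDefinitions()
    rows <- list()
    for (nm in names(config$epitopeStates)) {
      states <- config$epitopeStates[[nm]]
      if (is.character(states)) {
        tab <- read.delim(states, check.names = FALSE, comment.char = "#",
                          colClasses = "character")
        states <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(states) <- tab[[1L]]
      }
      def <- defs[[nm]]
      if (is.null(def)) stop("unknown epitope '", nm, "'")
      for (tx in rownames(states)) {
        sc <- epitopeIdentity(states, tx, def)
        rows[[length(rows) + 1L]] <- DataFrame(epitope = nm, taxon = tx,
                                               score = sc$score)
      }
    }
    epitopeScores <- do.call(rbind, rows)
    say("conserve", nrow(epitopeScores), " epitope scores computed")
  }

  tree <- NULL
  if (!is.null(config$identityMatrix)) {
    im <- config$identityMatrix
    if (is.character(im)) {
      tab <- read.delim(im, check.names = FALSE, comment.char = "#")
      m <- as.matrix(tab[, -1L])
      rownames(m) <- tab[[1L]]
      im <- identityMatrix(m)
    } else if (!is(im, "IdentityMatrix")) {
      im <- identityMatrix(im)
    }
    tree <- njTree(im)
    say("tree", "neighbor-joining tree over ", length(tree$tip.label),
        " taxa")
  }

  summary <- list(
    gene = metadata(gm)$gene,
    seed = seed,
    nVariantSites = nrow(gm),
    nIntronic = sum(grepl("^intron", rd$region)),
    nCoding = sum(grepl("^exon", rd$region)),
    nSynonymous = sum(rd$classification == "synonymous"),
    nNonSynonymous = sum(rd$classification == "non_synonymous"),
    nonSynonymousChanges = rd$aaChange[rd$classification == "non_synonymous"],
    diagnosticSites = as.integer(diag),
    diplotypeCounts = if (!is.null(freqs)) as.list(freqs$counts),
    h1AlleleFrequency = if (!is.null(freqs)) freqs$h1AlleleFrequency,
    densities = if (!is.null(densities)) as.data.frame(densities),
    epitopeScores = if (!is.null(epitopeScores)) as.data.frame(epitopeScores))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .stamp(seed)
    writeVariantTable(gm, file.path(outDir, "variants.tsv"), header = hdr)
    if (!is.null(model))
      writeGeneModelGFF3(model, file.path(outDir, "gene_model.gff3"))
    if (!is.null(phasing)) {
      .writeTsv(as.data.frame(assignments(phasing)),
                file.path(outDir, "haplotype_assignments.tsv"), hdr)
      writeFasta(setNames(c(.collapse(phasing@h1), .collapse(phasing@h2)),
                          c("H1", "H2")),
                 file.path(outDir, "haplotypes.fasta"), type = "DNA")
    }
    if (!is.null(densities))
      .writeTsv(as.data.frame(densities),
                file.path(outDir, "polymorphism_density.tsv"), hdr)
    if (!is.null(epitopeScores))
      .writeTsv(as.data.frame(epitopeScores),
                file.path(outDir, "epitope_scores.tsv"), hdr)
    if (!is.null(tree))
      ape::write.tree(tree, file.path(outDir, "nj_tree.nwk"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    writeLines(log, file.path(outDir, "pipeline.log"))
  }

  invisible(list(variants = gm, phasing = phasing, frequencies = freqs,
                 densities = densities, epitopeScores = epitopeScores,
                 tree = tree, model = model, summary = summary, log = log))
}

.writeTsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
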