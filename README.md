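# allerGene

Sequence analysis of **group 1 allergen genes of house dust mites** (Der f 1
of *Dermatophagoides farinae*, Der p 1 of *D. pteronyssinus*, and their
homologs in other mite species) from direct-sequenced genomic amplicons.

Group 1 allergens are papain-family cysteine proteases and the dominant
IgE-binding allergens in house dust mite allergy. Surveying their
polymorphism from genomic amplicons — rather than RT-PCR cDNA clones —
requires a small but specific analysis chain, which this package implements
as tested, reusable components:

* **Gene-model inference** (`inferGeneModel`): spliced decomposition of a
  genomic amplicon against a cDNA reference. Exons align with substitutions
  only; introns are the genomic-only gaps, favouring canonical GT..AG
  junctions (leftmost placement on ties). Coordinates are 1-based with mRNA
  position 1 at the first nucleotide of the start codon.
* **Diploid variant calling** (`callVariantSites`, `classifySite`): in a
  Sanger consensus of a diploid, a heterozygous site appears as an IUPAC
  ambiguity code (W = A/T, ...). Sites with ≥ 2 distinct alleles after
  IUPAC expansion are called, placed in exon/intron context, and coding
  sites are classified synonymous / non-synonymous by expanding the
  observed codons and comparing the encoded residues.
* **Two-haplotype phasing** (`phaseTwoHaplotypes`): Clark-style resolution
  over diagnostic sites (biallelic, both alleles seen homozygous):
  homozygotes define the candidate haplotypes H1/H2, heterozygotes are
  assigned where their ambiguity pattern equals the site-wise union of the
  two, and the H1 allele frequency is estimated as
  `(2·n_H1/H1 + n_het) / (2·n_consistent)`.
* **Preproenzyme coordinates** (`buildCoordinateMap`, `ntToAA`,
  `crossSpeciesPosition`): the translated polypeptide is signal peptide +
  proenzyme + mature enzyme; mature residues are numbered 1..L and the
  signal/pro segments take negative positions (no position 0). A deletion
  set defines the partner-species dual numbering (e.g. Der f 1 mature 100 =
  Der p 1 position 99 when position 9 is deleted).
* **Cross-species conservation** (`alignProteins`, `percentIdentity`,
  `epitopeIdentity`, `columnConservation`, `njTree`): progressive
  BLOSUM62 multiple alignment, percent-identity matrices, Clustal-style
  column symbols, epitope identity scores
  `100 × conserved residues / epitope size` (e.g. the 14-residue 4C1
  antibody epitope and the 4-residue Ca²⁺-binding set), and a
  neighbor-joining tree on distances `(100 − identity)/100`.
* **Synthetic data** (`makeReferenceGene`, `makePopulation`,
  `makeHomologFamily`): generator for genes with known intron structure,
  Hardy–Weinberg diploid populations rendered as IUPAC consensus sequences
  (including a variable poly-T intron tract), and homolog families with
  controlled divergence — the ground truth for the test suite.

Curated fixtures ship with the package: the per-individual genotype tables
for 22 *D. farinae* and 12 *D. pteronyssinus* amplicons, the
epitope residue-state matrices for eight mite species, the epitope
definitions, and the published percent-identity matrix.

## Worked example

```r
library(allerGene)

gm <- classifyVariants(variantSites(derF1Genotypes()))
table(sub("_.*", "", SummarizedExperiment::rowData(gm)$region))
#>   exon intron
#>      7      7
table(SummarizedExperiment::rowData(gm)$classification)
#>       intronic non_synonymous     synonymous
#>              7              1              6
```

The 22 *D. farinae* consensus sequences vary at 14 positions: 7 intronic,
6 silent coding changes, and a single non-synonymous site (Trp→Arg at
mature position 197, codon TGG→CGG).

```r
ph <- phaseTwoHaplotypes(gm, findDiagnosticSites(gm))
ph
#> HaplotypePair over 9 diagnostic site(s)
#>   H1: AACGTCTGATTTTTACT
#>   H2: TACTCACTATCTTCACA
#>   assignments: H1/H1=15, H2/H2=5, H1/H2=0, inconsistent=2
```

Two recurring haplotypes explain the population; two individuals carry
ambiguity patterns that are not an exact H1∪H2 union and are reported as
inconsistent with their mismatching sites (the genotype table is
transcribed verbatim, discrepancies included, and the phaser surfaces
rather than corrects them).

```r
ep <- epitopeIdentity(epitopeStates("4C1"), "DerP1",
                      epitopeDefinitions()[["4C1"]], reference = "DerF1")
ep$score
#> [1] 85.71

derF1CoordinateMap()
#> PeptideCoordinateMap: signal 18 aa, pro 80 aa, mature 223 aa (preproenzyme 321 aa)
#>   deleted in partner at mature position(s): 9
```

Der p 1 conserves 12 of the 14 4C1 epitope residues of Der f 1 (85.71%),
and the 321-residue Der f 1 preproenzyme maps onto its 320-residue Der p 1
counterpart through the single deletion at mature position 9.

`runPipeline()` chains all stages (annotate → variants → phase → peptide →
conserve) from one config and writes a deterministic report bundle (GFF3
gene model, VCF-like variant table, haplotype report, density table,
epitope scores, Newick tree, JSON summary). A thin command-line wrapper is
installed at `inst/scripts/allergene.R`.

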