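---
title: "allerGene: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{allerGene: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerGene)
```

This vignette records the models behind each analysis stage, the tunable
parameters and their defaults, the numerical conventions, and the design
decisions taken where more than one defensible choice existed. It states
no result that the test suite or the acceptance script does not itself
compute.

## The analysis problem

Group 1 allergens of house dust mites (Der f 1, Der p 1 and homologs) are
papain-family cysteine proteases. Surveying their polymorphism from
direct-sequenced genomic amplicons requires: annotating the exon/intron
structure of each amplicon against a cDNA reference; calling variant sites
from diploid consensus sequences in which heterozygosity appears as IUPAC
ambiguity letters; resolving the population's two-haplotype structure;
mapping coding variants into the signal/pro/mature peptide coordinate
system; and scoring how well antibody-binding epitopes are conserved
across homologs from other mite species.

## Gene-model inference

`inferGeneModel()` finds the maximal-scoring tiling of the amplicon by
alternating exons and introns under a substitutions-only exon model:

* match +1, mismatch −1 per exonic column;
* intron opening −8, plus +4 when the intron is canonical (GT donor,
  AG acceptor);
* introns must be at least `minIntron` (default 20) nt long and flanked by
  non-empty exons.

The dynamic program is exact over all decompositions (implemented in C++;
amplicon-scale inputs of ~1.3 kb make this cheap). Mismatches are expected
— they are the polymorphisms under study — but a per-exon identity below
`identityThreshold` (default 0.90) aborts with an "unalignable" error
rather than returning a dubious model.

**Junction ambiguity.** When the bases flanking a junction repeat, an
intron can be shifted without changing the exon concatenation; all such
placements score equally except for the canonical bonus. The package
resolves ties deterministically: the leftmost placement that yields GT..AG,
else the leftmost placement overall. A small exhaustive oracle
(enumeration of every decomposition for short sequences with up to two
introns) pins the optimum in the test suite.

**Splice-site policy.** Under the default strict mode, a non-GT..AG intron
is accepted but flagged on the model and raised as a warning — never
silently. How non-canonical junctions in real amplicons should be treated
is genuinely open; flag-and-warn keeps the evidence visible while letting
the pipeline proceed. `strictSplice = FALSE` accepts silently.

**Coordinates.** All coordinates are 1-based inclusive. mRNA position 1 is
the first nucleotide of the start codon; the mRNA position of an intron is
the cDNA position of the last exonic nucleotide upstream of it. Partial 5'
ends can be patched from a reference with `spliceReferencePrefix()`, which
records the provenance of the patched positions.

## The packaged gene presets and a coordinate conflict

`derF1GeneSpec()` describes a Der f 1-like gene: a 966-nt CDS (321-aa
preproenzyme plus stop) in 6 exons, with 5 introns at mRNA positions 87,
291, 519, 600 and 760 and lengths 66, 78, 58, 66 and 60 nt.
`derP1GeneSpec()` is the Der p 1-like relative: 5 exons (963-nt CDS, one
mature residue fewer), the intron 3 homolog absent, and a variable poly-T
tract in intron 1.

The intron lengths deserve a note. The source survey reports both a total
gene length (1278 bp for Der f 1, implying 312 nt of intron around the
966-nt CDS) *and* per-site alignment coordinates whose arithmetic implies
328 nt of upstream intron (e.g. alignment nt 1211 presented as mature
residue 197, which sits at CDS 883–885 given the 98-residue signal+pro
region). Both cannot hold at once. The presets follow the **site
coordinates**, because every downstream check — the nt→aa mapping, the
dual-species numbering, the intron mRNA positions — derives from them; the
printed total length is exercised separately as pure length bookkeeping on
an ad-hoc generator spec in the tests. The same applies to Der p 1, whose
poly-T range (10–12 nt) spans the reported 3-state gene-length spread.

## Synthetic populations

`makePopulation()` draws a diploid population from two haplotypes:

* H2 differs from the reference haplotype H1 at `nDiagnosticSites`
  biallelic sites, placed away from the start/stop codons, splice
  dinucleotides and any poly-T tract, and in distinct codons (a codon
  carrying two heterozygous sites cannot be phased from a consensus trace,
  so planting one would make the truth unrecoverable by design rather than
  by data);
* each individual draws two haplotypes independently with `P(H1) = p`,
  giving Hardy–Weinberg diplotype proportions p², 2p(1−p), (1−p)²;
* private singleton mutations arrive as Poisson(`singletonRate`) per
  individual on one chromosome copy (with `silentOnly = TRUE` they are
  confined to codon third positions with a synonymous alternative);
* consensus rendering: homozygous positions as plain bases, heterozygous
  positions as the two-base IUPAC code; with a poly-T intron each
  individual draws one tract length uniformly from the range.

Defaults mirror the surveyed Der f 1 population: 22 individuals,
`h1Frequency = 0.73` (the allele frequency implied by the reported
diplotype counts), 9 diagnostic sites (the homozygote-segregating columns
of the genotype table), `singletonRate = 0.2` (about five private alleles
across 22 individuals). A single integer seed drives all draws through R's
default generator, and the RNG state is restored afterwards, so fixtures
are byte-stable.

What the generator does **not** emulate: sequencing error, chromatogram
artefacts, indels other than the declared poly-T tract, linkage beyond the
two-haplotype structure, and codon-usage bias (bases are i.i.d. at
`gcFraction`). Passing tests therefore demonstrate correctness of the
analysis logic under clean consensus sequences, not robustness to noisy
traces.

## Variant calling and classification

A site is variant iff at least two distinct alleles are observed across
individuals after IUPAC expansion. Exonic sites carry full codon calls per
individual; a codon with one ambiguity letter expands to exactly the two
consistent codons, while a codon with two or more ambiguous positions is
phase-ambiguous under direct sequencing — it is expanded to all consistent
codons and flagged, never silently resolved. A site is non-synonymous iff
at least one pair of observed codons encodes different residues; reported
changes list the majority residue first ("W->R").

For the packaged genotype-table fixtures, the presentation convention of
such tables decides region assignment: codon-valued columns are exonic,
single-base columns intronic.

**Polymorphism density.** The survey's "percentage of mutations per
sequenced nucleotide" is printed without a stated numerator or
denominator, and none of the defensible definitions reproduces the printed
values. `polymorphismDensity()` therefore ships four explicit modes
(variant sites / gene length — the default; variant sites / total
sequenced nt; mismatches-vs-consensus / total sequenced nt; coding
variants / CDS length), always reporting numerator and denominator
alongside the percentage, and the pipeline tabulates all of them rather
than asserting any printed value.

## Two-haplotype phasing

`phaseTwoHaplotypes()` is a Clark-style resolver specialised to the
two-haplotype model (more general statistical phasing is out of scope):

1. fully homozygous individuals define candidate haplotype patterns;
   patterns within `tolerance` (default 1) mismatching sites of a more
   frequent pattern are clustered with it; more than two clusters is an
   error naming the third pattern;
2. if only one homozygote pattern exists but heterozygotes do, the second
   haplotype is derived by peeling the known haplotype from the modal
   heterozygote pattern (the classic Clark step; without it, populations
   where the minor haplotype never occurs homozygous — expected ~13% of
   the time at p = 0.9, n = 200 — would be unresolvable);
3. H1 is the haplotype with the larger homozygote count, ties broken
   towards the lexicographically smaller allele vector;
4. every individual is assigned the diplotype whose expected consensus
   (site-wise IUPAC union of the two haplotypes) matches best; 1 to
   `tolerance` mismatches assign with a warning flag, more mark the
   individual "inconsistent" with the mismatching sites listed.

The default tolerance of 1 reflects the packaged genotype tables, which
contain rows that are near-but-not-exactly consistent as printed (two
individuals cited as the recurring haplotypes differ at one intronic
site). The tables are transcribed verbatim; the phaser surfaces the
discrepancies. For the same reason the survey's printed diplotype counts
(14/4/4 of 22) are not recoverable from the table as printed — phasing the
fixture yields 15/5/0 with two inconsistent heterozygotes — and nothing in
the package asserts them. Note also that H1/H2 labels are a convention
(commoner homozygote first): at intermediate frequencies the label can
attach to either planted haplotype, which the tests gauge-fix before
comparing to truth.

## Preproenzyme coordinates

`buildCoordinateMap(signal, pro, mature, crossDeletions)` keeps all three
segment lengths explicit rather than deriving one from another: published
signal-peptide lengths and the negative-coordinate convention (signal
C-terminus at −81, cleavage between −81 and −80) are internally tangled in
the source material, and explicit lengths sidestep the knot. Valid signed
positions are −(signal+pro)..−1 and 1..mature with no 0;
`preproToMature()`/`matureToPrepro()` are exact inverses (property-tested
over 1000 random maps). Codon indexing is ceiling-based on 1-based CDS
coordinates. Cross-species numbering is a deletion set: partner position =
mature position − number of deleted positions at or before it; this covers
the Der f 1 → Der p 1 direction (deletion at mature 9, so 100→99,
216→215) and generalises to other homolog pairs. The reverse direction is
an insertion and is not expressible in this map — use the partner's map.

## Cross-species conservation

`alignProteins()` is a deterministic progressive aligner: all pairwise
global alignments (Gotoh affine DP in C++, BLOSUM62, gap open 10,
extension 0.5 — a first gap residue costs 10, each further 0.5; terminal
gaps are penalised) give 1−identity distances; a UPGMA guide tree orders
profile merges; merges are global profile–profile alignments whose column
score is the frequency-weighted BLOSUM62 expectation with gap characters
scoring 0. Exact replication of any particular external aligner is a
non-goal; published identity matrices are therefore treated as
tolerance-level references only, and the one packaged as a fixture is used
directly as tree input.

Percent identity uses columns where neither sequence has a gap as the
denominator (a stated convention, since the published matrix does not
state its own). Column conservation symbols follow the standard Clustal
strong/weak residue groups shipped as constants: `*` all identical and
gap-free, `:` one strong group, `.` one weak group. Epitope identity is
`100 × conserved/size`, rounded half-up to two decimals (matching printed
scores such as 85.71 = 12/14); an epitope position falling in an alignment
gap of the query counts as non-conserved and is flagged. Region mean
similarity averages, over the region's alignment columns (insertion
columns included), the fraction of sequence pairs with identical,
non-gap residues.

One packaged inconsistency is worth recording: the published residue-state
row for the *Acarus siro* homolog shows 6 of 14 4C1 positions conserved
(one position gapped), which gives 42.86 under any defensible counting
(42.86 with gap-as-mismatch; 46.15 excluding the gapped position), yet the
printed score beside that row is 50. The fixture preserves the residue
states verbatim, the package computes 42.86, and the corresponding
printed-value check in the test suite fails by design — the discrepancy is
in the source, not hidden by the package.

`njTree()` is classic neighbor joining (Q-criterion, Studier–Keppler
updates, ties towards the smallest index, closed-form resolution of the
final three nodes), written in-package as the distance-based substitute
for likelihood tree inference, which is out of scope. It reproduces
additive distances to 1e-9 and is cross-checked against an independent NJ
implementation in the tests. Distances from identity are
(100 − identity)/100; branch lengths may be negative, as classic NJ
allows.

## Pipeline and reproducibility

`runPipeline()` chains the stages from a single config (list or YAML),
logs each stage, stamps the package version and seed into every report
header, and writes no timestamps, so identical inputs and seed give
byte-identical bundles (asserted in the tests by re-running and comparing
files). Stage failures propagate with the stage name and input path.

## Problem sizes in the test suite

The suite chooses sizes that exercise the mathematics while keeping a full
run inside a few minutes: 100 random genes for exact model recovery,
40 small instances against the exhaustive decomposition oracle, all
64×64 ordered codon pairs against an independent translation path,
1000 random coordinate maps, 20 seeds × three haplotype frequencies ×
200 individuals for phasing recovery (on a compact 280-nt two-exon gene —
the phasing mathematics does not depend on gene length), and 20 random
additive matrices of 5–10 taxa for neighbor joining.

## Known limitations

* Exon alignment is substitutions-only: amplicons with real exonic indels
  (other than the declared poly-T tract) will fail or flag as unalignable
  rather than align.
* The phaser models exactly two recurring haplotypes plus private
  mutations; populations with three or more recurring haplotypes error out
  by design.
* The aligner is desk-scale (tens of sequences of hundreds of residues);
  it is not a general-purpose MSA tool, and no strand inference or
  multi-gene scanning is performed — amplicons are assumed given in coding
  orientation.
* Signal-peptide cleavage, tertiary structure and likelihood-based
  phylogenetics are out of scope; segment lengths are inputs, and the NJ
  tree is a distance-based summary, not a substitute for model-based
  inference.
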