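---
title: "Annotating conserved miRNA genes by homology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating conserved miRNA genes by homology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirhom)
```

## The problem

Most miRNA genes of a newly sequenced or under-annotated mammal can be
recovered without new wet-lab work, because precursor miRNAs (pre-miRNAs,
the ~60-110-nt stem-loop intermediates from which ~22-nt mature miRNAs are
excised) are strongly conserved. `mirhom` implements that annotation
strategy as a tested pipeline with four stages:

1. **Homology search.** Every reference precursor is mapped onto the target
   genome (both strands) by exact k-mer seeding and banded-alignment
   scoring. A candidate locus must satisfy three criteria: full-length
   precursor identity strictly above 93 %; for every annotated mature arm,
   at most one mismatch in the seed (mature positions 2-8) and at most two
   outside it; and a one-to-one assignment of each genomic locus to its
   best-matching reference (one reference may still own several
   non-overlapping paralogous loci, as mir-548-type families do).
2. **Hairpin validation.** Each candidate, extended by 10 nt of genomic
   context on each side, must fold into an acceptable stem-loop: the mature
   sequence entirely within one arm of the stem, no internal loop or bulge
   of 6 nt or more (counting the larger side), and a minimum free energy of
   at most -15 kcal/mol. Candidates passing all three and carrying outside
   support (annotated as a miRNA in another species, experimentally
   supported homolog, or previously reported in the target species) are
   *high confidence*.
3. **Small RNA-seq quantification.** Multi-individual libraries are
   QC-filtered (adapter/primer reads; reads with more than 10 % N; more
   than 50 % low-quality bases; inserts shorter than 18 nt), collapsed to
   unique tags, placed on the genome by perfect full-length matching,
   stripped of tags touching rRNA/tRNA/snRNA/snoRNA/repeat features or
   exons, and assigned to mature miRNAs. A mature is called expressed when
   it has at least 10 reads summed over samples and is detected in at least
   3 individuals. Expression is normalised to transcripts per million:
   reads for the miRNA divided by the sample's clean reads, times 10^6.
4. **Genomic characterisation.** High-confidence loci are classified as
   intergenic, intronic, exonic (with a UTR sub-class) or
   splice-site-overlapping; antisense (mirror) pairs are overlapping loci
   on opposite strands; loci on one strand whose neighbours lie within
   10 kb form clusters, labelled homo-seed when all members share the
   7-nt seed of their dominant mature and hetero-seed otherwise; each
   miRNA receives a conservation age (vertebrate, mammal, primate,
   Cercopithecidae) from its homolog species set; and age is correlated
   with mean expression by Spearman rank correlation (older coded higher,
   so a positive rho means older miRNAs are more highly expressed).

## Thermodynamic engine

Folding is delegated to ViennaRNA's `RNAfold` (Turner nearest-neighbour
parameters, 37 °C), the standard engine for this task; `mirhom` owns the
structure analysis (dot-bracket parsing, stem dissection, bulge metric,
criteria). The test suite verifies the folding route against an exhaustive
enumeration oracle: for hundreds of random 15-25-mers, every non-crossing
canonical structure is generated and scored with `RNAeval` (the same
energy rules), and the minimum must equal the reported MFE. The MFE
threshold comparison is `mfe <= -15.0` exactly ("no more than -15").

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `identity` | 93 | % | strict lower bound on full-precursor identity |
| `seed_mm` / `nonseed_mm` | 1 / 2 | mismatches | per mature arm, seed = positions 2-8 |
| `mfe` | -15 | kcal/mol | hairpin stability bound (inclusive) |
| `bulge` | 6 | nt | largest internal loop/bulge side must be < 6 |
| `flank` | 10 | nt | genomic context folded with the locus |
| `cluster_gap` | 10000 | nt | edge-to-edge gap joining cluster neighbours |
| `min_reads` / `min_individuals` | 10 / 3 | reads / samples | expression call |
| `scan_k` | 12 | nt | seed k-mer length of the genome scan |
| `scan_floor` | 85 | % | identity floor for raw hits, below the filter |
| low-quality base | Phred < 20 | - | QC rule 3; the cutoff is configurable |

Decisions taken where the procedure was genuinely open:

* **Cluster gap metric.** "Within 10 kb" is read as the edge-to-edge
  separation (`next start - previous end - 1`), not start-to-start, and
  the pairwise rule is chained transitively; only chaining can produce the
  multi-ten-kilobase polycistrons (40+ genes) that clustered miRNA regions
  are known to form. Both the metric and the threshold are arguments.
* **Bulge counting.** For an internal loop with unpaired stretches on both
  sides, the larger side is counted and the `n < 6` rule applies to the
  maximum over the stem. Counting both sides would make the criterion
  stricter; the larger-side convention matches how bulge size is usually
  quoted for single bulges.
* **Locus deduplication.** Two same-strand hits conflict when they overlap
  by at least half of the shorter one; the higher-identity reference wins,
  ties go to the lexicographically smaller name, making runs reproducible.
* **Read-to-mature assignment** allows a 2-nt 3' trimming tolerance and up
  to two non-seed mismatches but zero seed mismatches - the stricter
  reading, since the seed defines miRNA identity. Tags matching several
  identically named matures are counted once per mature name, and a mature
  encoded by several precursors yields one expression record listing all
  of them. The >= 10-read support threshold is applied per mature, and a
  precursor counts as expressed if either arm passes.
* **QC attribution** follows the rule order (adapter, N content, quality,
  length): a read failing several rules is tallied under the first. The
  adapter detector scales its mismatch allowance with the overlap length
  (10 % error rate, capped at 2), so short chance overlaps must match
  exactly; full-length adapter alignments get the quoted
  "fewer than three mismatches".
* **Averages** in the per-library summary table are reported to the
  nearest integer (x.25 reports as x), reproducing the arithmetic of the
  published per-sample table.

## The synthetic truth set

`generate_truth_set()` plants miRNA hairpin loci with known coordinates in
a random three-chromosome genome (540 kb by default, 30 loci), then
`simulate_libraries()` emits four individual libraries of 100,000
fixed-length reads. The generator emulates:

* **Hairpins that really fold.** Each locus is an arm/loop/arm construct
  (30-bp stem, 2 wobble substitutions, A/C loop) rejection-sampled until
  its MFE structure is a single clean hairpin with both matures inside the
  arms, and the 10-nt genomic flanks are resampled until the flanked
  sequence folds cleanly too. Matures that would mimic the sequencing
  adapter are rejected, since their reads would be unrecoverable by
  design.
* **Age-structured expression.** Mean expression scales 160:10:1 for
  vertebrate-, mammal- and primate-conserved loci, with
  Cercopithecidae-specific loci lower still (0.3), matching the reported
  order-of-magnitude gaps; per-sample counts are negative binomial
  (dispersion 0.2) around those means, and the 5p arm carries 75 % of a
  locus's reads.
* **Genomic organisation.** Two planted clusters (a 3-member homo-seed and
  a 2-member hetero-seed), one antisense mirror pair built from a
  perfectly Watson-Crick stem so both strands fold, host genes with exons
  placed to make loci intronic, exonic, UTR-resident or
  splice-site-overlapping, and rRNA/tRNA features that seed
  QC-surviving structural noise.
* **Noise classes.** Adapter dimers, high-N reads, low-quality reads and
  short inserts (removed by the four QC rules) plus rRNA/tRNA fragments
  (removed at annotation filtering), at 4/2/4/5/10 % of each library.
* **Divergence.** Reference homologs differ from the planted loci by two
  substitutions placed outside the mature seeds, exercising the mismatch
  rules without crossing them.

What the simulation does **not** model - and what passing tests therefore
do not demonstrate about real data: sequencing errors (an option exists
but is off by default), ligation and GC bias, isomiR end heterogeneity,
degradation products of the planted precursors, multi-mapping between
near-identical paralog families at genome scale, and genome assembly
artefacts. Recovery rates on the synthetic study are an upper bound.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive with an explicit strand throughout;
  BED export converts to 0-based half-open and back losslessly.
* All sequence comparison maps U to T first; genome slices for
  minus-strand loci are reverse-complemented before any comparison.
* The banded aligner (band ±3) maximises matches, breaks ties toward
  fewer gaps, and scores gap columns as mismatches in the identity.
* An all-unpaired fold reports MFE 0.0; structures with several terminal
  loops are flagged non-hairpin rather than dissected.
* Empty candidate sets, zero-expression matures and single-sample
  summaries are all defined; a zero clean-read total is an error rather
  than an infinite TPM.
* Problem sizes in the tests: the enumeration oracle runs on 15-25-mers
  (500 cases), cluster brute force on up to 200 loci (100 cases), scan
  equivalence on 45-kb genomes, and the end-to-end study on the default
  30-locus truth set with four 100k-read libraries.

## Known limitations

* The homology scan's exact k-mer seeding can miss hits near the identity
  floor when mismatches are adversarially spaced; at the default
  thresholds (93 % filter over 60+-nt precursors) the guaranteed seed run
  is ample, and the property tests verify equivalence with a full slide.
* Hairpin validation folds one MFE structure; suboptimal structures and
  the partition function are out of scope, as are pseudoknots.
* Family grouping beyond seed identity (curated family tables) is not
  implemented; homo-/hetero-seed cluster classes use the dominant-arm
  seed, configurable to 5p-always.
* Synteny-based comparison of clusters to a second genome is out of
  scope.
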