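---
title: "Building and comparing A-to-I editomes across genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing A-to-I editomes across genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomer)
```

## The biology and the measurement problem

ADAR enzymes deaminate adenosine to inosine in double-stranded regions of
RNA. Inosine base-pairs like guanosine, so an edited position shows up in
RNA sequencing as an A-to-G mismatch against the genomic reference (or
T-to-C when the read maps to the reference minus strand of a minus-strand
transcript). The genome-wide catalogue of such positions — the *editome* —
shifts when editing is dysregulated, for instance when one *Adar* allele is
lost while chronic double-stranded RNA (here, the product of a transgenic
picornaviral RNA-dependent RNA polymerase, "RdRp") keeps the MDA5–interferon
axis active. This package reconstructs that comparison for a four-genotype
design: wild type, the *Adar* heterozygote, the RdRp transgene carrier, and
the double heterozygote carrying both, each with n biological replicates
(default 4).

Calling an editome from RNA alone is confounded by germline variation: a
heterozygous genomic A/G SNP looks exactly like a ~50%-edited site. The
pipeline therefore takes a per-line exome variant set (VCF) and removes
every candidate whose position appears in it. Exclusion keys on position
only, not allele — the conservative reading of "remove any colony-specific
SNP": if the exome says the position is variable in DNA, it cannot be
claimed as an RNA-DNA difference.

## The pipeline, stage by stage

**Candidate calling** (`call_edit_sites`). Each sample's pileup (per
position: reference base and A/C/G/T read counts) is scanned for the A-to-I
signature only: reference A with G reads, or reference T with C reads.
Every other mismatch class is ignored by construction. A position is
emitted iff

* coverage ≥ `min_coverage` (default 10 reads),
* edited reads ≥ `min_edited` (default 2 reads),
* edit fraction in [`min_fraction`, `max_fraction`) (default [0.05, 0.95)).

The source study states no thresholds, so these follow common
editing-caller practice and are explicit, configurable parameters rather
than reconstructions of anyone's settings. The half-open fraction ceiling
is a homozygous-variant guard: a position where essentially every read is G
is a genotype (or an SNP missed by the exome), not editing. The caller also
cross-checks the pileup's reference column against the genome and refuses
corrupt input, naming the first offending position.

**SNP exclusion** (`exclude_snps`), described above; order-preserving,
no-op on an empty variant set.

**Strand orientation** (`orient_edits`). "A-to-I" is defined on the
transcribed strand. A reference-strand A>G change under a + strand gene is
a genuine edit; the same change under only a − strand gene cannot be (on
the transcript it would be U-to-C), and is discarded. Intergenic sites
cannot be oriented; they are kept and flagged `ambiguous` by default,
because intergenic editing is a major category of the editome, with a
`drop_ambiguous` switch for the strict dialect.

**Feature attribution** (`feature_index`, `annotate_sites`). Each site
receives exactly one RNA-element category by a priority ladder evaluated
over all genes overlapping the position:

3'UTR > 5'UTR > CDS exon > intron > intergenic.

UTRs outrank CDS because the comparison reports 3'UTR editing separately
from "exons"; "exon" is implemented as CDS-exon so the five categories are
disjoint and partition the sites. The 5'UTR is carried as its own category;
`region_distribution(collapse_utr5 = TRUE)` folds it into CDS exon for a
four-category breakdown. Where several genes' features of the same rank
overlap a position, the lexicographically smallest gene id wins, making
annotation deterministic and input-order-independent. Repeat attribution is
orthogonal to region attribution — a 3'UTR site inside a SINE carries both
labels, which matters because ISG 3'UTRs are rich in retroelements. When
repeat intervals overlap, the smallest interval wins, with ties broken by
class priority (LINE > SINE > DNA transposon > other retroelement) and then
leftmost start. Intervals are handled as 1-based closed coordinates
throughout (the GenomicRanges convention), converted only at file
boundaries (BED stays 0-based half-open on disk); each point therefore
belongs to exactly one interval of any disjoint set, the same semantics a
0-based half-open representation would give.

**Consensus editomes** (`consensus_sites`, `consensus_genes`). A site
belongs to a genotype's consensus iff the identical (contig, position,
change) triple is called in *every* replicate — the n-fold set
intersection. A gene belongs iff every replicate has at least one call
annotated to it, anywhere in the gene, so the consensus gene set always
contains (and usually exceeds) the genes of the consensus sites. Edit
fraction is deliberately not part of site identity: the comparison counts
sites, it does not compare editing levels. The all-replicates rule is
absolute by default; `min_replicates` exists as an escape hatch but
defaults to n. Consensus sites are annotated against the shared genome
annotation, never per replicate, so their attribution is
replicate-invariant by construction.

**Genotype comparison** (`compare_editomes`, `venn_partition`). The four
consensus site sets and gene sets are partitioned into the 15 disjoint
four-set Venn cells; the singleton cells are each genotype's uniquely
edited sites and genes. The summary object also carries the per-genotype
counts table (sites, genes, per-category and per-repeat-class counts),
region distributions, and the double-het/WT consensus-site ratio — the
statistic behind the editing excess in the double heterozygote.

**ISG expression summaries** (`normalize_log`, `test_differential`,
`classify_isg_fraction`, `isg_proportion_test`). Counts are normalized to
CPM (FPKM-like if gene lengths are given) and log2-transformed with one
pseudocount. Differential expression between two genotypes uses a per-gene
Welch (unequal-variance) t-test on the log scale with Benjamini–Hochberg
correction; a gene is flagged DEG at |log2FC| ≥ 1 and q ≤ 0.05. The study's
own DE engine is unnamed in its methods, so this module's claims are about
its own defined statistics, not about reproducing any specific published
DEG list; the thresholds are arguments. ISG membership comes from a
user-supplied reference list (one gene per line) — ISG databases are
versioned, external resources and are not bundled. Genes with zero
variance in both groups get p = 1 when means are equal and p = 0 otherwise,
a stated degenerate-input convention. Whether uniquely edited sites
concentrate in ISG transcripts is tested on the 2×2 table of uniquely
edited *genic* sites (in-ISG vs other) for two genotypes, with a two-sided
conditional exact test: with margins fixed, p is the sum of hypergeometric
probabilities of all tables no more probable than the observed one — the
common two-sided convention, implemented by direct enumeration and checked
in the tests against full binomial-coefficient enumeration and
`fisher.test`. Intergenic unique sites carry no gene and are excluded from
the table by default; `intergenic = "nearest"` instead assigns each one
its nearest annotated gene. The odds ratio is ad/bc with the Haldane 0.5
continuity fallback when a cell is zero, and a zero margin marks the
result untestable rather than producing a meaningless p.

## What the synthetic generator emulates

The original editome was built from whole-genome mouse RNA-seq and exome
data that are not redistributable at desk scale, so every stage here is
validated by *parameter recovery* on synthetic data in which the truth is
planted:

* **Genome** (`sim_genome`): 2 contigs × 100 kb carrying 40 genes with
  exon/intron structure, 5'UTR/CDS/3'UTR partitions (3'UTRs ~30% of the
  exonic span), and repeat intervals of the four retroelement classes,
  with a SINE seeded into each ISG 3'UTR. The scale is chosen so every
  category is represented and a full 16-sample study simulates and
  analyses in seconds; genome size is irrelevant to the logic being
  tested.
* **Truth** (`plant_truth`): per-genotype active-site sets built from a
  shared core plus genotype-private extras, all on transcript-strand
  adenosines. Defaults: 500 WT sites, single mutants at 0.94× and 1.0×,
  and the double heterozygote at exactly 1.6× — the midpoint of the
  observed 50–65% excess — with its private extras weighted toward 3'UTRs,
  LINE/SINE overlaps and ISG genes, reproducing the reported 3'UTR /
  retroelement shift. Editing is gene-targeted: each genotype's genic
  sites fall in a shared editable gene set (50% of genes) plus a private
  set (10/5/7.5/20% for WT/Adar-het/RdRp/double-het), so genotypes differ
  in edited genes as well as sites, and the gene-level Venn is
  informative. Per-site edit fractions are uniform on [0.2, 0.8].
  Heterozygous A>G / T>C SNPs (default 60) are placed in exonic —
  exome-captured — space, never on an edit site.
* **Pileups** (`sim_pileups`): per-position coverage is negative binomial
  (default mean 30, size 8) scaled by a per-gene log-normal multiplier
  (sdlog 0.3), so calling is exercised under realistic depth variance.
  Sequencing error is a uniform per-base substitution to each of the three
  non-reference bases, default 0.3%. At an active truth site with fraction
  f the edited-base count is Binomial(c, f(1−e) + (1−f)e/3); at an SNP the
  alt fraction is centred at 0.5; everywhere else mismatches arise only
  from error.
* **Expression** (`sim_expression`): negative-binomial counts around
  baseline × genotype multiplier. ISG multipliers are tiered — 2–5× in the
  *Adar* het, 20–100× with the transgene, 200–600× in the double het,
  matching the order-of-magnitude ISG elevations reported for these
  genotypes. ISGs start from a low (quiescent) baseline, as
  interferon-stimulated genes do without stimulation, and the matrix
  carries 3000 inert background transcriptome rows so that massive ISG
  induction remains a modest fraction of library mass: without these two
  choices, CPM normalization at a 40-gene scale would turn the ISG burst
  into spurious global "downregulation", an artifact of the miniature
  gene universe rather than a property of the statistics. A
  `RdRp_transgene` pseudo-gene row is expressed only in transgene-bearing
  genotypes.

Every generator is a pure function of its configuration and a seed;
per-stage sub-seeds are derived deterministically from the one top-level
seed (`seed × 7919 + hash(stage)`, modulo 2^31), so each stage and each
sample is independently reproducible.

What the generator does **not** emulate: read-level artifacts (alignment
error, soft-clipping, strand bias), hyper-edited read clusters,
base-quality variation, allele-specific expression, non-A/G SNP classes,
and isoform structure. Passing recovery tests therefore demonstrates that
the set logic, filtering rules and statistics are correct under the stated
generative model — not that the thresholds are optimal for any particular
real aligner's error profile.

## Numerical and design choices

* Internal coordinates are 1-based (closed intervals), converted at file
  boundaries only; round-trip tests cover FASTA, GFF3, BED (0-based
  half-open on disk) and VCF.
* Site identity is (contig, pos, reference-strand change); per-site depth
  floors at the consensus step, and fraction-aware identity, are
  deliberately not applied.
* "Intergenic" and "extragenic" are treated as a single category
  (annotated-gene complement); the alternative reading — two distinct
  categories — is not implemented.
* The exact 2×2 test uses a relative tolerance of 1e-7 when comparing
  table probabilities, the same guard `fisher.test` uses against floating
  tie-breaking.
* Degenerate inputs have defined behaviour rather than silent defaults:
  empty region distributions report NA proportions, zero-margin 2×2 tables
  are flagged untestable, zero-total-count samples are an error in
  normalization, and a replicate with zero calls yields an empty (not
  missing) consensus.

## Study sizes used in the validation suite

The packaged tests and the acceptance script run the full default study
(2 × 100 kb genome, 16 samples at mean depth 30), a 2,000-site recovery
experiment at planted fraction 0.3, 500-instance randomized consensus
checks, exhaustive exact-test enumeration for all tables with margins ≤
12, and 100-replicate null simulations for FDR control — sizes at which
the stochastic tolerances quoted in the tests (e.g. recall within 0.03 of
0.90) are comfortably resolved on a laptop-class machine.

## A worked run

```{r pipeline, eval = FALSE}
res <- editome_pipeline(seed = 1)
print(res$comparison)
res$isg_fraction$summary
res$proportion_test
```

The comparison object prints per-genotype consensus gene/site counts, the
uniquely edited sets, and the double-het/WT site ratio; with the default
generator the ratio recovers the planted 1.6 to within the consensus
attenuation (~1.5–1.6), the 3'UTR proportion roughly doubles in the double
heterozygote, and the DEG list is dominated by the planted ISGs.

## Known limitations

Consensus recovery attenuates with replicate count (a site must survive
calling in all n replicates, so consensus recall is roughly the
single-sample recall to the n-th power); the reported ratio is robust to
this because the attenuation applies to numerator and denominator alike,
but absolute consensus counts undershoot the planted counts by design.
The Welch/BH stand-in is not a negative-binomial GLM; at n = 4 it is
conservative for low-count genes. The proportion test conditions on both
margins and is conservative for small tables, as all conditional exact
tests are.
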