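---
title: "Methods: annotation improvement and stage comparison with txforge"
author: "txforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation improvement and stage comparison with txforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txforge)
```

## The problem

Insect genome annotations are frequently incomplete: gene models miss
5'/3' UTR sequence, coding sequences lack start or stop codons, whole
genes are absent, and repeat-element expression is rarely quantified.
txforge implements the computational core of a reference-guided
annotation-improvement and stage-comparison workflow for a two-condition
ovarian RNA-seq design — an early previtellogenic stage (PVS, the
tropharium plus early egg chambers) versus mature eggs, two biological
replicates each. In this design the egg is transcriptionally quiescent,
so transcripts detected there were maternally deposited; comparing the
two stages therefore reads out maternal RNA deposition.

Every stage of the workflow can be exercised against synthetic data with
a planted, machine-readable ground truth (the *truth ledger*), so the
package's correctness claims are set-equalities against known answers
rather than eyeballed summaries.

## Transfrag classification and annotation update

Assembled transcript fragments ("transfrags") are compared with the
reference annotation through their **intron chains** — the ordered list
of splice-junction coordinates:

* `=` — the chain is identical to a same-strand reference transcript.
  Terminal-exon boundary changes do not break the match; this is what
  lets an `=` transfrag extend a gene's UTRs.
* `j` — multi-exon, same strand, shares at least one junction with a
  reference transcript but not the whole chain: a candidate novel
  isoform.
* `u` — no exonic overlap with any reference transcript on either
  strand: a candidate novel intergenic gene.
* `other` — everything else (for example antisense overlap, or a
  transfrag spanning two same-strand genes); excluded downstream.

Junction equality is exact coordinate equality — no fuzz window. The
synthetic transfrags are exact, and wobble-tolerant matching belongs to
real-data preprocessing, which is out of scope here.

Novel isoforms must clear three filters: at least 20 supporting read
pairs, abundance at least 40% of the gene's major isoform (compared in
the candidate's strongest condition), and CPM above 1 in at least one
condition. Novel genes are clusters of sufficiently supported `u`
transfrags linked by same-strand exonic overlap; single-exon transfrags
are eligible (the multi-exon requirement belongs to the isoform
definition only). Gene extensions are measured strand-aware on the
genomic termini of the gene span (union over isoforms); a per-isoform
spliced-distance variant would differ for truncations crossing introns,
which the generator deliberately avoids (below).

## ORF discovery and completeness

ORFs are scanned per reading frame with the standard genetic code and
ATG as the only start. Each stop-delimited segment contributes its
maximal ORF: `complete` (ATG…stop), `5prime_partial` (sequence start to
a stop with no upstream in-frame ATG), `3prime_partial` (ATG to the
sequence end), or `internal` (the frame is open across the whole
sequence). Reported calls need at least 100 codons (excluding the
stop), matching the common predictor default. Oriented transcripts are
scanned forward-only; orientation-unknown contigs six-frame. When one
sequence carries several ORF types, the most complete wins; the
preference of 5'- over 3'-partial in that ordering is a package
convention (the underlying rule does not rank the two partial types).
Homology evidence for ORF retention is intentionally not implemented —
length is the sole criterion, with an optional protein-set match in the
de novo route.

## Unmapped-read rescue and contig deduplication

Unmapped reads are trimmed of terminal poly-A (3') and poly-T (both
ends) runs longer than 4 nt, then kept when longer than 25 nt with GC
above 20% — all thresholds strict. The symmetric A/T end policy is a
declared convention; the underlying tool chain does not fully specify
it.

Contigs pass a fixed cascade: stage-level TPM ≥ 10, within-stage
deduplication, an external quality gate (a pass/fail table hook; no
score is computed here), coding classification, cross-stage
deduplication, and a final estimated-reads ≥ 20 filter. Deduplication
is greedy clustering at 95% nucleotide identity: contigs sorted by
length descending, each joining the first representative it matches,
identity defined as aligned matches over the length of the shorter
sequence (the convention of the standard clustering tool, which
reproduces its grouping on near-duplicates of unequal length). For
thresholds ≥ 0.95 an exact shared-11-mer prescreen skips hopeless
alignments: a qualifying alignment must contain an exact run of ≥ 19 nt,
so the screen cannot change the result. Repeat-novelty calls compare a
contig to a consensus library; `known` needs identity ≥ 0.8 with ≥ 50%
contig coverage, a weaker alignment (≥ 30 nt at ≥ 60% identity) is a
`novel` variant, anything less `no_hit`. Both thresholds are exposed as
arguments since the underlying study states neither; the homology step
is a seeded ungapped extension rather than full gapped alignment, which
is exact on the synthetic truths and deterministic at desk scale.

## Repeat-class quantification

Repeat features of the same class and strand that strictly overlap are
merged transitively (adjacent features stay separate); only merged
regions longer than 0.5 kb are quantified — merging always precedes the
length filter, so fragmented long elements are not lost. Each genomic
placement of a read pair contributes weight `1/n_hits` to the features
it overlaps (one shared base suffices; assignment is unstranded because
the library strandedness is not specified). Ambiguity is decided at the
pair level: a pair whose placements touch more than one element class
(gene versus each repeat class) contributes its full weight to an
ambiguous bucket instead. Per sample, assigned + ambiguous + excluded +
unassigned equals the pair count exactly — this conservation identity is
asserted in the tests.

## Quantification and differential expression

Gene-level pair counting excludes pairs that are not both-ends-aligned
on one contig and strand, counts unique placements by default, assigns
a pair to the gene with the largest overlapped base count, and counts
exact ties once for each tied gene (the counting tool's documented
behaviour for its overlap flag), with a strict-largest mode available.
CPM uses total assigned pairs as the library size (the "total mapped
reads" denominator is ambiguous in the source description; total
assigned is the documented default). Genes need CPM > 1 in at least two
of the four samples to be tested.

Between-sample normalization is the trimmed mean of M-values (TMM):
reference sample by upper-quartile proximity, per-gene log ratios
trimmed 30% by M and 5% by A, inverse-binomial-variance precision
weights, factors rescaled to geometric mean 1. The implementation is
self-contained and is cross-checked in the tests against an independent
step-by-step evaluation (to 1e-6) and against the established edgeR
implementation.

The DE engine is a self-implemented negative-binomial Wald test, not a
wrapper: per gene, mean `mu_ij = s_j q_i 2^(x_j beta)` with size factors
`s_j`, fitted by IRLS. Dispersion is estimated by the method of moments
on group-centred normalized counts and then pooled through a lowess
mean–dispersion trend ("fit-only" sharing), whose fitted value is used
per gene with a floor of 1e-8. The pooling is the one genuinely open
design choice here: at two replicates per group the raw gene-wise
moment estimate has so few degrees of freedom that a plug-in normal
Wald is anticonservative, while switching the reference distribution to
a residual-df t destroys power at stringent FDR thresholds. The trend
keeps the normal Wald calibrated (measured type-I error ≈ 0.05 at
nominal 0.05 under the simulated null) without per-gene empirical-Bayes
shrinkage, which stays out of scope as an extension hook. The cost is
that per-gene departures from the mean–dispersion trend are not
modelled; on real data with dispersion outliers the test would be
liberal for those genes.

A gene is called differentially expressed at BH-adjusted p ≤ 0.01 and
linear fold-change ≥ 2.5 (or ≤ 1/2.5); "up" means higher in Egg.
"Fold-change 2.5" is read on the linear scale — the conventional reading
of an unqualified fold-change — with a log2-scale mode behind a flag,
since the source description does not disambiguate. Top-k tables rank
DEGs of one direction by mean CPM in that direction's condition after a
caller-supplied exclusion set (for example ribosomal-protein genes).
Enrichment is an upper-tail hypergeometric test per term against a
caller-supplied term map over a background, BH-corrected over terms
with at least one selected gene at FDR ≤ 0.05 — a deliberate
re-implementation of the database-backed enrichment service as a pure
statistical primitive.

## The synthetic-data generator

The generator emulates the two-condition, two-replicate design with a
recoverable ground truth. Defaults (all in `sim_config()`): 200
multi-exon genes on 4 × 300 kb contigs at GC 0.42; 10% of genes and 10%
of second isoforms dropped from the "reference"; UTR truncations at
each end with probability 0.5 and uniform 50–450 bp lengths; NB counts
with log-normal baseline means (median 300) and dispersion 0.05; 10% of
genes carry a planted |log2FC| = 2 (up = higher in Egg); transfrag
support is 80% of a transcript's pairs; a repeat landscape of
Tc1-mariner, Helitron, Tc1, Unknown and Satellite copies (the dominant
classes of the triatomine mobilome) with 30% within-class overlap, 30%
multi-mapping and 3% cross-class placements; and an unmapped pool
mixing dropped-gene reads with 15% poly-A-tailed and 15% low-GC junk.

Several generator choices exist purely to make ground truth exact
rather than statistical:

* CDS bodies are sampled from codons excluding ATG and the stops, and a
  rejection step re-draws any gene whose transcript carries a
  reportable ORF other than the annotated CDS. ORF-completeness truth
  is therefore unambiguous.
* Exon-skipping isoforms skip a middle exon whose length is not a
  multiple of 3, and the pre-skip CDS stays under 100 codons, so the
  variant frameshifts and cannot carry its own complete ORF that would
  mask the primary isoform's completeness after truncation.
* UTR truncations are confined to terminal exons, so spliced and
  genome-projected truncation distances coincide and the extension
  recovery check is an exact vector equality. Truncations entering the
  CDS remove at least 6 bp of it and jointly (both ends) leave at least
  `min_aa + 5` codons, so a truncated reference ORF is partial, never
  absent.
* Repeat copies avoid gene spans and copies of other classes, so
  cross-class ambiguity is controlled by the multi-mapping rate rather
  than placement accidents; same-class overlaps are planted on purpose
  to exercise merging.
* Genes are placed without genomic overlap (a stronger condition than
  the per-strand requirement), keeping classification and counting
  oracles unambiguous.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequencing errors, positional coverage
bias, fragment-length distributions, assembler failure modes beyond
support noise, overlapping or nested genes, dispersion outliers, and
real repeat-family sequence divergence. Library sizes are free
parameters: the source study publishes no per-stage figures usable for
calibration at desk scale.

## Numerical and determinism notes

Internal coordinates are 0-based half-open with a single conversion
boundary in the io layer (external GTF/GFF is 1-based inclusive), which
makes round-trips byte-exact and testable. All generator stages derive
their RNG streams from one seed plus fixed offsets, so a config is
reproducible end to end; the JSON run report omits wall-clock timings
(returned in the R object instead) so reruns are byte-identical. Ties
are always broken lexicographically (major isoform, cluster
representatives of equal length, locus ordering). Degenerate inputs
(empty annotation, all-zero samples, empty repeat library) raise typed
errors or return empty results as documented rather than being
silently repaired.

Problem sizes used by the tests and the acceptance script — 200 genes,
2,000 null plus 500 planted-DE genes, 200 contigs for clustering, a few
thousand repeat pairs — were chosen as the smallest sizes at which the
recovery identities are non-trivial and the calibration estimates have
usable precision.

## Known limitations

* The DE test has no dispersion shrinkage; genes far off the
  mean–dispersion trend are tested liberally.
* One-group-all-zero genes pass the CPM filter in principle but their
  Wald statistics are unstable (the usual motivation for shrinkage).
* The homology routines (protein seeds, repeat novelty) are ungapped;
  diverged repeats with indels would be under-called `novel` rather
  than `known`.
* BAM/SAM ingestion, assembler internals, quality-score computation,
  and database-backed enrichment are out of scope by design; the
  corresponding inputs arrive as files in the simplified formats the
  io layer documents.
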