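---
title: "Methods: supervised in-silico evaluation of candidate fusion transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised in-silico evaluation of candidate fusion transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-seq is the workhorse for detecting fusion transcripts — chimeric RNAs
joining exons of a 5' partner gene (geneA) and a 3' partner (geneB, written
geneA::geneB). Prediction tools disagree substantially, and apparent fusions
arise not only from genomic rearrangement but from read-through
transcription, *cis*/*trans*-splicing, reverse-transcription mispriming and
read misalignment. `fuseval` re-examines the alignment evidence for a
*given* list of candidates: it quantifies support for the fusion against
counter-evidence for the unfused partners, computes sequence features at the
breakpoint, filters weakly supported variants, and classifies each variant's
feature profile as resembling known oncogenic fusions ("COSMIC-like"),
resembling artifacts, or other.

## Fusion contigs and coordinates

For each candidate, the two partner genes are extracted from the genome and
concatenated into one contig in collinear transcribed orientation
(minus-strand genes are reverse-complemented so both read 5'→3' left to
right; geneA precedes geneB with no spacer, and `geneB_offset` marks the
junction of the gene territories). Introns longer than `max_intron`
(default 1000 bases) are shrunk by removing their central region, keeping
the first ⌈max/2⌉ and last ⌊max/2⌋ bases. Keeping the two flanking halves —
rather than some other subsequence — preserves ≥ 500 bases around every
splice site, so donor/acceptor dinucleotides are always intact on the
contig.

All internal coordinates are 0-based half-open; GTF/SAM conventions
(1-based inclusive) are converted only at I/O boundaries. The genome↔contig
map is piecewise linear and invertible on every retained base; bases removed
by shrinking map to no contig position. Gene span is the merged-exon extent
(no promoter/UTR padding — no flank size is specified by the method), and no
cap is placed on gene span in the builder (the 100 kb limit in the original
tool is an aligner-stage parameter, out of scope here). Overlapping
transcripts are kept both per-transcript and as a merged exon union; the
union view is what breakpoint/annotation agreement is tested against.

## Evidence classes and per-read QC

Each aligned fragment receives exactly one class:

* **SPLIT** — a read whose alignment crosses `geneB_offset` through a
  junction gap (CIGAR `N`), defining the breakpoint pair
  (last aligned base of the 5' segment, first aligned base of the 3'
  segment). Requires ≥ 10 aligned bases (anchor) on each side of the
  junction, anchor entropy ≥ 1.2 bits, ≥ 98% identity and ≤ 10 clipped
  bases per read end.
* **SPANNING** — mates aligned concordantly and wholly on opposite sides of
  `geneB_offset`, each read with entropy ≥ 1.2 and passing identity/clip
  rules.
* **COUNTER_5P / COUNTER_3P** — an alignment wholly within one gene segment
  overlapping a candidate breakpoint by ≥ 10 aligned bases on each side,
  supporting the unfused partner. The 10-base requirement mirrors the split
  anchor rule (the method states only that such fragments "span" the
  breakpoint).
* **BACKGROUND** — anything else passing QC; **DISCARD** — QC failures.

Design notes: identity is `(aligned length − edit distance) / aligned
length`, so indel bases count as errors; anchor entropy is computed on the
*read* bases adjacent to the junction (reference bases would differ only
under sequencing error; the choice is configurable in principle and noted
here because the method text does not specify it); duplicates are not
collapsed; orphan mates are treated as single-end and can be SPLIT or
COUNTER but never SPANNING. Counter evidence requires candidate breakpoints,
which come from split reads — classification therefore runs in two passes
(split/spanning first, counter re-screening second).

## Quantification

Split reads are unique to their breakpoint; spanning fragments are often
compatible with several variants of one fusion (their insert brackets more
than one junction). A kallisto-style EM fractionally assigns them: starting
from uniform abundances, the E-step splits each ambiguous fragment across
its compatible variants proportionally to current abundances, the M-step
sets each abundance to unique splits + fractional spanning, iterating to
`tol = 1e-6` (ties stay symmetric; no jitter). The EM conserves spanning
mass and its full multinomial likelihood is non-decreasing (both are tested
properties).

Expression summaries:

* `FFPM = fragments × 10⁶ / total fragments`. The denominator is the total
  sequenced fragment count, supplied by configuration or counted from the
  SAM (including unmapped records); the source used is logged. The numerator
  uses the EM-estimated total by default (raw counts are a config switch —
  the method text does not say which is used for FFPM, and EM-estimated is
  consistent with its quantification section).
* `FAR = (fusion + 1) / (counter + 1)` per partner side. The +1 pseudocounts
  are a design choice: strong fusions frequently have *zero*
  breakpoint-spanning counter reads and the raw ratio would be infinite;
  the pseudocount keeps the feature finite and ordering-faithful.

A cohort-level helper implements the tumor-enrichment score
`((tumor_with+1)/tumor_total) / ((normal_with+1)/normal_total)`.

## Breakpoint sequence features

* **Splice dinucleotides** — donor = 2 contig bases after the left break,
  acceptor = 2 bases before the right break; consensus defaults to GT–AG
  (GC–AG and AT–AC can be added to the consensus set by configuration).
* **Reference agreement** — the left side agrees if the break equals an
  annotated exon 3' end of geneA (transcribed orientation, merged-exon
  view), the right side if it equals an exon 5' start of geneB. Splice type
  is `ONLY_REF_SPLICE` (consensus + both agree), `INCL_NON_REF_SPLICE`
  (consensus, novel boundary) or `NON_CANONICAL` (non-consensus).
* **Microhomology** — every exact k-mer (k = 10) shared between the geneA
  and geneB segments, enumerated as all start-position pairs (not merged
  into maximal matches: the count follows the literal exact-k-mer
  definition; a merged view would undercount overlapping homologies).
  Counted per contig; locality is carried by the per-variant distance.
* **Microhomology distance** — Euclidean distance in the contig coordinate
  plane from the breakpoint pair to the nearest k-mer match pair. With no
  matches at all, the contig diagonal `sqrt(lenA² + lenB²)` is returned:
  a finite "maximally distant" sentinel chosen so the feature scales
  sensibly (the method text is silent on the empty case).

These feed the 9-attribute vector, in fixed order: FFPM, 5'-FAR, 3'-FAR,
5'-counter-FFPM, 3'-counter-FFPM, consensus indicator, reference-agreement
indicator, microhomology count, microhomology distance.

## Filters

* Minimum evidence: ≥ 1 split read; ≥ 3 if the breakpoint dinucleotides are
  non-consensus.
* LDAS (long double anchor support): some *single* split read with ≥ 25
  aligned bases on both sides. The aggregate reading (best left and best
  right anchors from different reads) is implemented but off by default —
  "supported by at least one read" reads most naturally per read, and the
  per-read rule is the stricter of the two.
* Promiscuity: per sample, a gene partnered in more than 10 distinct
  fusions fails all of its fusions.
* Paralog shadowing: a fusion fails when a strictly better-supported fusion
  in the sample pairs the same or paralogous partners, position by position.
  "More dominantly supported" is unquantified upstream; strict fragment-
  count inequality is used (ties keep both). Paralog pairs come from a
  user-supplied two-column file; no paralogy inference is built in.

## Clustering and classification

Features are scaled per attribute: Z-score, truncation to [−2, 2] (outlier
control), then linear rescale so each non-constant attribute fills
[−2, 2] exactly (constant attributes become zeros). A Euclidean
k-nearest-neighbor graph (k = 50; undirected, unweighted union of directed
kNN relations) is partitioned with Leiden under the modularity objective.
The resolution is data-set dependent — the original analyses used 3 for one
cohort and 2 for another after examining granularity — and the default here
is 3; the synthetic archetype benchmark below selects 0.1 the same way
(the value at which the cluster count stabilizes at the generating number).
Per-cluster enrichment for known-fusion membership uses the one-sided
(upper-tail) Fisher's exact test with Benjamini–Hochberg adjustment across
clusters.

A random forest (500 trees, √p feature subsampling; CART/gini, implemented
in-package since no forest library is available in the target environment)
predicts cluster labels from the scaled features, trained on at most 300
members per cluster with a stratified 2/3–1/3 train/test split; held-out
accuracy is reported by the model object. Predicted labels map through a
user-supplied cluster→category annotation (e.g. "COSMIC-like", "High FAR",
"Microhomology RT-induced artifact"); unmapped labels default to "other".
Cluster identities are dataset-specific, so the annotation map is
configuration, not a shipped constant.

## What the simulator emulates — and what it does not

`simulate_scenario()` generates: multi-exon genes (3–6 exons of 150–300 bp,
introns 300–3000 bp so that some exceed the shrinking threshold) on both
strands with GT–AG introns by construction; fusion breakpoints planted at
exon boundaries (`REF_SPLICE`), mid-exon with edited consensus flanks
(`NON_REF_CONSENSUS`), mid-exon without consensus (`NON_CANONICAL`), or
inside a planted shared 10-mer (`MICROHOMOLOGY_ARTIFACT`); and 100-base
paired-end reads as split, spanning, counter and background fragments with
exact CIGAR/NM truth SAM records (optionally FASTQ). Depth defaults — 10
split + 10 spanning per variant, 5 counter reads per partner side, 20
background pairs — are chosen as a typical well-supported fusion at desk
scale. Errors are uniform substitutions (rate 0 by default); base qualities
are constant; there are no indel errors, PCR duplicates, GC bias or
coverage heterogeneity. Counter reads are contiguous alignments across the
partner breakpoint (pre-mRNA-style support); spliced counter reads are not
simulated. Mid-exon breakpoints sit 30 bases from the relevant exon edge so
anchors, mates and counter overlaps always fit inside exons.

A green end-to-end test therefore establishes correct evidence capture,
quantification, feature computation and filtering under the stated QC
model — not robustness to alignment ambiguity, realistic error profiles or
library artifacts, which only real aligned data exercises.

The feature-archetype generator draws the 9 attributes from three
annotated profiles (COSMIC-like: high FFPM, 3'-FAR > 5'-FAR, consensus
reference splicing, few/distal microhomologies; artifact-like:
non-consensus novel breakpoints coinciding with abundant microhomology;
high-counter: lowly expressed fusion against highly expressed unfused
partners, FAR ≈ 1). The two indicator attributes are deterministic per
archetype — they are what defines the classes — while all continuous
attributes carry log-normal/Poisson noise.

## Numerical choices and degenerate inputs

* EM: uniform initialization, `tol = 1e-6` on the max abundance change,
  1000-iteration cap; one variant converges in a single iteration.
* Scaling requires ≥ 2 rows; sd = 0 columns become zeros rather than NaN.
* kNN k is reduced to n − 1 with a warning when rows ≤ k.
* Leiden and the forest are seeded; identical input + seed give identical
  labels, splits and reports (tested byte-for-byte).
* Missing NM tags fall back to edit distance 0 with a warning.
* Fusion lists accept `::` and `--` separators; contig names use `--`,
  display names `::`.
* Breakpoints within 2 bases of a contig edge are rejected
  ("edge breakpoint") rather than silently truncating dinucleotides.

## Known limitations

* Alignment is an input: the package neither runs an aligner nor realigns
  clipped tails; genome-wide mapping ambiguity is out of scope.
* The paralog filter is intentionally simplified to the supplied-pairs
  semantics described above.
* In-frame/frameshift coding-effect annotation, interactive visualization
  and de-novo transcript reconstruction are out of scope.
* Category prediction on a fresh sample applies the batch's own feature
  scaling; with very few variants per run this is a coarser normalization
  than the cohort-level scaling used at training time.
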