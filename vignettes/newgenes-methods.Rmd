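---
title: "Methods: classifying and characterizing genes across an annotation upgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and characterizing genes across an annotation upgrade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a genome assembly is upgraded and its official gene set re-annotated,
the new gene set typically grows. The growth has two distinct causes that
this package separates and quantifies:

* **Type I New genes** — genes whose coding sequence cannot be mapped onto
  the *old* assembly at all: the underlying sequence was missing or too
  fragmented before the upgrade. These genes are attributable to assembly
  improvement.
* **Type II New genes** — genes whose coding sequence *is* present in the
  old assembly but which share no same-strand coding base pair with any
  old-annotation gene model. These are attributable to better evidence
  (RNA-seq, peptides, protein homologs) and better gene predictors.
* **Previously Known genes** — everything else: the gene maps to the old
  assembly and overlaps an old gene model's coding sequence.

The motivating setting is an AT-rich insect genome whose early sequencing
chemistry under-represented its most AT-rich regions, so that assembly
improvement recovered disproportionately GC-poor sequence and the genes
living there. The package therefore also characterizes the classes by GC
compositional domain, coding-sequence structure, codon-usage bias
(effective number of codons), splice-site canonicality, expression breadth
and evidence support, and runs the class-comparison statistics alongside.

# Classification procedure

Coding sequences of the new gene set are mapped onto the old assembly and
filtered under two published criteria, both always computed:

* **stringent**: identity >= 0.95 and query coverage >= 0.80;
* **relaxed**: identity >= 0.95 and query coverage >= 0.50.

A gene with no retained alignment is Type I New. Otherwise the gene's
alignment blocks are intersected with the old annotation's coding exons,
*strand-aware*: a single shared coding base pair on the same strand makes
the gene Previously Known, zero same-strand coding overlap makes it Type II
New. Overlap is computed coding-vs-coding (alignment blocks of the new
CDS against old coding exons), which is the reading consistent with the
"coding base pair" criterion; the old gene's full span is deliberately not
used. When a gene's alignments overlap more than one old gene (candidate
split/merge events) the class is Previously Known and a `multi_overlap`
flag is set for manual review — any evidence of correspondence defeats
"new".

Relaxing the coverage threshold can only move genes out of Type I (the
identity threshold and the overlap rule are unchanged), and the three
classes always partition the gene set; both invariants are tested.

## The built-in mapper

`map_cds()` is a deliberately simple deterministic mapper for the setting
where the old assembly is (approximately) a subsequence of the new one, as
it is for the synthetic fixtures: exact 15-mer anchors on both strands are
merged into maximal exact blocks, blocks shorter than 25 bp are discarded
(a random 15-mer is expected to hit a megabase-scale genome about once per
kilobase of query, while a chance 25-mer match has probability ~1e-6), and
blocks are chained co-linearly with a dynamic programme that maximizes the
number of covered query bases. Adjacent blocks may overlap by a few bases
where a block extends across an exon–intron junction by chance; the chain
scores and reports the union, and emitted blocks are trimmed to be
disjoint. Identity is 1 by construction; coverage is chained query bases
over query length, one alignment per query/old-scaffold/strand.

Real-genome users should instead supply splice-aware alignments
(PSL/BED12/GFF3) from an external aligner via `read_alignments()`; both
paths share `filter_alignments()` and `classify_genes()`. For external
alignments an E-value prefilter of 1e-20 is assumed already applied; the
built-in mapper's exact-anchor requirement subsumes it.

# GC compositional domains

`segment_scaffold()` partitions each scaffold into GC-homogeneous domains
by recursive binary segmentation of the G/C-vs-A/T binary sequence. At
each step the candidate split maximizes the Jensen–Shannon divergence
between the two halves; the split is accepted when

1. the divergence exceeds the (1 − alpha) quantile of the same statistic
   computed on `null_replicates` simulated homogeneous Bernoulli sequences
   of the same length and composition (an empirical-null calibration with
   the same contract as a dynamic analytic threshold, which is not
   published for the reference implementation of this segmentation), and
2. the two halves differ by at least `min_gc_contrast` (default 0.02) in
   GC fraction.

The second condition is an effect-size floor: each recursion node's
empirical-null test has a false-split probability of alpha by
construction, and a sampling-noise split inside a truly homogeneous
region separates halves differing by well under one GC percentage point
(sd ~0.4% for 25-kb halves). Domains closer in composition than two
percentage points are below what this analysis treats as a compositional
domain boundary.

Numerical choices:

* Scaffolds shorter than 10 kb cannot be segmented reliably and are
  returned whole, flagged `unsegmented`; genes on them are excluded from
  the weighted-GC analysis and counted rather than analysed.
* Minimum domain length 3,000 bp (configurable).
* Candidate split points are evaluated on a grid of at most ~4,096
  positions per node — exact below 4 kb, ~250 bp granularity at 1 Mb —
  which bounds the cost of each decision; domain boundaries are therefore
  accurate to the grid step, ample for domain-scale GC averaging.
* Non-ACGT symbols are excluded from every GC numerator and denominator,
  and runs of 10 or more Ns split candidate domains outright: assembly
  gaps must not masquerade as composition. Whether the original analyses
  excluded Ns is not documented; this package's policy is stated here as
  its own.
* The per-node null sample is seeded from (seed, segment length,
  composition) only, so the same node sees the same null draws at any
  alpha — the domain count is then monotone in alpha, a tested property.

## Per-gene weighted GC

Because codon usage itself biases GC, the GC value attached to each domain
for gene-level analysis is computed from **non-coding positions only**
(positions not covered by any coding exon on either strand); a fully
coding domain has an undefined value and is skipped with renormalization.
A gene's value is then the mean of the non-coding GC of the domains it
spans, weighted by the fraction of the gene's genomic span (first to last
coding base, not the exon-only footprint) in each domain. Exon-only
weighting is available via the exported building blocks but the span is
the default, matching the "fraction of the gene's length" convention.

# Gene features

* **CDS metrics** — exact integer totals, arithmetic means over genes, and
  a 20-nt-bin length histogram (edges [0,20), [20,40), ...).
* **Splice sites** — the two intronic bases at each end of every intron,
  reverse-complemented for minus-strand genes so canonical always means
  5'-GT...AG-3' on the transcribed strand. Only introns supported by a
  same-strand spliced transcript alignment with *identical* gap
  coordinates enter the canonical/non-canonical counts. Introns shorter
  than 4 bp are flagged invalid.
* **Effective number of codons (Nc)** — Wright's estimator, one fixed
  dialect: per amino acid observed n >= 2 times with codon fractions p_i,
  F = (n Σp_i² − 1)/(n − 1); class means over the 2-, 3-, 4- and 6-fold
  degenerate amino acids; Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, truncated
  at 61. When Ile (the only 3-fold amino acid) is unobserved, (F2+F4)/2
  is substituted. Nc is 20 exactly when every observed degenerate amino
  acid uses a single codon and 61 after truncation under equal synonymous
  usage; both closed forms are asserted in the tests. Some popular
  implementations treat the 6-fold class differently; one documented
  dialect beats silent divergence. CDSs whose length is not a multiple of
  three are analysed on the longest in-frame prefix with a warning.
* **N50** — the smallest length L such that scaffolds of length >= L hold
  at least half the assembled bases.

# Evidence support

* **Transcripts** — a spliced alignment on the opposite strand from a gene
  contradicts the gene's direction and is discarded; spliced same-strand
  alignments and all unspliced alignments (direction undeterminable)
  support the gene iff >= 1 bp of an alignment block intersects a coding
  exon. "Spliced" means >= 2 blocks separated by >= 30 bp on the target
  (configurable; the boundary is not defined by the source analyses).
* **Expression breadth** — over the four designated single-tissue
  libraries (brain, antennae, ovary, testes by default): narrow = spliced
  support in exactly one tissue, broad = in all four, none = in zero,
  neither otherwise.
* **Peptides** — a gene is supported iff some peptide of >= 6 amino acids
  is an exact substring of its translated CDS. For 100%-identity,
  full-length peptide matches this is equivalent to running a
  scoring-matrix alignment and removes a tool dependency.
* **Protein homologs** — >= 1 same-strand coding base pair with a homolog
  alignment; alignments carrying identity/coverage fields are admitted at
  60%/60% (the usual protein-to-genome thresholds), otherwise taken as
  given. Per-source flags (e.g. the Dipteran reference proteome) support
  the source-restricted contrasts.
* **Conservation and protein domains** — consumed as precomputed tables
  (gene → informant-genome hit at the translated-search E-value threshold
  of 1e-6; gene → domain identifier). Computing them is out of scope.
* **Aggregate** — *biological gene evidence* = transcript OR peptide OR
  homolog OR domain support; *any support* additionally ORs the
  cross-genome conservation flags, which by themselves say nothing about
  a gene model's structure.

# Statistics

Frequency contrasts between a New class and the Previously Known class use
the uncorrected Pearson chi-square test on the 2×2 table (1 df). The
protein-domain version-contrast uses the Yates-corrected chi-square — the
one place the correction is applied, mirroring the reporting convention of
the analyses this package reproduces. Mean contrasts run both a two-sided
Kolmogorov–Smirnov test and a Welch t-test and report the *least
significant* of the two P-values, avoiding normality and equal-variance
assumptions. P-values are reported raw, with no multiple-testing
correction across features (the report footer notes this). Identical
constant samples report P = 1 by convention. The type-I error of the
proportion test is verified by simulation (5% ± 2% at alpha = 0.05 over
1,000 null replicates).

Derived report arithmetic is exact integer subtraction for deltas;
percent increases and coverage percentages are reported to one decimal
and percent reductions as integers, following the mixed rounding of the
summary tables being reproduced.

# The synthetic-data generator

No generative model is published for the study system, so the generator
implements the smallest structure under which every pipeline stage has a
known answer, with defaults chosen once to mirror the documented
phenomena:

* **Genome** — scaffolds are concatenations of compositional domains with
  exponential lengths (mean 30 kb) and i.i.d. bases at one of two GC
  levels (0.20/0.45 by default — a bimodal caricature of a genome whose
  GC spans ~10–70%).
* **Genes** — ~100 per Mb, placed with probability 0.7 into the
  lowest-GC domain class (genes concentrate in AT-rich domains), 1–10
  coding exons with a minimum exon size of nine codons, CDS >= 75 nt
  (negative-binomial codon counts, mean ~400 codons), ATG start, single
  stop, no internal stops, GT/AG introns except a 2% non-canonical
  minority. The assembly sequence under each gene is overwritten so the
  ORF is genuinely present. Genes never overlap.
* **Old assembly** — deletions are sampled per domain with expected
  deleted fractions 0.30 (lowest-GC domains) versus 0.05 (others), mean
  deletion 4 kb; deleted flanks are rejoined, and rare breaks (2e-6/bp)
  split old scaffolds. A lift table records every surviving interval.
* **Class truth** — a gene is Type I truth when its mappable retained CDS
  fraction (surviving runs of >= 25 bp, grouped per old scaffold, best
  scaffold taken) falls below 0.80 (stringent) or 0.50 (relaxed). The
  25-bp floor is the same constant the mapper uses for block admission,
  which makes truth recovery exact by construction rather than by luck of
  the seed. Retained genes enter the simulated old annotation with a
  logistic probability in CDS length (midpoint 600 bp, scale 250 bp,
  ceiling 0.92), emulating the documented tendency of early predictors to
  miss short genes; emitted old models are the lifted surviving exon
  pieces. Retained, unannotated genes are Type II truth.
* **Evidence** — per-tissue expression (p = 0.55), spliced alignments
  whose blocks are exactly the gene's exons (85% of expressed multi-exon
  genes; unspliced single blocks otherwise), opposite-strand spliced
  noise at 2%, tryptic-like peptides (>= 6 aa exact substrings), homolog
  alignments (p = 0.5 any source, 0.12 Dipteran), per-informant
  conservation flags (0.85/0.78) and domain-table hits (0.45). Breadth
  truth is recorded from the actual spliced emissions.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and polymorphism (the old
assembly is an exact subsequence, so mapper identity is always 1),
repeats and gene families (anchors are near-unique by construction),
alternative splicing and UTRs, false genes in the old annotation
(deliberately not modelled: the prevalence of such artifacts is
undocumented, and guessing a rate would only blur the truth labels),
read-level noise and quality scores, and realistic splice-site motifs
beyond the terminal dinucleotides.

# Problem sizes and runtime choices

The test suite exercises the full pipeline on a 1 Mb, ~100-gene fixture
(classification truth recovery, direction checks) and a 300 kb, ~30-gene
fixture for the per-module checks; segmentation checks use 50–60 kb
sequences across 20 seeds with 20 null replicates per split decision.
These sizes give every stochastic check comfortable margins while keeping
a full run to a few minutes on one core. Oracle-equivalence checks
(interval overlap, weighted GC, ENC, N50, chi-square) run >= 100 random
instances each at 1e-9 tolerance.

# Known limitations

* The built-in mapper is exact-match only; divergence between assembly
  versions beyond indels/fragmentation requires external alignments.
* Whether published identity thresholds apply per alignment path or per
  covering block set is unspecified in the source analyses; this package
  computes overall identity per alignment (summed matches over summed
  aligned length) and exposes the thresholds as parameters.
* Segmentation boundary precision is limited by the evaluation grid
  (~250 bp at 1 Mb) and the effect-size floor hides compositional
  boundaries subtler than two GC percentage points.
* The evidence matrix treats every library equally; no attempt is made to
  model library depth or mapping artefacts.
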