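# newgenes

Tools for asking — and answering — a question every genome consortium faces
after an assembly upgrade: **where did all the new genes come from?**

When an assembly and its official gene set are rebuilt, the gene count
typically jumps. `newgenes` separates the two causes. Each gene of the new
annotation is mapped onto the *old* assembly and classified:

| Class | Rule | Attribution |
|---|---|---|
| **Type I New** | coding sequence fails to map to the old assembly (identity ≥ 0.95 and coverage ≥ 0.80 stringent / ≥ 0.50 relaxed) | assembly improvement |
| **Type II New** | maps, but shares **no same-strand coding base pair** with any old gene model | better evidence & prediction |
| **Previously Known** | maps and overlaps an old gene's coding sequence | carried over |

The classes are then characterized the way annotation projects characterize
them: coding-sequence length and exon structure; the GC of the
**compositional domain** each gene resides in (recursive Jensen–Shannon
segmentation, non-coding positions only, weighted by the fraction of the
gene's span per domain); Wright's **effective number of codons**

    Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6,   F = (n Σ p_i² − 1)/(n − 1)

ranging from 20 (one codon per amino acid) to 61 (uniform synonymous
usage); GT/AG splice-site canonicality restricted to transcript-supported
introns; expression breadth over four designated tissue libraries; and an
evidence matrix (transcripts with the strand rule, ≥ 6-aa exact-substring
peptides, same-strand protein homologs, domain-table and cross-genome
conservation support). Class contrasts use uncorrected Pearson chi-square
tests for frequencies and report the *least significant* of a
Kolmogorov–Smirnov and a Welch t-test for means.

Because the genomes this analysis was designed for are far beyond desk
scale, the package ships a **synthetic-data generator** that emulates the
relevant structure — bimodal-GC scaffolds, genes biased into AT-rich
domains, an old assembly degraded preferentially in low-GC regions, a
length-biased old annotation, multi-tissue spliced/unspliced evidence —
with complete ground truth, so the entire pipeline is exercisable and
testable in minutes.

Intended users: genome-annotation groups comparing gene-set versions,
and anyone needing a tested reference implementation of the
classification rules, the segmentation, or Wright's Nc.

## Worked example

```r
library(newgenes)

# 1. simulate a 300-kb genome with known ground truth
gspec <- genome_sim_spec(seed = 42, n_scaffolds = 2, scaffold_length = 150000)
gen <- simulate_genome(gspec)
pl  <- place_genes(gen$assembly, gen$domains, gspec)
deg <- degrade_assembly(pl$assembly, pl$genes, gen$domains, degradation_spec(seed = 43))

# 2. map new coding sequences onto the old assembly and classify
res <- classify_both_modes(pl$genes, pl$assembly, deg$old_assembly, deg$old_genes)
table(res$stringent$class)
#> PreviouslyKnown           TypeI          TypeII
#>              16               6               8

# 3. agreement with the generator's truth
truth <- deg$truth
mean(res$stringent$class == truth$class_stringent[match(res$stringent$gene_id, truth$gene_id)])
#> [1] 1

# 4. characterise: GC domains and codon usage
dom <- segment_assembly(pl$assembly, segmentation_params(seed = 1))
dom <- domain_noncoding_gc(dom, pl$genes, pl$assembly)
wgc <- gene_weighted_gc(pl$genes, dom)
cls <- setNames(res$stringent$class, res$stringent$gene_id)
round(100 * tapply(wgc$weighted_gc, cls[wgc$gene_id], mean, na.rm = TRUE), 2)
#> PreviouslyKnown           TypeI          TypeII
#>           28.18           20.60           34.23

# 5. a class contrast, reported the conservative way
lens <- gene_summary(pl$genes)
mean_comparison(lens$cds_length[cls[lens$gene_id] == "TypeII"],
                lens$cds_length[cls[lens$gene_id] == "PreviouslyKnown"])$p_reported
#> [1] 0.05793022
```

The 30 genes are classified with 100% agreement to the generator's truth
table. The class means show the expected structure of an upgrade of an
AT-rich genome: Type I New genes sit in the most GC-poor domains (20.6%
GC versus 28.2% for Previously Known — they were recovered with the
missing AT-rich sequence), while Type II New genes sit in more
GC-balanced territory (34.2%). At 30 genes the Type II-vs-Known CDS-length
contrast is suggestive but not significant (p ≈ 0.058 under the
max-of-KS-and-Welch rule); at the 100-gene fixture used in the test suite
the shortness of Type II genes is unambiguous.

A full run — classification in both modes, segmentation, features,
evidence matrix, report and statistics, every intermediate written as
TSV/BED/JSON — is one call:

```r
run_pipeline("config.yaml")   # see ?run_pipeline for the config keys
```

A thin command-line front end with `simulate`, `classify`, `segment`,
`features`, `evidence`, `stats`, `report` and `run` subcommands lives at
`inst/cli/newgenes.R`.

## The methods vignette

`vignettes/newgenes-methods.Rmd` documents the model and its assumptions:
the classification rules and their edge cases, the segmentation statistic
and its empirical-null calibration, the Nc dialect, the evidence rules,
the statistical protocol, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the package's
numerical choices.
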