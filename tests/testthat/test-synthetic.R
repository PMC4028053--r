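test_that("simulated genomes hit their target GC and are deterministic", {
  spec <- genome_sim_spec(seed = 3, n_scaffolds = 1, scaffold_length = 100000,
                          gc_levels = 0.5)
  gen <- simulate_genome(spec)
  s <- as.character(gen$assembly[[1]])
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.01)

  gen2 <- simulate_genome(spec)
  f1 <- tempfile(); f2 <- tempfile()
  write_assembly(gen$assembly, f1)
  write_assembly(gen2$assembly, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-domain GC matches the emitted domain truth", {
  spec <- genome_sim_spec(seed = 5, n_scaffolds = 4, scaffold_length = 250000,
                          gc_levels = c(0.2, 0.45))
  gen <- simulate_genome(spec)
  for (scf in names(gen$assembly)) {
    v <- strsplit(as.character(gen$assembly[[scf]]), "")[[1]] %in% c("G", "C")
    d <- gen$domains[gen$domains$scaffold == scf, ]
    # partition check
    expect_equal(d$start, c(1L, utils::head(d$end, -1) + 1L))
    expect_equal(max(d$end), length(v))
    for (i in seq_len(nrow(d))) {
      emp <- mean(v[d$start[i]:d$end[i]])
      expect_lt(abs(emp - d$gc_level[i]), 0.05)
      if (d$end[i] - d$start[i] + 1 >= 5000) {
        # binomial error at shorter domains exceeds the tighter tolerance
        expect_lt(abs(emp - d$gc_level[i]), 0.02)
      }
    }
  }
})

test_that("placed genes are real ORFs respecting the placement bias", {
  spec <- genome_sim_spec(seed = 7, n_scaffolds = 1, scaffold_length = 100000,
                          low_gc_gene_bias = 1.0, gene_density_per_mb = 150)
  gen <- simulate_genome(spec)
  pl <- place_genes(gen$assembly, gen$domains, spec)
  gsum <- gene_summary(pl$genes)
  expect_gt(nrow(gsum), 5)

  lowest <- min(gen$domains$gc_level)
  low_dom <- gen$domains[gen$domains$gc_level == lowest, ]
  for (i in seq_len(nrow(gsum))) {
    mid <- (gsum$span_start[i] + gsum$span_end[i]) %/% 2
    expect_true(any(mid >= low_dom$start & mid <= low_dom$end),
                label = paste("midpoint of", gsum$gene_id[i], "in a lowest-GC domain"))
  }

  cds <- cds_sequences(pl$genes, pl$assembly)
  for (s in as.character(cds)) {
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    aa <- translate_cds(s)
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_gte(nchar(s), 75)
  }
})

test_that("single-exon gene fraction matches the configured distribution", {
  spec <- genome_sim_spec(seed = 19, n_scaffolds = 2, scaffold_length = 1000000,
                          gene_density_per_mb = 250)
  gen <- simulate_genome(spec)
  pl <- place_genes(gen$assembly, gen$domains, spec)
  gsum <- gene_summary(pl$genes)
  n <- nrow(gsum)
  expect_equal(n, 500)
  observed <- sum(gsum$n_exons == 1)
  p1 <- spec$exon_count_probs[1]
  # exact central 99% binomial interval
  expect_gte(observed, qbinom(0.005, n, p1))
  expect_lte(observed, qbinom(0.995, n, p1))
})

test_that("zero degradation leaves the assembly and genes intact", {
  fx <- fixture_small()
  deg <- degrade_assembly(fx$assembly, fx$genes, fx$domain_truth,
                          degradation_spec(seed = 1, deletion_rate_low_gc = 0,
                                           deletion_rate_high_gc = 0,
                                           scaffold_break_rate = 0))
  expect_identical(unname(as.character(deg$old_assembly)),
                   unname(as.character(fx$assembly)))
  expect_true(all(deg$truth$retained_fraction == 1))
  expect_false(any(deg$truth$class_stringent == "TypeI"))
})

test_that("recorded retained fractions equal a brute-force lift-table check", {
  fx <- fixture_small()
  brute <- lift_retained_fraction(fx$genes, fx$lift)
  ord <- match(brute$gene_id, fx$truth$gene_id)
  expect_equal(brute$total, fx$truth$retained_fraction[ord], tolerance = 1e-12)
  # the mappable fraction never exceeds the brute-force single-scaffold value
  expect_true(all(fx$truth$mappable_fraction[ord] <= brute$best_scaffold + 1e-12))
})

test_that("a fully deleted gene is Type I truth", {
  # one gene, then delete its whole scaffold region by hand-driven rates
  spec <- genome_sim_spec(seed = 23, n_scaffolds = 1, scaffold_length = 60000,
                          gene_density_per_mb = 40, gc_levels = c(0.2, 0.45))
  gen <- simulate_genome(spec)
  pl <- place_genes(gen$assembly, gen$domains, spec)
  deg <- degrade_assembly(pl$assembly, pl$genes, gen$domains,
                          degradation_spec(seed = 2,
                                           deletion_rate_low_gc = 0.98,
                                           deletion_rate_high_gc = 0.98,
                                           deletion_length_mean = 60000))
  zero <- deg$truth$gene_id[deg$truth$retained_fraction == 0]
  expect_gt(length(zero), 0)
  expect_true(all(deg$truth$class_stringent[deg$truth$gene_id %in% zero] == "TypeI"))
  expect_true(all(deg$truth$class_relaxed[deg$truth$gene_id %in% zero] == "TypeI"))
})

test_that("evidence simulation honours its forcing cases", {
  fx <- fixture_small()
  ev_all <- simulate_evidence(fx$genes, fx$assembly,
                              evidence_sim_spec(seed = 4, expression_prob = 1,
                                                spliced_fraction = 1,
                                                antisense_noise_rate = 0))
  gsum <- gene_summary(fx$genes)
  multi <- gsum$gene_id[gsum$n_exons >= 2]
  bt <- ev_all$breadth_truth
  expect_true(all(bt$breadth[bt$gene_id %in% multi] == "broad"))

  # no antisense noise: every spliced alignment is on its gene's strand
  per <- aln_summary(ev_all$transcripts)
  spl <- per[per$spliced, ]
  gene_strand <- stats::setNames(gsum$strand, gsum$gene_id)
  src_gene <- sub("^tx_[^_]+_", "", spl$query_id)
  expect_true(all(spl$strand == gene_strand[src_gene]))
})

test_that("emitted peptides are verbatim substrings of their source protein", {
  fx <- fixture_small()
  pep <- fx$evidence$peptides
  expect_gt(nrow(pep), 0)
  cds <- cds_sequences(fx$genes, fx$assembly)
  for (i in seq_len(nrow(pep))) {
    prot <- suppressWarnings(translate_cds(as.character(cds[[pep$source_gene[i]]])))
    expect_true(grepl(pep$peptide[i], prot, fixed = TRUE))
    expect_gte(nchar(pep$peptide[i]), 6)
  }
})

test_that("fixture files are byte-identical across reruns of the same specs", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  gspec <- genome_sim_spec(seed = 29, n_scaffolds = 1, scaffold_length = 60000,
                           gene_density_per_mb = 60)
  simulate_fixture(d1, gspec)
  simulate_fixture(d2, gspec)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
})
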