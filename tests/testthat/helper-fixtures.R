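# Shared fixtures, memoised so each is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ~30 genes on 2 x 150 kb scaffolds: the workhorse fixture
fixture_small <- function() {
  memo("small", function() {
    gspec <- genome_sim_spec(seed = 11, n_scaffolds = 2, scaffold_length = 150000)
    gen <- simulate_genome(gspec)
    pl <- place_genes(gen$assembly, gen$domains, gspec)
    deg <- degrade_assembly(pl$assembly, pl$genes, gen$domains,
                            degradation_spec(seed = 13))
    ev <- simulate_evidence(pl$genes, pl$assembly, evidence_sim_spec(seed = 17))
    list(gspec = gspec, assembly = pl$assembly, genes = pl$genes,
         domain_truth = gen$domains, old_assembly = deg$old_assembly,
         old_genes = deg$old_genes, lift = deg$lift, truth = deg$truth,
         evidence = ev)
  })
}

# ~100 genes on 4 x 250 kb scaffolds (1 Mb): used by the acceptance checks
fixture_medium <- function() {
  memo("medium", function() {
    gspec <- genome_sim_spec(seed = 11, n_scaffolds = 4, scaffold_length = 250000)
    gen <- simulate_genome(gspec)
    pl <- place_genes(gen$assembly, gen$domains, gspec)
    deg <- degrade_assembly(pl$assembly, pl$genes, gen$domains,
                            degradation_spec(seed = 13))
    ev <- simulate_evidence(pl$genes, pl$assembly, evidence_sim_spec(seed = 17))
    list(gspec = gspec, assembly = pl$assembly, genes = pl$genes,
         domain_truth = gen$domains, old_assembly = deg$old_assembly,
         old_genes = deg$old_genes, lift = deg$lift, truth = deg$truth,
         evidence = ev)
  })
}

fixture_small_classified <- function() {
  memo("small_classified", function() {
    fx <- fixture_small()
    classify_both_modes(fx$genes, fx$assembly, fx$old_assembly, fx$old_genes)
  })
}

# independent classification oracle: per-base intersection of alignment
# blocks with old-gene coding exons on the same strand
classify_oracle <- function(new_genes, kept_alns, old_genes) {
  gsum <- gene_summary(new_genes)
  rows <- lapply(gsum$gene_id, function(gid) {
    a <- kept_alns[kept_alns$query_id == gid, , drop = FALSE]
    if (nrow(a) == 0) {
      return(data.frame(gene_id = gid, class = "TypeI", overlap_bp = 0L))
    }
    ov <- 0L
    if (!is.null(old_genes)) {
      for (r in seq_len(nrow(a))) {
        og <- old_genes[old_genes$scaffold == a$target[r] &
                        old_genes$strand == a$strand[r], , drop = FALSE]
        if (nrow(og) == 0) next
        for (b in a$start[r]:a$end[r]) {
          ov <- ov + sum(b >= og$start & b <= og$end)
        }
      }
    }
    data.frame(gene_id = gid,
               class = if (ov == 0L) "TypeII" else "PreviouslyKnown",
               overlap_bp = ov)
  })
  do.call(rbind, rows)
}

fixture_medium_classified <- function() {
  memo("medium_classified", function() {
    fx <- fixture_medium()
    classify_both_modes(fx$genes, fx$assembly, fx$old_assembly, fx$old_genes)
  })
}

# brute-force retained CDS bases per gene from the lift table: base-by-base
# intersection of coding exons with surviving intervals, totalled over all
# old scaffolds and (separately) for the best single old scaffold
lift_retained_fraction <- function(genes, lift) {
  gsum <- gene_summary(genes)
  rows <- lapply(seq_len(nrow(gsum)), function(i) {
    ex <- genes[genes$gene_id == gsum$gene_id[i], , drop = FALSE]
    lf <- lift[lift$new_scaffold == gsum$scaffold[i], , drop = FALSE]
    if (nrow(lf) == 0) {
      return(data.frame(gene_id = gsum$gene_id[i], total = 0, best_scaffold = 0))
    }
    per_scf <- vapply(unique(lf$old_scaffold), function(os) {
      lfo <- lf[lf$old_scaffold == os, , drop = FALSE]
      tot <- 0L
      for (j in seq_len(nrow(ex))) {
        for (b in ex$start[j]:ex$end[j]) {
          if (any(b >= lfo$new_start & b <= lfo$new_end)) tot <- tot + 1L
        }
      }
      tot
    }, numeric(1))
    data.frame(gene_id = gsum$gene_id[i],
               total = sum(per_scf) / gsum$cds_length[i],
               best_scaffold = max(per_scf) / gsum$cds_length[i])
  })
  do.call(rbind, rows)
}

# a tiny hand-built two-gene set on one scaffold, for unit tests
toy_gene_set <- function() {
  gene_set(data.frame(
    gene_id = c("gA", "gA", "gB"),
    scaffold = "chr1",
    strand = c("+", "+", "-"),
    start = c(101L, 301L, 1001L),
    end = c(220L, 420L, 1300L),
    stringsAsFactors = FALSE
  ))
}
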