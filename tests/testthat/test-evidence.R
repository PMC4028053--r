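toy_support_case <- function() {
  # gA: exons 101-220, 301-420 on +; gB: exon 1001-1300 on -
  gs <- toy_gene_set()
  mk <- function(id, strand, starts, ends, lib = "brain") {
    data.frame(aln_id = id, query_id = id, target = "chr1", strand = strand,
               start = starts, end = ends, library = lib,
               stringsAsFactors = FALSE)
  }
  list(gs = gs, mk = mk)
}

test_that("the transcript strand rule is applied exactly as stated", {
  tc <- toy_support_case()
  alns <- aln_set(rbind(
    # spliced, opposite strand, large coding overlap: discarded
    tc$mk("as_spliced", "-", c(101L, 301L), c(220L, 420L)),
    # unspliced, opposite strand, 1 bp coding overlap: support
    tc$mk("as_unspliced", "+", 1300L, 1400L),
    # spliced, same strand, but blocks only in the intron: no support
    tc$mk("intronic", "+", c(225L, 270L), c(240L, 296L))
  ))
  out <- transcript_overlap(tc$gs, alns)
  expect_false(out$spliced["gA", "brain"])
  expect_false(out$unspliced["gA", "brain"])
  expect_true(out$unspliced["gB", "brain"])
})

test_that("expression breadth partitions genes by tissue support pattern", {
  sup <- matrix(c(TRUE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3", "g4"),
                                c("brain", "antennae", "ovary", "testes")))
  br <- expression_breadth(sup)
  expect_equal(br$breadth, c("narrow", "broad", "neither", "none"))
  expect_error(expression_breadth(sup, tissues = "brain"), "at least two")
})

test_that("peptide support needs a >=6-aa exact substring", {
  prots <- c(g1 = "MKLVNNPQRSTWYACDEF", g2 = "MAAAAAAA")
  expect_true(peptide_support("NPQRST", prots)$supported[["g1"]])
  expect_false(peptide_support("NPQRS", prots)$supported[["g1"]])   # 5-mer
  expect_false(peptide_support("NPQRSA", prots)$supported[["g1"]])  # substitution
  expect_warning(sup <- peptide_support(c("NPQRST", "NPQ#ST"), prots),
                 "non-amino-acid")
  expect_true(sup$supported[["g1"]])
  m <- peptide_support("NPQRST", prots)$matches
  expect_equal(m$position, 6L)
})

test_that("homolog overlap needs one same-strand coding base pair", {
  tc <- toy_support_case()
  mkh <- function(id, strand, s, e, src) {
    data.frame(aln_id = id, query_id = id, target = "chr1", strand = strand,
               start = s, end = e, identity = 0.9, coverage = 0.9,
               source = src, stringsAsFactors = FALSE)
  }
  alns <- aln_set(rbind(
    mkh("h1", "+", 220L, 260L, "metazoa"),  # 1 bp on gA exon, same strand
    mkh("h2", "+", 1001L, 1300L, "dmel")    # opposite strand of gB
  ))
  out <- homolog_overlap(tc$gs, alns)
  expect_true(out["gA", "metazoa"])
  expect_true(out["gA", "any"])
  expect_false(out["gB", "dmel"])
  expect_false(out["gB", "any"])
  # admission thresholds drop weak alignments
  weak <- aln_set(mkh("h3", "+", 101L, 220L, "metazoa"))
  weak$identity <- 0.5
  expect_false(homolog_overlap(tc$gs, weak)["gA", "any"])
})

test_that("homolog flags equal a brute-force intersection oracle on a fixture", {
  fx <- fixture_small()
  out <- homolog_overlap(fx$genes, fx$evidence$homologs)
  per <- aln_summary(fx$evidence$homologs)
  gsum <- gene_summary(fx$genes)
  for (i in seq_len(nrow(gsum))) {
    gid <- gsum$gene_id[i]
    ex <- fx$genes[fx$genes$gene_id == gid, , drop = FALSE]
    brute <- FALSE
    h <- fx$evidence$homologs
    for (r in seq_len(nrow(h))) {
      if (h$target[r] != gsum$scaffold[i] || h$strand[r] != gsum$strand[i]) next
      if (h$identity[r] < 0.6 || h$coverage[r] < 0.6) next
      for (j in seq_len(nrow(ex))) {
        if (h$start[r] <= ex$end[j] && h$end[r] >= ex$start[j]) brute <- TRUE
      }
    }
    expect_identical(unname(out[gid, "any"]), brute, label = gid)
  }
})

test_that("conservation alone gives any_support but not gene evidence", {
  gs <- toy_gene_set()
  gsum <- gene_summary(gs)
  empty <- matrix(FALSE, nrow(gsum), 1,
                  dimnames = list(gsum$gene_id, "brain"))
  cons <- data.frame(gene_id = c("gA", "gB"), informant = "aflo",
                     supported = c(TRUE, FALSE))
  em <- build_evidence_matrix(gs, list(spliced = empty, unspliced = empty),
                              conservation = cons,
                              tissues = c("brain", "antennae", "ovary", "testes"))
  a <- em[em$gene_id == "gA", ]
  expect_false(a$biological_gene_evidence)
  expect_true(a$any_support)
  b <- em[em$gene_id == "gB", ]
  expect_false(b$any_support)
  expect_equal(a$breadth, "none")
})

test_that("evidence matrix percentages equal a hand tally on the fixture", {
  fx <- fixture_small()
  tx <- transcript_overlap(fx$genes, fx$evidence$transcripts)
  cds <- cds_sequences(fx$genes, fx$assembly)
  prots <- vapply(as.character(cds), function(s) {
    suppressWarnings(translate_cds(s))
  }, character(1))
  names(prots) <- names(cds)
  pep <- peptide_support(fx$evidence$peptides$peptide, prots)$supported
  hom <- homolog_overlap(fx$genes, fx$evidence$homologs)
  em <- build_evidence_matrix(fx$genes, tx, pep, hom,
                              fx$evidence$conservation, fx$evidence$domains)
  # hand tally of biological gene evidence
  for (i in seq_len(nrow(em))) {
    gid <- em$gene_id[i]
    manual <- em$transcript_any[i] || unname(pep[gid]) ||
      unname(hom[gid, "any"]) || gid %in% fx$evidence$domains$gene_id
    expect_identical(em$biological_gene_evidence[i], manual)
  }
  # breadth equals the generator's breadth truth (no-noise spliced emission)
  bt <- fx$evidence$breadth_truth
  ord <- match(em$gene_id, bt$gene_id)
  expect_equal(em$breadth, bt$breadth[ord])
})

test_that("support flags are monotone and order-invariant", {
  fx <- fixture_small()
  alns <- fx$evidence$transcripts
  half <- alns[alns$aln_id %in% unique(alns$aln_id)[1:20], ]
  out_half <- transcript_overlap(fx$genes, aln_set(as.data.frame(half)))
  out_full <- transcript_overlap(fx$genes, alns)
  expect_true(all(out_full$spliced[, colnames(out_half$spliced)] >= out_half$spliced))
  expect_true(all(out_full$unspliced[, colnames(out_half$unspliced)] >= out_half$unspliced))

  shuf <- alns[sample.int(nrow(alns)), ]
  out_shuf <- transcript_overlap(fx$genes, aln_set(as.data.frame(shuf)))
  expect_identical(out_full$spliced, out_shuf$spliced)
  expect_identical(out_full$unspliced, out_shuf$unspliced)
})
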