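test_that("cds_metrics sums, means and histogram follow the definitions", {
  gs <- gene_set(data.frame(
    gene_id = c("a", "b", "b"), scaffold = "s", strand = "+",
    start = c(1L, 501L, 901L), end = c(300L, 800L, 1500L)
  ))
  m <- cds_metrics(gs)
  expect_equal(m$mean_cds_length, 600)
  expect_equal(m$total_coding_nt, 1200L)
  expect_equal(m$per_gene$single_exon, c(TRUE, FALSE))
  # 20-nt bins with edges [0,20), [20,40), ...
  expect_equal(m$histogram$bin_start[1], 0L)
  expect_equal(m$histogram$count[m$histogram$bin_start == 300], 1L)
  expect_equal(m$histogram$count[m$histogram$bin_start == 900], 1L)
  expect_equal(sum(m$histogram$count), 2L)
})

test_that("cds_metrics totals equal a per-exon summation oracle and are order-invariant", {
  fx <- fixture_small()
  m <- cds_metrics(fx$genes)
  oracle_total <- 0L
  for (i in seq_len(nrow(fx$genes))) {
    oracle_total <- oracle_total + (fx$genes$end[i] - fx$genes$start[i] + 1L)
  }
  expect_identical(m$total_coding_nt, oracle_total)

  shuffled <- fx$genes[sample.int(nrow(fx$genes)), ]
  m2 <- cds_metrics(gene_set(as.data.frame(shuffled)))
  expect_identical(m2$total_coding_nt, m$total_coding_nt)
  expect_equal(m2$mean_cds_length, m$mean_cds_length)
})

test_that("splice sites are read strand-aware and gated on transcript support", {
  # plus-strand gene with GT..AG intron; minus-strand gene whose forward
  # sequence reads CT..AC (canonical after reverse complement)
  left <- strrep("A", 100)
  plus_intron <- paste0("GT", strrep("A", 46), "AG")
  minus_intron <- paste0("CT", strrep("A", 46), "AC")
  seqs <- c(chr = paste0(left, strrep("C", 30), plus_intron, strrep("C", 30),
                         strrep("T", 40), strrep("G", 30), minus_intron,
                         strrep("G", 30)))
  # exons: plus gene 101-130 and 181-210; minus gene 251-280 and 331-360
  gs <- gene_set(data.frame(
    gene_id = c("p", "p", "m", "m"), scaffold = "chr",
    strand = c("+", "+", "-", "-"),
    start = c(101L, 181L, 251L, 331L), end = c(130L, 210L, 280L, 360L)
  ))
  support <- aln_set(data.frame(
    aln_id = c("t1", "t1"), query_id = "t1", target = "chr", strand = "+",
    start = c(101L, 181L), end = c(130L, 210L)
  ))
  out <- splice_site_survey(gs, seqs, support)
  rec <- out$records
  p_rec <- rec[rec$gene_id == "p", ]
  m_rec <- rec[rec$gene_id == "m", ]
  expect_true(p_rec$canonical)
  expect_equal(p_rec$donor, "GT")
  expect_equal(p_rec$acceptor, "AG")
  expect_true(m_rec$canonical)
  expect_equal(m_rec$donor, "GT")  # revcomp of forward-strand AC
  expect_true(p_rec$transcript_supported)
  expect_false(m_rec$transcript_supported)
  # counts restricted to supported introns
  expect_equal(unname(out$counts["supported"]), 1L)
  expect_equal(unname(out$counts["canonical"]), 1L)
  expect_equal(unname(out$counts["total_introns"]), 2L)
})

test_that("simulated genes have mostly canonical, supported introns", {
  fx <- fixture_small()
  out <- splice_site_survey(fx$genes, fx$assembly, fx$evidence$transcripts)
  expect_gt(unname(out$counts["supported"]), 0)
  frac_canon <- out$counts[["canonical"]] / out$counts[["supported"]]
  expect_gt(frac_canon, 0.9)
  # survey is invariant under alignment row order
  shuf <- fx$evidence$transcripts[sample.int(nrow(fx$evidence$transcripts)), ]
  out2 <- splice_site_survey(fx$genes, fx$assembly, aln_set(as.data.frame(shuf)))
  expect_identical(out$counts, out2$counts)
})

test_that("Wright ENC hits its closed forms and bounds", {
  code <- Biostrings::GENETIC_CODE
  aas <- setdiff(unique(code), "*")
  one_per_aa <- vapply(aas, function(a) names(code)[code == a][1], character(1))
  nc20 <- enc(paste(rep(one_per_aa, 100), collapse = ""))
  expect_identical(nc20$nc, 20)

  sense <- names(code)[code != "*"]
  degen_aa <- names(table(code[sense]))[table(code[sense]) >= 2]
  degen <- sense[code[sense] %in% degen_aa]
  nc61 <- enc(paste(rep(degen, 60), collapse = ""))
  expect_identical(nc61$nc, 61)

  expect_true(is.na(enc(strrep("ATGTGG", 30))$nc))
  expect_match(enc(strrep("ATGTGG", 30))$reason, "degenerate")

  expect_warning(enc(paste0(strrep("GAAGAG", 30), "GA")), "divisible by 3")
})

test_that("ENC equals a literal transcription of the estimator on random CDS", {
  enc_oracle <- function(cds) {
    code <- Biostrings::GENETIC_CODE
    cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    cod <- cod[!code[cod] %in% "*"]
    fam <- split(cod, code[cod])
    # per-amino-acid homozygosity
    Fhat <- lapply(fam, function(x) {
      n <- length(x)
      if (n < 2) return(NA_real_)
      p <- as.numeric(table(x)) / n
      (n * sum(p^2) - 1) / (n - 1)
    })
    classes <- list(
      c("F", "Y", "C", "H", "Q", "N", "K", "D", "E"),
      "I",
      c("V", "P", "T", "A", "G"),
      c("L", "S", "R")
    )
    Fbar <- vapply(classes, function(cl) {
      v <- unlist(Fhat[names(Fhat) %in% cl])
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    if (is.na(Fbar[2]) && !is.na(Fbar[1]) && !is.na(Fbar[3])) {
      Fbar[2] <- (Fbar[1] + Fbar[3]) / 2
    }
    if (any(is.na(Fbar)) || any(Fbar <= 0)) return(NA_real_)
    min(61, 2 + 9 / Fbar[1] + 1 / Fbar[2] + 5 / Fbar[3] + 3 / Fbar[4])
  }
  set.seed(202)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:100) {
    cds <- paste(sample(sense, 200, TRUE), collapse = "")
    got <- enc(cds)$nc
    want <- enc_oracle(cds)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_lt(abs(got - want), 1e-9)
    }
  }
})

test_that("ENC stays within [20, 61] on fixture genes", {
  fx <- fixture_small()
  tbl <- enc_per_gene(fx$genes, fx$assembly)
  ok <- !is.na(tbl$nc)
  expect_true(all(tbl$nc[ok] >= 20 - 1e-9))
  expect_true(all(tbl$nc[ok] <= 61 + 1e-9))
})

test_that("scaffold N50 matches its definition and a sort-and-scan oracle", {
  expect_equal(scaffold_n50(100), 100)
  expect_equal(scaffold_n50(c(8, 5, 3, 2)), 5)
  expect_error(scaffold_n50(numeric(0)), "empty")

  n50_oracle <- function(x) {
    s <- sort(x, decreasing = TRUE)
    half <- sum(x) / 2
    acc <- 0
    for (v in s) {
      acc <- acc + v
      if (acc >= half) return(v)
    }
  }
  set.seed(303)
  for (rep in 1:100) {
    lens <- sample.int(100000L, sample(1:1000, 1), replace = TRUE)
    expect_identical(scaffold_n50(lens), n50_oracle(lens))
  }
})
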