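rand_seq <- function(n, gc, seed) {
  set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

test_that("a two-level sequence splits into exactly two domains at the joint", {
  s <- paste0(rand_seq(30000, 0.15, 41), rand_seq(30000, 0.45, 42))
  d <- segment_scaffold(s, segmentation_params(seed = 3))
  expect_equal(nrow(d), 2L)
  expect_lt(abs(d$end[1] - 30000), 500)
  expect_lt(d$gc_all[1], 0.2)
  expect_gt(d$gc_all[2], 0.4)
  # the split point maximises the Jensen-Shannon divergence: compare against
  # an exhaustive single-split maximisation on the binary sequence
  v <- as.integer(strsplit(s, "")[[1]] %in% c("G", "C"))
  n <- length(v); cum <- cumsum(v); tot <- cum[n]
  H <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  ms <- seq(3000L, n - 3000L)
  dj <- H(tot / n) - (ms / n) * H(cum[ms] / ms) -
    ((n - ms) / n) * H((tot - cum[ms]) / (n - ms))
  best <- ms[which.max(dj)]
  expect_lt(abs(d$end[1] - best), 500)
})

test_that("short scaffolds are returned whole and flagged unsegmented", {
  s <- rand_seq(8000, 0.3, 43)
  d <- segment_scaffold(s, segmentation_params(seed = 1))
  expect_equal(nrow(d), 1L)
  expect_true(d$unsegmented)
  expect_equal(c(d$start, d$end), c(1L, 8000L))
})

test_that("segmentation is deterministic and monotone in alpha", {
  s <- paste0(rand_seq(20000, 0.2, 44), rand_seq(15000, 0.45, 45),
              rand_seq(20000, 0.25, 46))
  d1 <- segment_scaffold(s, segmentation_params(seed = 5))
  d2 <- segment_scaffold(s, segmentation_params(seed = 5))
  expect_identical(d1, d2)
  n_by_alpha <- vapply(c(0.01, 0.05, 0.20), function(a) {
    nrow(segment_scaffold(s, segmentation_params(significance_alpha = a, seed = 5)))
  }, numeric(1))
  expect_true(all(diff(n_by_alpha) >= 0))
})

test_that("N runs split domains and Ns are excluded from GC", {
  s <- paste0(rand_seq(15000, 0.2, 47), strrep("N", 50), rand_seq(15000, 0.2, 48))
  d <- segment_scaffold(s, segmentation_params(seed = 2))
  expect_gte(nrow(d), 3L)
  gap <- d[d$start == 15001, ]
  expect_equal(gap$end, 15050)
  expect_equal(gap$n_bases, 0L)
  expect_true(is.na(gap$gc_all))
  # domains partition the scaffold
  expect_equal(d$start, c(1L, utils::head(d$end, -1) + 1L))
  expect_equal(max(d$end), nchar(s))
})

test_that("non-coding domain GC matches a positional counting oracle", {
  seqs <- c(chr1 = paste0(strrep("AT", 250), strrep("GC", 150), strrep("AT", 100)))
  genes <- gene_set(data.frame(gene_id = "g1", scaffold = "chr1", strand = "+",
                               start = 401L, end = 700L))
  dom <- data.frame(scaffold = "chr1", start = 1L, end = 1000L,
                    gc_all = NA_real_, n_bases = 1000L, unsegmented = FALSE)
  out <- domain_noncoding_gc(dom, genes, seqs)
  ch <- strsplit(seqs[["chr1"]], "")[[1]]
  noncoding_pos <- setdiff(1:1000, 401:700)
  expect_equal(out$n_noncoding, length(noncoding_pos))
  expect_equal(out$gc_noncoding, mean(ch[noncoding_pos] %in% c("G", "C")))

  # no genes: gc_noncoding equals gc_all
  dom$gc_all <- mean(ch %in% c("G", "C"))
  empty_genes <- gene_set(data.frame(gene_id = "g2", scaffold = "other",
                                     strand = "+", start = 1L, end = 300L))
  out2 <- domain_noncoding_gc(dom, empty_genes,
                              c(seqs, other = strrep("A", 300)))
  expect_equal(out2$gc_noncoding, out2$gc_all)

  # fully coding domain: undefined
  cover <- gene_set(data.frame(gene_id = "g3", scaffold = "chr1", strand = "+",
                               start = 1L, end = 999L, partial = TRUE))
  out3 <- domain_noncoding_gc(data.frame(scaffold = "chr1", start = 1L,
                                         end = 999L, gc_all = 0.3,
                                         n_bases = 999L, unsegmented = FALSE),
                              cover, seqs)
  expect_true(is.na(out3$gc_noncoding))
  expect_equal(out3$n_noncoding, 0L)
})

test_that("gene-weighted GC is the domain-length-weighted mean", {
  genes <- gene_set(data.frame(gene_id = "g1", scaffold = "chr1", strand = "+",
                               start = 101L, end = 400L))
  dom <- data.frame(scaffold = "chr1", start = c(1L, 221L), end = c(220L, 1000L),
                    gc_all = c(0.2, 0.4), n_bases = c(220L, 780L),
                    unsegmented = FALSE, gc_noncoding = c(0.20, 0.40),
                    n_noncoding = c(100L, 100L))
  w <- gene_weighted_gc(genes, dom)
  # span 101..400: 120 bp in the 0.20 domain, 180 bp in the 0.40 domain
  expect_equal(w$weighted_gc, 0.4 * 0.2 + 0.6 * 0.4)

  # wholly within one domain: exactly that domain's value
  g2 <- gene_set(data.frame(gene_id = "g2", scaffold = "chr1", strand = "+",
                            start = 301L, end = 600L))
  expect_equal(gene_weighted_gc(g2, dom)$weighted_gc, 0.40)

  # unsegmented scaffold: excluded
  dom_u <- data.frame(scaffold = "chr1", start = 1L, end = 1000L,
                      gc_all = 0.3, n_bases = 1000L, unsegmented = TRUE,
                      gc_noncoding = 0.3, n_noncoding = 1000L)
  wu <- gene_weighted_gc(genes, dom_u)
  expect_true(wu$excluded)
  expect_true(is.na(wu$weighted_gc))
})

test_that("weighted GC equals a per-base oracle for straddling genes", {
  fx <- fixture_small()
  params <- segmentation_params(seed = 9)
  dom <- segment_assembly(fx$assembly, params)
  dom <- domain_noncoding_gc(dom, fx$genes, fx$assembly)
  wgc <- gene_weighted_gc(fx$genes, dom)
  gsum <- gene_summary(fx$genes)
  for (i in seq_len(nrow(gsum))) {
    span <- gsum$span_start[i]:gsum$span_end[i]
    d <- dom[dom$scaffold == gsum$scaffold[i], ]
    per_base <- vapply(span, function(b) {
      d$gc_noncoding[which(b >= d$start & b <= d$end)[1]]
    }, numeric(1))
    per_base <- per_base[!is.na(per_base)]
    expect_lt(abs(wgc$weighted_gc[wgc$gene_id == gsum$gene_id[i]] -
                  mean(per_base)), 1e-9)
  }
})
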