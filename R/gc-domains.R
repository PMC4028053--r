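# Recursive Jensen-Shannon segmentation of scaffolds into GC-homogeneous
# compositional domains, non-coding domain GC, and the per-gene
# length-weighted domain GC value.

#' Segmentation parameters
#'
#' @param min_scaffold_length scaffolds shorter than this are returned whole
#'   and flagged unsegmented (default 10,000 bp, the resolution floor of
#'   recursive GC segmentation).
#' @param min_domain_length minimum domain length (default 3,000 bp).
#' @param significance_alpha significance level of the split test.
#' @param null_replicates homogeneous null sequences simulated per split
#'   decision.
#' @param min_gc_contrast minimum GC difference between the two halves for a
#'   split to be accepted (default 0.02): domains differing by less than two
#'   GC percentage points are below the resolution this analysis treats as a
#'   compositional domain boundary, which also keeps sampling-noise splits
#'   out of homogeneous sequence.
#' @param seed integer seed for the null calibration.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(min_scaffold_length = 10000L,
                                min_domain_length = 3000L,
                                significance_alpha = 0.05,
                                null_replicates = 20L,
                                min_gc_contrast = 0.02,
                                seed = 1L) {
  stopifnot_positive(c(min_scaffold_length, min_domain_length, null_replicates),
                     "segmentation lengths/replicates")
  stopifnot_fraction(significance_alpha, "significance_alpha")
  stopifnot_fraction(min_gc_contrast, "min_gc_contrast")
  structure(list(min_scaffold_length = as.integer(min_scaffold_length),
                 min_domain_length = as.integer(min_domain_length),
                 significance_alpha = significance_alpha,
                 null_replicates = as.integer(null_replicates),
                 min_gc_contrast = min_gc_contrast,
                 seed = as.integer(seed)),
            class = "segmentation_params")
}

#' @keywords internal
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

# max Jensen-Shannon divergence over candidate split points of a 0/1 vector,
# evaluated on a grid of at most ~4096 points (exact for short segments)
#' @keywords internal
max_jsd <- function(v, min_len) {
  n <- length(v)
  if (n < 2L * min_len) return(list(d = -Inf, at = NA_integer_))
  cum <- cumsum(v)
  tot <- cum[n]
  p <- tot / n
  ms <- seq.int(min_len, n - min_len)
  step <- max(1L, floor(length(ms) / 4096L))
  ms <- ms[seq.int(1L, length(ms), by = step)]
  nl <- ms
  pl <- cum[ms] / nl
  pr <- (tot - cum[ms]) / (n - nl)
  d <- binary_entropy(p) - (nl / n) * binary_entropy(pl) -
    ((n - nl) / n) * binary_entropy(pr)
  i <- which.max(d)
  list(d = d[i], at = ms[i])
}

# null threshold for a homogeneous segment; the node-local seed depends only
# on (seed, n, composition) so the same node sees the same null sample at any
# alpha, which keeps the domain count monotone in alpha
#' @keywords internal
jsd_threshold <- function(n, p, params) {
  local_seed <- (params$seed * 1000003L +
                 (n %% 100003L) * 131L + round(p * 9973)) %% 2147483647L
  with_seed(local_seed, {
    maxd <- vapply(seq_len(params$null_replicates), function(b) {
      max_jsd(stats::rbinom(n, 1L, p), params$min_domain_length)$d
    }, numeric(1))
    stats::quantile(maxd, 1 - params$significance_alpha, names = FALSE)
  })
}

#' Segment one scaffold into GC compositional domains
#'
#' Recursive binary segmentation on the G/C-vs-A/T binary sequence: each step
#' picks the split maximising the Jensen-Shannon divergence between the two
#' halves and accepts it iff the divergence exceeds the (1 - alpha) quantile
#' of the same statistic on simulated homogeneous sequences of equal length
#' and composition.  Scaffolds shorter than `min_scaffold_length` are
#' returned whole and flagged unsegmented.  Ns are excluded from every GC
#' numerator and denominator; runs of 10 or more Ns split candidate domains
#' outright.
#'
#' @param sequence character scalar or `DNAString`.
#' @param params a [segmentation_params()].
#' @param scaffold scaffold name recorded in the output.
#' @return data frame: `scaffold`, `start`, `end`, `gc_all`, `n_bases`
#'   (non-N), `unsegmented`.
#' @export
segment_scaffold <- function(sequence, params = segmentation_params(),
                             scaffold = "scaffold") {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (L < 1) stop("segment_scaffold: empty sequence")
  ch <- strsplit(s, "")[[1]]
  v <- ifelse(ch %in% c("G", "C"), 1L, ifelse(ch %in% c("A", "T"), 0L, NA_integer_))

  mk_row <- function(start, end, unsegmented = FALSE) {
    vv <- v[start:end]
    nb <- sum(!is.na(vv))
    data.frame(scaffold = scaffold, start = start, end = end,
               gc_all = if (nb > 0) sum(vv, na.rm = TRUE) / nb else NA_real_,
               n_bases = nb, unsegmented = unsegmented,
               stringsAsFactors = FALSE)
  }
  if (L < params$min_scaffold_length) {
    return(mk_row(1L, L, unsegmented = TRUE))
  }

  # hard boundaries at runs of >= 10 Ns
  is_n <- is.na(v)
  r <- rle(is_n)
  seg_bounds <- cumsum(r$lengths)
  seg_starts <- c(1L, utils::head(seg_bounds, -1) + 1L)
  gap <- r$values & r$lengths >= 10L
  pieces <- data.frame(start = seg_starts, end = seg_bounds, gap = gap)
  # merge consecutive non-gap pieces
  grp <- cumsum(c(TRUE, diff(pieces$gap) != 0))
  pieces <- do.call(rbind, lapply(split(pieces, grp), function(p) {
    data.frame(start = min(p$start), end = max(p$end), gap = p$gap[1])
  }))

  out <- list()
  for (i in seq_len(nrow(pieces))) {
    if (pieces$gap[i]) {
      out[[length(out) + 1L]] <- mk_row(pieces$start[i], pieces$end[i])
      next
    }
    idx <- seq.int(pieces$start[i], pieces$end[i])
    idx <- idx[!is.na(v[idx])]
    if (length(idx) == 0) {
      out[[length(out) + 1L]] <- mk_row(pieces$start[i], pieces$end[i])
      next
    }
    vv <- v[idx]
    segs <- segment_recurse(vv, params)
    lo_orig <- pieces$start[i]
    for (j in seq_len(nrow(segs))) {
      o_start <- if (j == 1) lo_orig else idx[segs$lo[j]]
      o_end <- if (j == nrow(segs)) pieces$end[i] else idx[segs$hi[j]]
      out[[length(out) + 1L]] <- mk_row(o_start, o_end)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# returns lo/hi bounds (in compressed coordinates) of accepted domains
#' @keywords internal
segment_recurse <- function(v, params) {
  n <- length(v)
  best <- max_jsd(v, params$min_domain_length)
  if (!is.finite(best$d)) {
    return(data.frame(lo = 1L, hi = n))
  }
  p <- sum(v) / n
  gc_l <- sum(v[seq_len(best$at)]) / best$at
  gc_r <- (sum(v) - gc_l * best$at) / (n - best$at)
  if (abs(gc_l - gc_r) < params$min_gc_contrast) {
    return(data.frame(lo = 1L, hi = n))
  }
  thr <- jsd_threshold(n, p, params)
  if (best$d <= thr) {
    return(data.frame(lo = 1L, hi = n))
  }
  left <- segment_recurse(v[seq_len(best$at)], params)
  right <- segment_recurse(v[seq.int(best$at + 1L, n)], params)
  right$lo <- right$lo + best$at
  right$hi <- right$hi + best$at
  rbind(left, right)
}

#' Segment every scaffold of an assembly
#'
#' @param assembly named `DNAStringSet` or named character vector.
#' @param params a [segmentation_params()].
#' @return data frame of domains across scaffolds (see [segment_scaffold()]).
#' @export
segment_assembly <- function(assembly, params = segmentation_params()) {
  seqs <- as_assembly_chars(assembly)
  do.call(rbind, lapply(names(seqs), function(scf) {
    segment_scaffold(seqs[[scf]], params, scaffold = scf)
  }))
}

#' Non-coding GC content of compositional domains
#'
#' Adds `gc_noncoding` (GC fraction over domain positions not covered by any
#' coding exon on either strand; `NA` when the domain is fully coding) and
#' `n_noncoding` to a domain table.  Codon-usage bias of the genes themselves
#' is thereby kept out of the domain GC values.
#'
#' @param domains data frame from [segment_assembly()] / [segment_scaffold()].
#' @param genes a [gene_set()] (all genes, both strands).
#' @param assembly the assembly the domains were computed on.
#' @return the domain table with `gc_noncoding` and `n_noncoding` columns.
#' @export
domain_noncoding_gc <- function(domains, genes, assembly) {
  seqs <- as_assembly_chars(assembly)
  domains$gc_noncoding <- NA_real_
  domains$n_noncoding <- 0L
  for (scf in unique(domains$scaffold)) {
    s <- toupper(seqs[[scf]])
    ch <- strsplit(s, "")[[1]]
    isgc <- ch %in% c("G", "C")
    isbase <- isgc | ch %in% c("A", "T")
    coding <- logical(nchar(s))
    ex <- genes[genes$scaffold == scf, , drop = FALSE]
    for (j in seq_len(nrow(ex))) coding[ex$start[j]:ex$end[j]] <- TRUE
    sel <- which(domains$scaffold == scf)
    for (i in sel) {
      pos <- domains$start[i]:domains$end[i]
      use <- pos[!coding[pos] & isbase[pos]]
      domains$n_noncoding[i] <- length(use)
      domains$gc_noncoding[i] <- if (length(use) > 0) mean(isgc[use]) else NA_real_
    }
  }
  domains
}

#' Length-weighted domain GC per gene
#'
#' Each gene's value is the mean of the non-coding GC of the domains it
#' spans, weighted by the fraction of the gene's genomic span (first to last
#' coding base) falling in each domain.  Domains with undefined non-coding GC
#' are skipped with renormalisation.  Genes on scaffolds that were too short
#' to segment are excluded (`weighted_gc = NA`, `excluded = TRUE`) and
#' counted by the caller rather than analysed.
#'
#' @param genes a [gene_set()].
#' @param domains domain table with `gc_noncoding` (from
#'   [domain_noncoding_gc()]).
#' @return data frame: `gene_id`, `weighted_gc`, `excluded`.
#' @export
gene_weighted_gc <- function(genes, domains) {
  gsum <- gene_summary(genes)
  rows <- lapply(seq_len(nrow(gsum)), function(i) {
    g <- gsum[i, ]
    d <- domains[domains$scaffold == g$scaffold, , drop = FALSE]
    if (nrow(d) == 0) {
      stop("gene_weighted_gc: no domains for scaffold ", g$scaffold)
    }
    if (all(d$unsegmented)) {
      return(data.frame(gene_id = g$gene_id, weighted_gc = NA_real_,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    ov_lo <- pmax(g$span_start, d$start)
    ov_hi <- pmin(g$span_end, d$end)
    w <- pmax(0L, ov_hi - ov_lo + 1L)
    use <- w > 0 & !is.na(d$gc_noncoding)
    if (!any(use)) {
      return(data.frame(gene_id = g$gene_id, weighted_gc = NA_real_,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(gene_id = g$gene_id,
               weighted_gc = sum(w[use] * d$gc_noncoding[use]) / sum(w[use]),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
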