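# Per-gene structural and codon-usage characterisation.

#' CDS metrics for a gene set
#'
#' @param gs a [gene_set()].
#' @param bin_width histogram bin width for CDS lengths (default 20 nt, bin
#'   edges \[0,20), \[20,40), ...).
#' @return list with `per_gene` (gene_id, cds_length, n_exons, single_exon),
#'   `mean_cds_length`, `range_cds_length`, `total_coding_nt` and `histogram`
#'   (data frame `bin_start`, `bin_end`, `count`).
#' @export
cds_metrics <- function(gs, bin_width = 20L) {
  gsum <- gene_summary(gs)
  per_gene <- data.frame(
    gene_id = gsum$gene_id,
    cds_length = gsum$cds_length,
    n_exons = gsum$n_exons,
    single_exon = gsum$n_exons == 1L,
    stringsAsFactors = FALSE
  )
  breaks <- seq(0L, (max(gsum$cds_length) %/% bin_width + 1L) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(gsum$cds_length, breaks),
                     nbins = length(breaks) - 1L)
  list(
    per_gene = per_gene,
    mean_cds_length = mean(gsum$cds_length),
    range_cds_length = range(gsum$cds_length),
    total_coding_nt = sum(gsum$cds_length),
    histogram = data.frame(bin_start = utils::head(breaks, -1),
                           bin_end = breaks[-1], count = counts)
  )
}

#' Survey splice-site dinucleotides
#'
#' For every intron (the gap between consecutive coding exons), reads the two
#' intronic base pairs at each end; minus-strand introns are
#' reverse-complemented before comparison, so canonical means 5'-GT ... AG-3'
#' on the transcribed strand.  An intron is transcript-supported iff some
#' same-strand spliced alignment has a block gap with identical start and end
#' coordinates; canonical/non-canonical counts are restricted to supported
#' introns.
#'
#' @param gs a [gene_set()].
#' @param assembly the assembly the genes live on.
#' @param alignments an [aln_set()] of transcript alignments (or `NULL`).
#' @param min_intron minimum gap width for an alignment gap to count as an
#'   intron.
#' @return list with `records` (one row per intron: `gene_id`, `intron_start`,
#'   `intron_end`, `donor`, `acceptor`, `canonical`, `valid`,
#'   `transcript_supported`) and `counts` (supported introns only).
#' @export
splice_site_survey <- function(gs, assembly, alignments = NULL,
                               min_intron = 30L) {
  seqs <- as_assembly_chars(assembly)

  gap_keys <- character(0)
  if (!is.null(alignments) && nrow(alignments) > 0) {
    for (b in split(alignments, alignments$aln_id)) {
      if (nrow(b) < 2) next
      b <- b[order(b$start), , drop = FALSE]
      g_lo <- b$end[-nrow(b)] + 1L
      g_hi <- b$start[-1] - 1L
      ok <- g_hi - g_lo + 1L >= min_intron
      if (any(ok)) {
        gap_keys <- c(gap_keys, paste(b$target[1], b$strand[1],
                                      g_lo[ok], g_hi[ok]))
      }
    }
  }
  gap_keys <- unique(gap_keys)

  rows <- list()
  for (gid in unique(gs$gene_id)) {
    ex <- gs[gs$gene_id == gid, , drop = FALSE]
    if (nrow(ex) < 2) next
    ex <- ex[order(ex$start), , drop = FALSE]
    scf <- ex$scaffold[1]
    strand <- ex$strand[1]
    i_lo <- ex$end[-nrow(ex)] + 1L
    i_hi <- ex$start[-1] - 1L
    for (j in seq_along(i_lo)) {
      valid <- i_hi[j] - i_lo[j] + 1L >= 4L
      donor <- acceptor <- NA_character_
      if (valid) {
        left2 <- toupper(substr(seqs[[scf]], i_lo[j], i_lo[j] + 1L))
        right2 <- toupper(substr(seqs[[scf]], i_hi[j] - 1L, i_hi[j]))
        if (strand == "+") {
          donor <- left2
          acceptor <- right2
        } else {
          donor <- revcomp(right2)
          acceptor <- revcomp(left2)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, intron_start = i_lo[j], intron_end = i_hi[j],
        donor = donor, acceptor = acceptor,
        canonical = identical(donor, "GT") && identical(acceptor, "AG"),
        valid = valid,
        transcript_supported = paste(scf, strand, i_lo[j], i_hi[j]) %in% gap_keys,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), intron_start = integer(0),
               intron_end = integer(0), donor = character(0),
               acceptor = character(0), canonical = logical(0),
               valid = logical(0), transcript_supported = logical(0))
  sup <- records[records$transcript_supported & records$valid, , drop = FALSE]
  list(records = records,
       counts = c(canonical = sum(sup$canonical),
                  noncanonical = sum(!sup$canonical),
                  supported = nrow(sup),
                  total_introns = nrow(records)))
}

# degeneracy classes of the standard genetic code (stop codons excluded;
# Met and Trp are non-degenerate and outside the estimator)
ENC_CLASSES <- list(
  `2` = c("F", "Y", "C", "H", "Q", "N", "K", "D", "E"),
  `3` = "I",
  `4` = c("V", "P", "T", "A", "G"),
  `6` = c("L", "S", "R")
)

#' Wright's effective number of codons (Nc)
#'
#' For each amino acid observed n >= 2 times with codon usage fractions p_i,
#' the codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1).  Class
#' averages over the 2-, 3-, 4- and 6-fold degenerate amino acids give
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, truncated at 61.  If the 3-fold class
#' (Ile) is unobserved, the mean of F2 and F4 is substituted.  Nc ranges from
#' 20 (one codon per amino acid) to 61 (all synonymous codons used equally).
#'
#' @param cds character scalar (or `DNAString`) coding sequence.  Trailing
#'   bases beyond the last full codon are dropped with a warning; stop codons
#'   are excluded from the counts.
#' @return list with `nc` (numeric or `NA`), `f_bar` (named class averages),
#'   `codon_counts` and, when `nc` is `NA`, a `reason`.
#' @export
enc <- function(cds) {
  s <- toupper(as.character(cds))
  n <- nchar(s)
  if (n %% 3L != 0L) {
    warning("enc: CDS length not divisible by 3; trailing bases dropped")
    s <- substr(s, 1L, n - n %% 3L)
  }
  codons <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                      seq(3L, nchar(s), by = 3L))
  codons <- codons[!codons %in% STOP_CODONS & !grepl("[^ACGT]", codons)]
  counts <- table(codons)
  gc_map <- Biostrings::GENETIC_CODE
  aa_of <- gc_map[names(counts)]

  f_hat <- sapply(unique(aa_of), function(aa) {
    cc <- as.numeric(counts[aa_of == aa])
    naa <- sum(cc)
    if (naa < 2) return(NA_real_)
    p <- cc / naa
    (naa * sum(p^2) - 1) / (naa - 1)
  })
  names(f_hat) <- unique(aa_of)

  f_bar <- vapply(names(ENC_CLASSES), function(k) {
    vals <- f_hat[intersect(ENC_CLASSES[[k]], names(f_hat))]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))

  if (all(is.na(f_bar))) {
    return(list(nc = NA_real_, f_bar = f_bar, codon_counts = counts,
                reason = "no degenerate amino acid observed at least twice"))
  }
  if (is.na(f_bar[["3"]]) && !is.na(f_bar[["2"]]) && !is.na(f_bar[["4"]])) {
    f_bar[["3"]] <- mean(c(f_bar[["2"]], f_bar[["4"]]))
  }
  if (any(is.na(f_bar))) {
    return(list(nc = NA_real_, f_bar = f_bar, codon_counts = counts,
                reason = paste("undefined class average:",
                               paste(names(f_bar)[is.na(f_bar)], collapse = ","))))
  }
  if (any(f_bar <= 0)) {
    return(list(nc = NA_real_, f_bar = f_bar, codon_counts = counts,
                reason = "class-average homozygosity of zero"))
  }
  nc <- 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] + 5 / f_bar[["4"]] + 3 / f_bar[["6"]]
  list(nc = min(nc, 61), f_bar = f_bar, codon_counts = counts)
}

#' ENC for every gene of a gene set
#'
#' Genes whose CDS length is not a multiple of 3 are analysed on the longest
#' in-frame prefix.
#'
#' @param gs a [gene_set()].
#' @param assembly the assembly.
#' @return data frame `gene_id`, `nc`.
#' @export
enc_per_gene <- function(gs, assembly) {
  cds <- cds_sequences(gs, assembly)
  data.frame(
    gene_id = names(cds),
    nc = vapply(names(cds), function(g) {
      suppressWarnings(enc(as.character(cds[[g]]))$nc)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Scaffold N50
#'
#' The smallest length L such that scaffolds of length >= L together contain
#' at least half of the total assembled bases.
#'
#' @param lengths positive scaffold lengths.
#' @return N50 in bp.
#' @export
scaffold_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("scaffold_n50: empty length list")
  stopifnot_positive(lengths, "scaffold lengths")
  srt <- sort(lengths, decreasing = TRUE)
  srt[which(cumsum(srt) >= sum(srt) / 2)[1]]
}
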