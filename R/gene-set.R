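#' Gene-model table
#'
#' A gene set is a data frame with one row per coding exon and columns
#' `gene_id`, `scaffold`, `strand` (`+`/`-`), `start`, `end` (1-based,
#' inclusive, the GFF3 convention used throughout) and `exon_rank`
#' (1 = 5'-most exon on the transcribed strand).  An optional logical
#' `partial` column marks genes whose CDS length is not a multiple of 3.
#'
#' @param df data frame with the columns above.
#' @return a validated `gene_set` (a data frame).
#' @export
gene_set <- function(df) {
  req <- c("gene_id", "scaffold", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene_set: missing columns: ", paste(miss, collapse = ", "))
  if (!"exon_rank" %in% names(df)) {
    df <- df[order(df$gene_id, df$start), , drop = FALSE]
    df$exon_rank <- stats::ave(df$start, df$gene_id, FUN = seq_along)
    neg <- df$strand == "-"
    if (any(neg)) {
      n_by_gene <- stats::ave(df$start, df$gene_id, FUN = length)
      df$exon_rank[neg] <- n_by_gene[neg] - df$exon_rank[neg] + 1
    }
  }
  if (!"partial" %in% names(df)) df$partial <- FALSE
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_gene_set(df)
  class(df) <- c("gene_set", "data.frame")
  df
}

#' @keywords internal
validate_gene_set <- function(df) {
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene_set: strand must be '+' or '-'")
  }
  if (any(df$end < df$start) || any(df$start < 1)) {
    stop("gene_set: exon coordinates must satisfy 1 <= start <= end")
  }
  by_gene <- split(seq_len(nrow(df)), df$gene_id)
  for (idx in by_gene) {
    g <- df[idx, , drop = FALSE]
    if (length(unique(g$strand)) != 1L) {
      stop("gene_set: gene ", g$gene_id[1], " has exons on both strands")
    }
    if (length(unique(g$scaffold)) != 1L) {
      stop("gene_set: gene ", g$gene_id[1], " spans multiple scaffolds")
    }
    o <- order(g$start)
    if (any(g$start[o][-1] <= g$end[o][-length(idx)])) {
      stop("gene_set: gene ", g$gene_id[1], " has overlapping exons")
    }
    len <- sum(g$end - g$start + 1)
    if (len %% 3L != 0L && !any(g$partial)) {
      stop("gene_set: gene ", g$gene_id[1],
           " CDS length ", len, " is not a multiple of 3 and not flagged partial")
    }
  }
  invisible(df)
}

#' Per-gene summary of a gene set
#'
#' @param gs a [gene_set()].
#' @return data frame with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `span_start`, `span_end`, `cds_length`, `n_exons`.
#' @export
gene_summary <- function(gs) {
  agg <- do.call(rbind, lapply(split(gs, gs$gene_id), function(g) {
    data.frame(
      gene_id = g$gene_id[1], scaffold = g$scaffold[1], strand = g$strand[1],
      span_start = min(g$start), span_end = max(g$end),
      cds_length = sum(g$end - g$start + 1), n_exons = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  agg[order(agg$gene_id), , drop = FALSE]
}

#' Extract spliced CDS sequences for a gene set
#'
#' Exons are concatenated in transcription order; minus-strand genes are
#' reverse-complemented so the returned sequence reads 5' to 3'.
#'
#' @param gs a [gene_set()].
#' @param assembly named `DNAStringSet` (or named character vector).
#' @return named `DNAStringSet`, one sequence per gene.
#' @export
cds_sequences <- function(gs, assembly) {
  seqs <- as_assembly_chars(assembly)
  out <- vapply(split(gs, gs$gene_id), function(g) {
    if (!g$scaffold[1] %in% names(seqs)) {
      stop("cds_sequences: scaffold ", g$scaffold[1], " absent from assembly")
    }
    g <- g[order(g$start), , drop = FALSE]
    s <- paste(substring(seqs[[g$scaffold[1]]], g$start, g$end), collapse = "")
    if (g$strand[1] == "-") revcomp(s) else s
  }, character(1))
  Biostrings::DNAStringSet(out)
}

#' @keywords internal
as_assembly_chars <- function(assembly) {
  if (methods::is(assembly, "DNAStringSet")) {
    stats::setNames(as.character(assembly), names(assembly))
  } else if (is.character(assembly)) {
    assembly
  } else {
    stop("assembly must be a DNAStringSet or a named character vector")
  }
}

#' Convert a gene set to a GRanges of coding exons
#' @param gs a [gene_set()].
#' @return `GRanges` with `gene_id` and `exon_rank` metadata columns.
#' @export
gene_set_granges <- function(gs) {
  GenomicRanges::GRanges(
    seqnames = gs$scaffold,
    ranges = IRanges::IRanges(start = gs$start, end = gs$end),
    strand = gs$strand,
    gene_id = gs$gene_id,
    exon_rank = gs$exon_rank
  )
}

#' Spliced-alignment table
#'
#' Alignments are stored long: one row per aligned block with columns
#' `aln_id`, `query_id`, `target`, `strand`, `start`, `end` plus per-alignment
#' `identity` and `coverage` (repeated across the alignment's blocks; `NA`
#' when the source format does not carry them) and optional `library` /
#' `source` labels.
#'
#' @param df data frame with the columns above.
#' @return a validated `aln_set` (a data frame).
#' @export
aln_set <- function(df) {
  req <- c("aln_id", "query_id", "target", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("aln_set: missing columns: ", paste(miss, collapse = ", "))
  for (col in c("identity", "coverage")) if (!col %in% names(df)) df[[col]] <- NA_real_
  for (col in c("library", "source")) if (!col %in% names(df)) df[[col]] <- NA_character_
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("aln_set: strand must be '+' or '-'")
  if (any(df$end < df$start)) stop("aln_set: blocks must satisfy start <= end")
  ok <- is.na(df$identity) | (df$identity >= 0 & df$identity <= 1)
  if (!all(ok)) stop("aln_set: identity must lie in [0, 1]")
  ok <- is.na(df$coverage) | (df$coverage >= 0 & df$coverage <= 1)
  if (!all(ok)) stop("aln_set: coverage must lie in [0, 1]")
  for (idx in split(seq_len(nrow(df)), df$aln_id)) {
    b <- df[idx, , drop = FALSE]
    o <- order(b$start)
    if (any(b$start[o][-1] <= b$end[o][-length(idx)])) {
      stop("aln_set: alignment ", b$aln_id[1], " has out-of-order or overlapping blocks")
    }
  }
  class(df) <- c("aln_set", "data.frame")
  df
}

#' Per-alignment summary with the spliced flag
#'
#' An alignment is spliced when it has at least two blocks separated by a gap
#' of at least `min_intron` bases on the target (default 30 bp).
#'
#' @param alns an [aln_set()].
#' @param min_intron minimum target gap for an alignment to count as spliced.
#' @return data frame, one row per alignment.
#' @export
aln_summary <- function(alns, min_intron = 30) {
  rows <- lapply(split(alns, alns$aln_id), function(b) {
    b <- b[order(b$start), , drop = FALSE]
    gaps <- if (nrow(b) > 1) b$start[-1] - b$end[-nrow(b)] - 1 else integer(0)
    data.frame(
      aln_id = b$aln_id[1], query_id = b$query_id[1], target = b$target[1],
      strand = b$strand[1], identity = b$identity[1], coverage = b$coverage[1],
      library = b$library[1], source = b$source[1],
      n_blocks = nrow(b), aligned_bp = sum(b$end - b$start + 1),
      spliced = nrow(b) > 1 && any(gaps >= min_intron),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
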