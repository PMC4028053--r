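#' Read an assembly FASTA
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write an assembly FASTA
#' @param assembly named `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_assembly <- function(assembly, path) {
  if (is.character(assembly)) assembly <- Biostrings::DNAStringSet(assembly)
  Biostrings::writeXStringSet(assembly, path, width = 70L)
  invisible(path)
}

#' Read a gene set from GFF3
#'
#' Expects the conventional gene/mRNA/CDS hierarchy; CDS features are grouped
#' per gene through their Parent chain.  Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  cds_idx <- which(type == "CDS")
  if (length(cds_idx) == 0) stop("read_gene_set: no CDS features in ", path)
  id_to_idx <- stats::setNames(seq_along(gr), ids)

  # Follow Parent links (CDS -> mRNA -> gene) to the top-level feature.
  top_parent <- function(i) {
    seen <- 0L
    while (!is.na(parent_of[i])) {
      nxt <- id_to_idx[parent_of[i]]
      if (is.na(nxt)) {
        stop("read_gene_set: feature ", i, " (", type[i],
             ") has unresolvable Parent '", parent_of[i], "'")
      }
      i <- nxt
      seen <- seen + 1L
      if (seen > 10L) stop("read_gene_set: Parent chain too deep at feature ", i)
    }
    i
  }

  rows <- lapply(cds_idx, function(i) {
    if (is.na(parent_of[i])) {
      stop("read_gene_set: CDS feature number ", i, " has no Parent")
    }
    st <- as.character(BiocGenerics::strand(gr[i]))
    if (!st %in% c("+", "-")) {
      stop("read_gene_set: CDS feature number ", i, " has unknown strand '", st, "'")
    }
    g <- top_parent(i)
    partial <- FALSE
    if (!is.null(gr$partial)) {
      # the flag lives on the top-level gene feature
      partial <- isTRUE(as.logical(gr$partial[g])) || isTRUE(as.logical(gr$partial[i]))
    }
    data.frame(
      gene_id = if (!is.na(ids[g])) ids[g] else paste0("feature", g),
      scaffold = as.character(GenomicRanges::seqnames(gr[i])),
      strand = st,
      start = BiocGenerics::start(gr[i]),
      end = BiocGenerics::end(gr[i]),
      partial = partial,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (!is.null(gr$partial)) {
    part <- tapply(df$partial, df$gene_id, any)
    df$partial <- as.logical(part[df$gene_id])
  }
  gene_set(df)
}

#' Write a gene set as GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates) so the
#' file round-trips through [read_gene_set()] without coordinate change.
#'
#' @param gs a [gene_set()].
#' @param path output file.
#' @export
write_gene_set <- function(gs, path) {
  gsum <- gene_summary(gs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  part <- tapply(gs$partial, gs$gene_id, any)
  for (i in seq_len(nrow(gsum))) {
    g <- gsum[i, ]
    attr_extra <- if (isTRUE(part[[g$gene_id]])) ";partial=true" else ""
    writeLines(sprintf("%s\tnewgenes\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       g$scaffold, g$span_start, g$span_end, g$strand,
                       g$gene_id, attr_extra), con)
    mrna <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tnewgenes\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$scaffold, g$span_start, g$span_end, g$strand,
                       mrna, g$gene_id), con)
    ex <- gs[gs$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tnewgenes\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                         ex$scaffold[j], ex$start[j], ex$end[j], ex$strand[j],
                         mrna, mrna), con)
    }
  }
  invisible(path)
}

#' Read spliced alignments (BED12, PSL or GFF3)
#'
#' The dialect is auto-detected from the file extension and can be overridden.
#' Identity is recorded as `NA` when the format does not carry it (BED12);
#' query coverage is computed as aligned query bases / query length when the
#' query length is available, and `NA` otherwise (a downstream operation that
#' needs coverage will then raise an error at its use site).
#'
#' @param path alignment file.
#' @param format one of `"bed12"`, `"psl"`, `"gff3"` or `NULL` (auto).
#' @param query_lengths optional named vector of query lengths (BED12/GFF3).
#' @param library optional library label attached to every alignment.
#' @return an [aln_set()].
#' @export
read_alignments <- function(path, format = NULL, query_lengths = NULL,
                            library = NA_character_) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed12", psl = "psl", gff = "gff3", gff3 = "gff3",
      stop("read_alignments: cannot auto-detect dialect for extension '.", ext,
           "'; pass format=")
    )
  }
  switch(format,
    bed12 = read_alignments_bed12(path, query_lengths, library),
    psl = read_alignments_psl(path, library),
    gff3 = read_alignments_gff3(path, query_lengths, library),
    stop("read_alignments: unknown format '", format, "'")
  )
}

#' @keywords internal
read_alignments_bed12 <- function(path, query_lengths, library) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    gr$blocks <- IRanges::IRangesList(lapply(seq_along(gr), function(i) {
      IRanges::IRanges(1L, BiocGenerics::width(gr[i]))
    }))
  }
  rows <- lapply(seq_along(gr), function(i) {
    bl <- gr$blocks[[i]]
    qid <- if (!is.null(gr$name)) gr$name[i] else paste0("aln", i)
    cov <- NA_real_
    if (!is.null(query_lengths) && qid %in% names(query_lengths)) {
      cov <- sum(BiocGenerics::width(bl)) / query_lengths[[qid]]
    }
    st <- as.character(BiocGenerics::strand(gr[i]))
    if (!st %in% c("+", "-")) st <- "+"
    data.frame(
      aln_id = paste0(qid, "#", i), query_id = qid,
      target = as.character(GenomicRanges::seqnames(gr[i])), strand = st,
      start = BiocGenerics::start(gr[i]) + BiocGenerics::start(bl) - 1L,
      end = BiocGenerics::start(gr[i]) + BiocGenerics::end(bl) - 1L,
      identity = NA_real_, coverage = cov, library = library,
      source = NA_character_, stringsAsFactors = FALSE
    )
  })
  aln_set(do.call(rbind, rows))
}

#' @keywords internal
read_alignments_psl <- function(path, library) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(psLayout|match|---|\\s*$)", lines)]
  if (length(lines) == 0) stop("read_alignments: empty PSL file ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 21) stop("read_alignments: malformed PSL line ", i)
    matches <- as.numeric(f[1]); mism <- as.numeric(f[2]); rep <- as.numeric(f[3])
    strand <- substr(f[9], 1, 1)
    qname <- f[10]; qsize <- as.numeric(f[11]); tname <- f[14]
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    tstarts <- as.integer(strsplit(f[21], ",")[[1]])
    ident <- if (matches + mism > 0) matches / (matches + mism) else NA_real_
    data.frame(
      aln_id = paste0(qname, "#", i), query_id = qname, target = tname,
      strand = strand,
      start = tstarts + 1L, end = tstarts + sizes,
      identity = ident, coverage = sum(sizes) / qsize,
      library = library, source = NA_character_, stringsAsFactors = FALSE
    )
  })
  aln_set(do.call(rbind, rows))
}

#' @keywords internal
read_alignments_gff3 <- function(path, query_lengths, library) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("match", "cDNA_match", "match_part")]
  if (length(gr) == 0) stop("read_alignments: no match features in ", path)
  ids <- as.character(gr$ID)
  rows <- lapply(seq_along(gr), function(i) {
    qid <- if (!is.null(gr$Target) && !is.na(gr$Target[i])) {
      strsplit(as.character(gr$Target[i]), "\\s+")[[1]][1]
    } else {
      ids[i]
    }
    ident <- if (!is.null(gr$identity)) suppressWarnings(as.numeric(gr$identity[i])) else NA_real_
    cov <- if (!is.null(gr$coverage)) suppressWarnings(as.numeric(gr$coverage[i])) else NA_real_
    lib <- if (!is.null(gr$library) && !is.na(gr$library[i])) gr$library[i] else library
    src <- if (!is.null(gr$alnsource)) gr$alnsource[i] else NA_character_
    data.frame(
      aln_id = ids[i], query_id = qid,
      target = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(BiocGenerics::strand(gr[i])),
      start = BiocGenerics::start(gr[i]), end = BiocGenerics::end(gr[i]),
      identity = ident, coverage = cov, library = lib, source = src,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (!is.null(query_lengths)) {
    for (id in unique(df$aln_id[is.na(df$coverage)])) {
      sel <- df$aln_id == id
      q <- df$query_id[sel][1]
      if (q %in% names(query_lengths)) {
        df$coverage[sel] <- sum(df$end[sel] - df$start[sel] + 1) / query_lengths[[q]]
      }
    }
  }
  aln_set(df)
}

#' Write alignments (BED12, PSL or GFF3)
#'
#' The GFF3 dialect writes one `match_part` feature per block sharing an `ID`
#' per alignment, with `identity`, `coverage`, `library` and `alnsource`
#' attributes so [read_alignments()] round-trips losslessly.  BED12 drops
#' identity/coverage (the format has no field for them); PSL stores block
#' structure and approximate match counts.
#'
#' @param alns an [aln_set()].
#' @param path output file.
#' @param format one of `"bed12"`, `"psl"`, `"gff3"`.
#' @param query_lengths named vector of query lengths (required for PSL).
#' @export
write_alignments <- function(alns, path, format = c("gff3", "bed12", "psl"),
                             query_lengths = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  by_aln <- split(alns, alns$aln_id)
  by_aln <- by_aln[order(names(by_aln))]
  if (format == "gff3") {
    writeLines("##gff-version 3", con)
    for (b in by_aln) {
      b <- b[order(b$start), , drop = FALSE]
      for (j in seq_len(nrow(b))) {
        attrs <- sprintf("ID=%s;Target=%s", b$aln_id[1], b$query_id[1])
        if (!is.na(b$identity[1])) attrs <- paste0(attrs, ";identity=", format(b$identity[1], digits = 10))
        if (!is.na(b$coverage[1])) attrs <- paste0(attrs, ";coverage=", format(b$coverage[1], digits = 10))
        if (!is.na(b$library[1])) attrs <- paste0(attrs, ";library=", b$library[1])
        if (!is.na(b$source[1])) attrs <- paste0(attrs, ";alnsource=", b$source[1])
        writeLines(sprintf("%s\tnewgenes\tmatch_part\t%d\t%d\t.\t%s\t.\t%s",
                           b$target[j], b$start[j], b$end[j], b$strand[j], attrs), con)
      }
    }
  } else if (format == "bed12") {
    for (b in by_aln) {
      b <- b[order(b$start), , drop = FALSE]
      chrom_start <- min(b$start) - 1L
      chrom_end <- max(b$end)
      sizes <- paste0(paste(b$end - b$start + 1L, collapse = ","), ",")
      starts <- paste0(paste(b$start - 1L - chrom_start, collapse = ","), ",")
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                         b$target[1], chrom_start, chrom_end, b$query_id[1],
                         b$strand[1], chrom_start, chrom_end, nrow(b),
                         sizes, starts), con)
    }
  } else {
    for (b in by_aln) {
      b <- b[order(b$start), , drop = FALSE]
      qsize <- if (!is.null(query_lengths) && b$query_id[1] %in% names(query_lengths)) {
        query_lengths[[b$query_id[1]]]
      } else {
        stop("write_alignments: PSL output needs query_lengths for ", b$query_id[1])
      }
      aligned <- sum(b$end - b$start + 1L)
      ident <- if (is.na(b$identity[1])) 1 else b$identity[1]
      matches <- round(aligned * ident)
      writeLines(paste(
        matches, aligned - matches, 0, 0, 0, 0, 0, 0, b$strand[1],
        b$query_id[1], qsize, 0, aligned, b$target[1], 0,
        min(b$start) - 1L, max(b$end),
        nrow(b),
        paste0(paste(b$end - b$start + 1L, collapse = ","), ","),
        paste0(paste(cumsum(c(0, head(b$end - b$start + 1L, -1))), collapse = ","), ","),
        paste0(paste(b$start - 1L, collapse = ","), ","),
        sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a simple TSV with a header
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
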