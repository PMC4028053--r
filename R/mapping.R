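# Mapping new coding sequences onto the old assembly and classifying every
# gene as Type I New (absent from the old assembly), Type II New (present but
# unannotated) or Previously Known.

#' Mapping and classification parameters
#'
#' Stringent mode requires 95% identity and 80% query coverage; relaxed mode
#' keeps 95% identity but requires only 50% coverage.  The E-value prefilter
#' applies when external alignments are supplied; the built-in mapper's exact
#' k-mer anchor requirement subsumes it.
#'
#' @param min_identity minimum alignment identity (default 0.95).
#' @param min_coverage minimum query coverage; defaults to 0.80 for
#'   `mode = "stringent"` and 0.50 for `mode = "relaxed"`.
#' @param mode `"stringent"` or `"relaxed"`.
#' @param prefilter_evalue E-value prefilter documented for externally
#'   computed alignments.
#' @return a `mapping_params` list.
#' @export
mapping_params <- function(min_identity = 0.95,
                           min_coverage = NULL,
                           mode = c("stringent", "relaxed"),
                           prefilter_evalue = 1e-20) {
  mode <- match.arg(mode)
  if (is.null(min_coverage)) {
    min_coverage <- if (mode == "stringent") 0.80 else 0.50
  }
  stopifnot_fraction(c(min_identity, min_coverage), "identity/coverage thresholds")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 mode = mode, prefilter_evalue = prefilter_evalue),
            class = "mapping_params")
}

#' Map coding sequences onto an old assembly
#'
#' A deterministic exact-match mapper: 15-mer anchors are matched against both
#' strands of the old assembly, merged into maximal exact blocks (blocks
#' shorter than 25 bp are discarded as anchor noise), and chained co-linearly
#' per query/scaffold/strand to form splice-modelled alignments.  Identity is
#' 1 by construction (blocks are exact); query coverage is the chained query
#' bases over the query length.  Intended for the synthetic fixtures, where
#' the old assembly is an exact subsequence of the new; for real genomes,
#' supply splice-aware alignments via [read_alignments()] instead — both paths
#' share the downstream filtering.
#'
#' @param cds_seqs named `DNAStringSet` (or named character vector) of coding
#'   sequences, e.g. from [cds_sequences()].
#' @param old_assembly named `DNAStringSet` of the old assembly.
#' @param k anchor length.
#' @param min_block minimum exact-block length retained.
#' @param max_gap maximum target gap (intron or deletion) bridged in a chain.
#' @return an [aln_set()] with identity and coverage filled in.
#' @export
map_cds <- function(cds_seqs, old_assembly, k = 15L, min_block = MIN_MAP_BLOCK,
                    max_gap = 50000L) {
  queries <- as_assembly_chars(cds_seqs)
  targets <- as_assembly_chars(old_assembly)
  if (length(targets) == 0) stop("map_cds: empty old assembly")
  if (length(queries) == 0) stop("map_cds: no query sequences")

  # enumerate every k-mer of every query once
  qlen <- nchar(queries)
  km_q <- rep(names(queries), pmax(0L, qlen - k + 1L))
  km_pos <- unlist(lapply(qlen, function(n) if (n >= k) seq_len(n - k + 1L) else integer(0)))
  kmers <- unname(substring(queries[km_q], km_pos, km_pos + k - 1L))
  keep <- !grepl("[^ACGT]", kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  km_q <- km_q[keep]; km_pos <- km_pos[keep]

  hit_rows <- list()
  for (scf in names(targets)) {
    tseq <- Biostrings::DNAString(targets[[scf]])
    L <- length(tseq)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") tseq else Biostrings::reverseComplement(tseq)
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      n_hits <- lengths(starts)
      if (sum(n_hits) == 0) next
      pat <- rep(seq_along(n_hits), n_hits)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query = km_q[pat], qpos = km_pos[pat],
        tpos = unlist(starts), scaffold = scf, strand = strand, tlen = L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hit_rows)) return(empty_aln_set())
  hits <- do.call(rbind, hit_rows)

  # maximal exact runs: consecutive qpos on the same diagonal
  hits$diag <- hits$tpos - hits$qpos
  key <- paste(hits$query, hits$scaffold, hits$strand, hits$diag)
  blocks <- do.call(rbind, lapply(split(hits, key), function(h) {
    qp <- sort(unique(h$qpos))
    run_id <- cumsum(c(1L, diff(qp) != 1L))
    do.call(rbind, lapply(split(qp, run_id), function(r) {
      data.frame(
        query = h$query[1], scaffold = h$scaffold[1], strand = h$strand[1],
        tlen = h$tlen[1],
        qstart = min(r), qend = max(r) + k - 1L,
        tstart = min(r) + h$diag[1], tend = max(r) + k - 1L + h$diag[1],
        stringsAsFactors = FALSE
      )
    }))
  }))
  blocks <- blocks[blocks$qend - blocks$qstart + 1L >= min_block, , drop = FALSE]
  if (nrow(blocks) == 0) return(empty_aln_set())

  # co-linear chaining (maximise covered query bases) per query/scaffold/strand
  out_rows <- list()
  aln_n <- 0L
  for (grp in split(blocks, paste(blocks$query, blocks$scaffold, blocks$strand))) {
    grp <- grp[order(grp$qstart, grp$tstart), , drop = FALSE]
    n <- nrow(grp)
    len <- grp$qend - grp$qstart + 1L
    best <- len
    prev <- rep(NA_integer_, n)
    if (n > 1) {
      # blocks may overlap by up to k-1 junction bases; score the union
      for (i in 2:n) {
        for (j in 1:(i - 1)) {
          q_olap <- grp$qend[j] - grp$qstart[i] + 1L
          t_olap <- grp$tend[j] - grp$tstart[i] + 1L
          gain <- len[i] - max(0L, q_olap)
          if (q_olap < k && t_olap < k &&
              grp$qstart[i] > grp$qstart[j] && grp$tstart[i] > grp$tstart[j] &&
              grp$tstart[i] - grp$tend[j] - 1L <= max_gap &&
              best[j] + gain > best[i]) {
            best[i] <- best[j] + gain
            prev[i] <- j
          }
        }
      }
    }
    top <- which.max(best)
    chain <- top
    while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
    cb <- grp[chain, , drop = FALSE]
    if (nrow(cb) > 1) {
      # trim junction overlaps so emitted blocks are disjoint
      for (i in 2:nrow(cb)) {
        d <- max(0L, cb$qend[i - 1] - cb$qstart[i] + 1L,
                 cb$tend[i - 1] - cb$tstart[i] + 1L)
        cb$qstart[i] <- cb$qstart[i] + d
        cb$tstart[i] <- cb$tstart[i] + d
      }
    }
    aln_n <- aln_n + 1L
    q <- cb$query[1]
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(cb$qstart, cb$qend)
    )))
    if (cb$strand[1] == "-") {
      ts <- cb$tlen[1] - cb$tend + 1L
      te <- cb$tlen[1] - cb$tstart + 1L
    } else {
      ts <- cb$tstart
      te <- cb$tend
    }
    out_rows[[aln_n]] <- data.frame(
      aln_id = sprintf("%s|%s|%s", q, cb$scaffold[1], cb$strand[1]),
      query_id = q, target = cb$scaffold[1], strand = cb$strand[1],
      start = ts, end = te,
      identity = 1.0, coverage = covered / qlen[[q]],
      stringsAsFactors = FALSE
    )
  }
  aln_set(do.call(rbind, out_rows))
}

#' @keywords internal
empty_aln_set <- function() {
  aln_set(data.frame(aln_id = character(0), query_id = character(0),
                     target = character(0), strand = character(0),
                     start = integer(0), end = integer(0),
                     identity = numeric(0), coverage = numeric(0),
                     stringsAsFactors = FALSE))
}

#' Filter alignments on identity and coverage
#'
#' An alignment is retained iff identity >= `min_identity` and query coverage
#' >= `min_coverage`.  Alignments with unknown coverage are an error: supply
#' query lengths when reading the alignment file.
#'
#' @param alns an [aln_set()].
#' @param params a [mapping_params()].
#' @return the retained subset of `alns`.
#' @export
filter_alignments <- function(alns, params = mapping_params()) {
  if (nrow(alns) == 0) return(alns)
  per <- aln_summary(alns)
  if (any(is.na(per$coverage))) {
    stop("filter_alignments: coverage unknown for ",
         sum(is.na(per$coverage)), " alignment(s); ",
         "supply query lengths to read_alignments()")
  }
  if (any(is.na(per$identity))) {
    stop("filter_alignments: identity unknown for ",
         sum(is.na(per$identity)), " alignment(s)")
  }
  keep <- per$aln_id[per$identity >= params$min_identity &
                     per$coverage >= params$min_coverage]
  out <- alns[alns$aln_id %in% keep, , drop = FALSE]
  class(out) <- class(alns)
  out
}

#' Classify genes as Type I New, Type II New or Previously Known
#'
#' A gene with no retained alignment is Type I New.  Otherwise, if zero bases
#' of its alignment blocks intersect any old-gene coding exon on the same
#' strand, it is Type II New; any same-strand coding overlap (a single coding
#' base pair suffices) makes it Previously Known.  A `multi_overlap` flag
#' marks genes whose alignments overlap more than one old gene.
#'
#' @param new_genes the new [gene_set()] (classified per gene; alignments are
#'   matched by `query_id` == `gene_id`).
#' @param retained_alns retained alignments from [filter_alignments()].
#' @param old_genes old-annotation [gene_set()] in old-assembly coordinates
#'   (may be `NULL` when the old set is empty).
#' @param mode label recorded in the output (`"stringent"` or `"relaxed"`).
#' @param old_scaffolds optional character vector of old-assembly scaffold
#'   names; when given, an alignment to an unknown scaffold is an error.
#' @return data frame: `gene_id`, `class`, `mode`, `overlap_bp`,
#'   `n_alignments`, `best_coverage`, `multi_overlap`.
#' @export
classify_genes <- function(new_genes, retained_alns, old_genes,
                           mode = "stringent", old_scaffolds = NULL) {
  gsum <- gene_summary(new_genes)
  if (!is.null(old_scaffolds) && nrow(retained_alns) > 0) {
    bad <- setdiff(unique(retained_alns$target), old_scaffolds)
    if (length(bad)) {
      stop("classify_genes: alignment targets absent from old assembly: ",
           paste(bad, collapse = ", "))
    }
  }
  old_gr <- if (!is.null(old_genes) && nrow(old_genes) > 0) {
    gene_set_granges(old_genes)
  } else {
    GenomicRanges::GRanges()
  }
  rows <- lapply(seq_len(nrow(gsum)), function(i) {
    gid <- gsum$gene_id[i]
    a <- retained_alns[retained_alns$query_id == gid, , drop = FALSE]
    if (nrow(a) == 0) {
      return(data.frame(gene_id = gid, class = "TypeI", mode = mode,
                        overlap_bp = 0L, n_alignments = 0L,
                        best_coverage = NA_real_, multi_overlap = FALSE,
                        stringsAsFactors = FALSE))
    }
    blocks <- GenomicRanges::GRanges(a$target,
                                     IRanges::IRanges(a$start, a$end),
                                     strand = a$strand)
    ov_bp <- 0L
    n_old <- 0L
    if (length(old_gr) > 0) {
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(blocks, old_gr, ignore.strand = FALSE)
      )
      if (length(hits) > 0) {
        pi <- IRanges::pintersect(blocks[S4Vectors::queryHits(hits)],
                                  old_gr[S4Vectors::subjectHits(hits)])
        ov_bp <- sum(BiocGenerics::width(pi))
        n_old <- length(unique(old_gr$gene_id[S4Vectors::subjectHits(hits)]))
      }
    }
    data.frame(
      gene_id = gid,
      class = if (ov_bp == 0L) "TypeII" else "PreviouslyKnown",
      mode = mode, overlap_bp = ov_bp,
      n_alignments = length(unique(a$aln_id)),
      best_coverage = max(a$coverage),
      multi_overlap = n_old > 1L, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run mapping + classification in both stringent and relaxed modes
#'
#' @param new_genes new [gene_set()].
#' @param new_assembly new assembly (for CDS extraction).
#' @param old_assembly old assembly.
#' @param old_genes old [gene_set()] (or `NULL`).
#' @param alignments optional precomputed [aln_set()]; when `NULL` the
#'   built-in [map_cds()] mapper is used.
#' @return named list of classification data frames (`stringent`, `relaxed`)
#'   plus the unfiltered alignments under `alignments`.
#' @export
classify_both_modes <- function(new_genes, new_assembly, old_assembly,
                                old_genes = NULL, alignments = NULL) {
  if (is.null(alignments)) {
    cds <- cds_sequences(new_genes, new_assembly)
    alignments <- map_cds(cds, old_assembly)
  }
  old_scf <- names(as_assembly_chars(old_assembly))
  res <- lapply(c(stringent = "stringent", relaxed = "relaxed"), function(m) {
    kept <- filter_alignments(alignments, mapping_params(mode = m))
    classify_genes(new_genes, kept, old_genes, mode = m, old_scaffolds = old_scf)
  })
  res$alignments <- alignments
  res
}
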