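# Per-gene evidence tallies: transcript overlap with the strand rule,
# expression breadth, peptide matching, homolog overlap, conservation, and
# the aggregate evidence matrix.

#' Transcript overlap per gene and library
#'
#' A spliced alignment on the opposite strand from the gene is discarded (its
#' direction contradicts the gene); spliced same-strand alignments and all
#' unspliced alignments (whose direction cannot be determined) support a gene
#' iff at least one base of an alignment block intersects a coding exon.
#'
#' @param gs a [gene_set()].
#' @param alignments an [aln_set()] with a `library` column.
#' @param min_intron spliced/unspliced boundary passed to [aln_summary()].
#' @return list with `spliced` and `unspliced`: logical gene x library
#'   matrices.
#' @export
transcript_overlap <- function(gs, alignments, min_intron = 30L) {
  gsum <- gene_summary(gs)
  libs <- sort(unique(alignments$library))
  spliced_m <- matrix(FALSE, nrow(gsum), length(libs),
                      dimnames = list(gsum$gene_id, libs))
  unspliced_m <- spliced_m
  if (is.null(alignments) || nrow(alignments) == 0) {
    return(list(spliced = spliced_m, unspliced = unspliced_m))
  }
  per <- aln_summary(alignments, min_intron = min_intron)
  exon_gr <- gene_set_granges(gs)
  block_gr <- GenomicRanges::GRanges(alignments$target,
                                     IRanges::IRanges(alignments$start,
                                                      alignments$end),
                                     strand = alignments$strand)
  spliced_of <- stats::setNames(per$spliced, per$aln_id)
  lib_of <- stats::setNames(per$library, per$aln_id)

  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(block_gr, exon_gr, ignore.strand = TRUE)
  )
  if (length(hits) > 0) {
    aln_ids <- alignments$aln_id[S4Vectors::queryHits(hits)]
    gene_ids <- exon_gr$gene_id[S4Vectors::subjectHits(hits)]
    same_strand <- alignments$strand[S4Vectors::queryHits(hits)] ==
      as.character(BiocGenerics::strand(exon_gr[S4Vectors::subjectHits(hits)]))
    spl <- spliced_of[aln_ids]
    lib <- lib_of[aln_ids]
    use_spliced <- spl & same_strand
    use_unspliced <- !spl
    for (i in which(use_spliced)) spliced_m[gene_ids[i], lib[i]] <- TRUE
    for (i in which(use_unspliced)) unspliced_m[gene_ids[i], lib[i]] <- TRUE
  }
  list(spliced = spliced_m, unspliced = unspliced_m)
}

#' Expression breadth over the four designated tissues
#'
#' narrow = spliced support in exactly one tissue; broad = support in all
#' four; none = support in zero; neither otherwise.
#'
#' @param spliced_support logical gene x library matrix (from
#'   [transcript_overlap()]).
#' @param tissues the designated single-tissue library names.
#' @return data frame `gene_id`, `breadth`.
#' @export
expression_breadth <- function(spliced_support,
                               tissues = c("brain", "antennae", "ovary", "testes")) {
  if (length(tissues) < 2) {
    stop("expression_breadth: need at least two designated tissue libraries")
  }
  missing <- setdiff(tissues, colnames(spliced_support))
  m <- matrix(FALSE, nrow(spliced_support), length(missing),
              dimnames = list(rownames(spliced_support), missing))
  sup <- cbind(spliced_support, m)[, tissues, drop = FALSE]
  k <- rowSums(sup)
  data.frame(
    gene_id = rownames(sup),
    breadth = ifelse(k == 0, "none",
                     ifelse(k == 1, "narrow",
                            ifelse(k == length(tissues), "broad", "neither"))),
    stringsAsFactors = FALSE
  )
}

#' Peptide support by exact substring match
#'
#' A gene is supported iff at least one peptide of length >= 6 amino acids is
#' an exact substring of its translated CDS (equivalent to a 100%-identity,
#' full-length peptide alignment).  Shorter peptides are ignored; peptides
#' with non-amino-acid symbols are rejected with a warning.
#'
#' @param peptides character vector of peptide sequences.
#' @param proteins named character vector (or `AAStringSet`) of proteins, one
#'   per gene.
#' @param min_length minimum peptide length counted (default 6).
#' @return list with `supported` (named logical per gene) and `matches`
#'   (data frame `peptide`, `gene_id`, `position`).
#' @export
peptide_support <- function(peptides, proteins, min_length = 6L) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  peptides <- toupper(peptides)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides)
  if (any(bad)) {
    warning("peptide_support: rejecting ", sum(bad),
            " peptide(s) with non-amino-acid symbols")
    peptides <- peptides[!bad]
  }
  peptides <- unique(peptides[nchar(peptides) >= min_length])
  supported <- stats::setNames(rep(FALSE, length(proteins)), names(proteins))
  match_rows <- list()
  for (p in peptides) {
    pos <- regexpr(p, proteins, fixed = TRUE)
    hit <- which(pos > 0)
    supported[hit] <- TRUE
    for (h in hit) {
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        peptide = p, gene_id = names(proteins)[h], position = as.integer(pos[h]),
        stringsAsFactors = FALSE
      )
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(peptide = character(0), gene_id = character(0),
               position = integer(0))
  list(supported = supported, matches = matches)
}

#' Protein-homolog overlap per gene
#'
#' A gene is supported by a homolog alignment iff at least one coding base
#' pair overlaps on the same strand.  When identity/coverage fields are
#' present, alignments are first admitted at `min_identity` / `min_coverage`
#' (defaults 0.60/0.60, the usual protein-to-genome alignment thresholds);
#' alignments without those fields are taken as given.
#'
#' @param gs a [gene_set()].
#' @param alignments an [aln_set()] with a `source` column labelling the
#'   source proteome (e.g. `"dmel"` for the Dipteran reference).
#' @param min_identity,min_coverage admission thresholds.
#' @return logical gene x source matrix with an extra `any` column.
#' @export
homolog_overlap <- function(gs, alignments, min_identity = 0.60,
                            min_coverage = 0.60) {
  gsum <- gene_summary(gs)
  sources <- sort(unique(alignments$source))
  out <- matrix(FALSE, nrow(gsum), length(sources) + 1L,
                dimnames = list(gsum$gene_id, c(sources, "any")))
  if (is.null(alignments) || nrow(alignments) == 0) return(out)
  ok_id <- is.na(alignments$identity) | alignments$identity >= min_identity
  ok_cov <- is.na(alignments$coverage) | alignments$coverage >= min_coverage
  alignments <- alignments[ok_id & ok_cov, , drop = FALSE]
  if (nrow(alignments) == 0) return(out)
  exon_gr <- gene_set_granges(gs)
  block_gr <- GenomicRanges::GRanges(alignments$target,
                                     IRanges::IRanges(alignments$start,
                                                      alignments$end),
                                     strand = alignments$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(block_gr, exon_gr, ignore.strand = FALSE)
  )
  if (length(hits) > 0) {
    src <- alignments$source[S4Vectors::queryHits(hits)]
    gid <- exon_gr$gene_id[S4Vectors::subjectHits(hits)]
    for (i in seq_along(src)) {
      out[gid[i], src[i]] <- TRUE
      out[gid[i], "any"] <- TRUE
    }
  }
  out
}

#' Build the per-gene evidence matrix and per-class tallies
#'
#' Biological gene evidence is transcript OR peptide OR homolog OR
#' domain-table support; `any_support` additionally ORs the cross-genome
#' conservation flags (conservation alone does not count as gene evidence).
#'
#' @param gs a [gene_set()].
#' @param transcript per-gene transcript support from [transcript_overlap()].
#' @param peptide named logical from [peptide_support()].
#' @param homolog matrix from [homolog_overlap()] (or `NULL`).
#' @param conservation data frame `gene_id`, `informant`, `supported`.
#' @param domain_table data frame `gene_id`, `domain_id`.
#' @param tissues designated tissue libraries for breadth.
#' @return data frame, one row per gene, with per-library spliced flags,
#'   `spliced_any`, `unspliced_any`, `transcript_any`, `peptide`,
#'   `homolog_any`, `homolog_dmel`, `domain_table`, per-informant
#'   conservation, `biological_gene_evidence`, `any_support` and `breadth`.
#' @export
build_evidence_matrix <- function(gs, transcript, peptide = NULL,
                                  homolog = NULL, conservation = NULL,
                                  domain_table = NULL,
                                  tissues = c("brain", "antennae", "ovary", "testes")) {
  gsum <- gene_summary(gs)
  ids <- gsum$gene_id
  em <- data.frame(gene_id = ids, stringsAsFactors = FALSE)

  spl <- transcript$spliced
  unspl <- transcript$unspliced
  for (lib in colnames(spl)) em[[paste0("spliced_", lib)]] <- unname(spl[ids, lib])
  em$spliced_any <- unname(rowSums(spl[ids, , drop = FALSE]) > 0)
  em$unspliced_any <- unname(rowSums(unspl[ids, , drop = FALSE]) > 0)
  em$transcript_any <- em$spliced_any | em$unspliced_any

  em$peptide <- if (!is.null(peptide)) unname(peptide[ids]) else FALSE
  em$peptide[is.na(em$peptide)] <- FALSE

  if (!is.null(homolog)) {
    em$homolog_any <- unname(homolog[ids, "any"])
    em$homolog_dmel <- if ("dmel" %in% colnames(homolog)) {
      unname(homolog[ids, "dmel"])
    } else FALSE
  } else {
    em$homolog_any <- FALSE
    em$homolog_dmel <- FALSE
  }

  if (!is.null(conservation) && nrow(conservation) > 0) {
    unknown <- setdiff(unique(conservation$gene_id), ids)
    if (length(unknown)) {
      warning("build_evidence_matrix: dropping conservation rows for ",
              length(unknown), " gene(s) absent from the gene set")
      conservation <- conservation[conservation$gene_id %in% ids, , drop = FALSE]
    }
    for (inf in sort(unique(conservation$informant))) {
      sel <- conservation[conservation$informant == inf & conservation$supported, ]
      em[[paste0("conservation_", inf)]] <- ids %in% sel$gene_id
    }
  }
  cons_cols <- grep("^conservation_", names(em), value = TRUE)
  cons_any <- if (length(cons_cols)) {
    Reduce(`|`, em[cons_cols])
  } else rep(FALSE, nrow(em))

  if (!is.null(domain_table) && nrow(domain_table) > 0) {
    unknown <- setdiff(unique(domain_table$gene_id), ids)
    if (length(unknown)) {
      warning("build_evidence_matrix: dropping domain rows for ",
              length(unknown), " gene(s) absent from the gene set")
    }
    em$domain_table <- ids %in% domain_table$gene_id
  } else {
    em$domain_table <- FALSE
  }

  em$biological_gene_evidence <- em$transcript_any | em$peptide |
    em$homolog_any | em$domain_table
  em$any_support <- em$biological_gene_evidence | cons_any

  br <- expression_breadth(spl, tissues = tissues)
  em$breadth <- br$breadth[match(ids, br$gene_id)]
  em
}
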