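# The class-by-class summary report (one row group per feature family,
# columns All / Type I / Type II / Previously Known) and the statistical
# comparisons between classes.

REPORT_CLASSES <- c("All", "TypeI", "TypeII", "PreviouslyKnown")

#' Build the class-by-class summary report
#'
#' Aggregates every characterisation into one long table: each row carries a
#' feature and a gene class with a count and a percentage (to one decimal) or
#' a mean value.  Count rows partition: TypeI + TypeII + PreviouslyKnown =
#' All.
#'
#' @param class_labels classification data frame from [classify_genes()]
#'   (one mode).
#' @param gs the new [gene_set()].
#' @param cds per-gene CDS metrics (`cds_metrics(gs)$per_gene`).
#' @param splice splice-site records from [splice_site_survey()].
#' @param evidence evidence matrix from [build_evidence_matrix()].
#' @param weighted_gc data frame from [gene_weighted_gc()].
#' @param enc_tbl data frame from [enc_per_gene()].
#' @return data frame: `section`, `metric`, `class`, `count`, `percent`,
#'   `value`.
#' @export
build_report <- function(class_labels, gs, cds, splice, evidence,
                         weighted_gc, enc_tbl) {
  for (nm in c("class_labels", "cds", "evidence", "weighted_gc", "enc_tbl")) {
    if (is.null(get(nm))) stop("build_report: missing upstream table: ", nm)
  }
  cls <- stats::setNames(class_labels$class, class_labels$gene_id)
  ids_of <- function(klass) {
    if (klass == "All") names(cls) else names(cls)[cls == klass]
  }
  n_total <- length(cls)

  rows <- list()
  add <- function(section, metric, counts = NULL, denoms = NULL, values = NULL) {
    for (k in REPORT_CLASSES) {
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section, metric = metric, class = k,
        count = if (!is.null(counts)) counts[[k]] else NA_integer_,
        percent = if (!is.null(counts) && !is.null(denoms)) {
          coverage_percent(counts[[k]], denoms[[k]])
        } else NA_real_,
        value = if (!is.null(values)) values[[k]] else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  count_by <- function(flag_ids) {
    sapply(REPORT_CLASSES, function(k) length(intersect(flag_ids, ids_of(k))),
           simplify = FALSE)
  }
  class_sizes <- sapply(REPORT_CLASSES, function(k) length(ids_of(k)),
                        simplify = FALSE)
  total_denom <- sapply(REPORT_CLASSES, function(k) n_total, simplify = FALSE)
  mean_by <- function(x, ids) {
    sapply(REPORT_CLASSES, function(k) {
      v <- x[ids %in% ids_of(k)]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, simplify = FALSE)
  }

  add("genes", "n_genes", counts = class_sizes, denoms = total_denom)

  add("cds", "mean_cds_length", values = mean_by(cds$cds_length, cds$gene_id))
  add("cds", "mean_n_exons", values = mean_by(cds$n_exons, cds$gene_id))
  add("cds", "single_exon_genes",
      counts = count_by(cds$gene_id[cds$single_exon]), denoms = class_sizes)
  add("cds", "multi_exon_genes",
      counts = count_by(cds$gene_id[!cds$single_exon]), denoms = class_sizes)

  if (!is.null(splice) && nrow(splice) > 0) {
    intr_by <- sapply(REPORT_CLASSES, function(k) {
      sum(splice$gene_id %in% ids_of(k))
    }, simplify = FALSE)
    add("intron", "n_introns", counts = intr_by,
        denoms = sapply(REPORT_CLASSES, function(k) nrow(splice), simplify = FALSE))
    sup_by <- sapply(REPORT_CLASSES, function(k) {
      sum(splice$transcript_supported & splice$gene_id %in% ids_of(k))
    }, simplify = FALSE)
    add("intron", "supported_introns", counts = sup_by, denoms = intr_by)
  }

  add("peptide", "peptide_match",
      counts = count_by(evidence$gene_id[evidence$peptide]), denoms = class_sizes)
  add("protein", "homolog_any",
      counts = count_by(evidence$gene_id[evidence$homolog_any]), denoms = class_sizes)
  add("protein", "homolog_dmel",
      counts = count_by(evidence$gene_id[evidence$homolog_dmel]), denoms = class_sizes)

  add("expression", "transcript_any",
      counts = count_by(evidence$gene_id[evidence$transcript_any]), denoms = class_sizes)
  add("expression", "spliced_any",
      counts = count_by(evidence$gene_id[evidence$spliced_any]), denoms = class_sizes)
  add("expression", "spliced_none",
      counts = count_by(evidence$gene_id[!evidence$spliced_any]), denoms = class_sizes)
  add("expression", "broad",
      counts = count_by(evidence$gene_id[evidence$breadth == "broad"]),
      denoms = class_sizes)
  add("expression", "narrow",
      counts = count_by(evidence$gene_id[evidence$breadth == "narrow"]),
      denoms = class_sizes)

  for (cc in grep("^conservation_", names(evidence), value = TRUE)) {
    add("conservation", cc,
        counts = count_by(evidence$gene_id[evidence[[cc]]]), denoms = class_sizes)
  }
  add("evidence", "biological_gene_evidence",
      counts = count_by(evidence$gene_id[evidence$biological_gene_evidence]),
      denoms = class_sizes)
  add("evidence", "any_support",
      counts = count_by(evidence$gene_id[evidence$any_support]), denoms = class_sizes)

  add("gc", "genes_on_segmented_scaffolds",
      counts = count_by(weighted_gc$gene_id[!weighted_gc$excluded]),
      denoms = class_sizes)
  wg <- weighted_gc[!weighted_gc$excluded, ]
  add("gc", "mean_weighted_gc_percent",
      values = lapply(mean_by(wg$weighted_gc * 100, wg$gene_id), function(v) {
        if (is.na(v)) v else round(v, 2)
      }))

  ok <- !is.na(enc_tbl$nc)
  add("enc", "mean_nc",
      values = lapply(mean_by(enc_tbl$nc[ok], enc_tbl$gene_id[ok]), function(v) {
        if (is.na(v)) v else round(v, 2)
      }))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statistical comparisons between gene classes
#'
#' Frequency features are compared with the uncorrected Pearson chi-square
#' test (1 df); mean features with [mean_comparison()] (the larger of the KS
#' and Welch P-values is reported).  Each New class is compared against the
#' Previously Known class.  P-values are reported raw, without
#' multiple-testing correction.
#'
#' @param class_labels classification data frame (one mode).
#' @param cds per-gene CDS metrics.
#' @param evidence evidence matrix.
#' @param weighted_gc per-gene weighted GC.
#' @param enc_tbl per-gene ENC.
#' @return data frame: `feature`, `comparison`, `test`, `statistic`,
#'   `p_reported`, `direction`.
#' @export
class_comparisons <- function(class_labels, cds, evidence, weighted_gc,
                              enc_tbl) {
  cls <- stats::setNames(class_labels$class, class_labels$gene_id)
  known <- names(cls)[cls == "PreviouslyKnown"]
  rows <- list()
  for (newk in c("TypeI", "TypeII")) {
    grp <- names(cls)[cls == newk]
    if (length(grp) == 0 || length(known) == 0) next
    comp <- paste0(newk, "_vs_Known")

    prop_feats <- list(
      single_exon = cds$gene_id[cds$single_exon],
      spliced_any = evidence$gene_id[evidence$spliced_any],
      narrow = evidence$gene_id[evidence$breadth == "narrow"],
      broad = evidence$gene_id[evidence$breadth == "broad"],
      peptide = evidence$gene_id[evidence$peptide],
      homolog_any = evidence$gene_id[evidence$homolog_any],
      homolog_dmel = evidence$gene_id[evidence$homolog_dmel]
    )
    for (f in names(prop_feats)) {
      a <- length(intersect(prop_feats[[f]], grp))
      b <- length(intersect(prop_feats[[f]], known))
      res <- chisq_prop(a, length(grp), b, length(known))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, comparison = comp, test = "proportion_chisq",
        statistic = res$statistic, p_reported = res$p,
        direction = sign(a / length(grp) - b / length(known)),
        stringsAsFactors = FALSE
      )
    }

    mean_feats <- list(
      cds_length = stats::setNames(cds$cds_length, cds$gene_id),
      weighted_gc = stats::setNames(weighted_gc$weighted_gc, weighted_gc$gene_id),
      nc = stats::setNames(enc_tbl$nc, enc_tbl$gene_id)
    )
    for (f in names(mean_feats)) {
      x <- mean_feats[[f]]
      a <- x[names(x) %in% grp]
      b <- x[names(x) %in% known]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      res <- mean_comparison(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, comparison = comp, test = "mean_ks_welch",
        statistic = NA_real_, p_reported = res$p_reported,
        direction = sign(res$mean_a - res$mean_b),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
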