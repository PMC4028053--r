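# End-to-end orchestration: read inputs, classify, segment, characterise,
# tally evidence, test, report.

#' Run the full gene-upgrade analysis pipeline
#'
#' Executes mapping/classification (both stringent and relaxed), GC-domain
#' segmentation with per-gene weighted GC, structural and codon-usage
#' characterisation, evidence tallies and the class-by-class report, writing
#' every intermediate table into the output directory.  Reruns on the same
#' inputs produce byte-identical outputs.
#'
#' @param config a list or path to a YAML file with components `inputs`
#'   (paths: `new_assembly`, `new_genes`, `old_assembly`, and optionally
#'   `old_genes`, `transcripts`, `homologs`, `peptides`, `conservation`,
#'   `domain_table`), `params` (optional: `seed`, `alpha`,
#'   `min_domain_length`, `null_replicates`, `min_intron`, `tissues`) and
#'   `output_dir`.
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  params <- config$params
  if (is.null(params)) params <- list()
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("run_pipeline: config$output_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  p_get <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  seed <- p_get("seed", 1L)
  tissues <- p_get("tissues", c("brain", "antennae", "ovary", "testes"))
  min_intron <- p_get("min_intron", 30L)

  need <- function(key) {
    path <- inputs[[key]]
    if (is.null(path)) stop("run_pipeline: config$inputs$", key, " is required")
    for (pp in path) if (!file.exists(pp)) {
      stop("run_pipeline: missing input file: ", pp)
    }
    path
  }
  optional <- function(key) {
    path <- inputs[[key]]
    if (is.null(path)) return(NULL)
    for (pp in path) if (!file.exists(pp)) {
      stop("run_pipeline: missing input file: ", pp)
    }
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  log <- list(package = "newgenes",
              version = as.character(utils::packageVersion("newgenes")),
              seed = seed, params = params, inputs = inputs)

  res <- list()
  res$new_assembly <- stage("read_inputs", read_assembly(need("new_assembly")))
  res$new_genes <- stage("read_inputs", read_gene_set(need("new_genes")))
  res$old_assembly <- stage("read_inputs", read_assembly(need("old_assembly")))
  og_path <- optional("old_genes")
  res$old_genes <- if (!is.null(og_path)) {
    stage("read_inputs", read_gene_set(og_path))
  } else NULL

  res$classification <- stage("classify", classify_both_modes(
    res$new_genes, res$new_assembly, res$old_assembly, res$old_genes
  ))
  write_tsv(res$classification$stringent,
            file.path(out_dir, "classification_stringent.tsv"))
  write_tsv(res$classification$relaxed,
            file.path(out_dir, "classification_relaxed.tsv"))

  seg_params <- segmentation_params(
    min_domain_length = p_get("min_domain_length", 3000L),
    significance_alpha = p_get("alpha", 0.05),
    null_replicates = p_get("null_replicates", 20L),
    seed = seed
  )
  res$domains <- stage("segment", {
    d <- segment_assembly(res$new_assembly, seg_params)
    domain_noncoding_gc(d, res$new_genes, res$new_assembly)
  })
  bed <- data.frame(chrom = res$domains$scaffold,
                    chromStart = res$domains$start - 1L,
                    chromEnd = res$domains$end,
                    gc_all = round(res$domains$gc_all, 5),
                    gc_noncoding = round(res$domains$gc_noncoding, 5))
  write_tsv(bed, file.path(out_dir, "domains.bed"))
  res$weighted_gc <- stage("segment", gene_weighted_gc(res$new_genes, res$domains))
  write_tsv(res$weighted_gc, file.path(out_dir, "gene_weighted_gc.tsv"))

  tx_path <- optional("transcripts")
  res$transcripts <- if (!is.null(tx_path)) {
    stage("read_evidence", do.call(rbind, lapply(tx_path, read_alignments)))
  } else NULL

  res$cds <- stage("features", cds_metrics(res$new_genes))
  res$splice <- stage("features", splice_site_survey(
    res$new_genes, res$new_assembly, res$transcripts, min_intron = min_intron
  ))
  res$enc <- stage("features", enc_per_gene(res$new_genes, res$new_assembly))
  feats <- merge(res$cds$per_gene, res$enc, by = "gene_id")
  write_tsv(feats, file.path(out_dir, "gene_features.tsv"))
  write_tsv(res$splice$records, file.path(out_dir, "splice_sites.tsv"))

  hom_path <- optional("homologs")
  homologs <- if (!is.null(hom_path)) {
    stage("read_evidence", read_alignments(hom_path))
  } else NULL
  pep_path <- optional("peptides")
  pep_support <- NULL
  if (!is.null(pep_path)) {
    peptides <- readLines(pep_path)
    cds_all <- cds_sequences(res$new_genes, res$new_assembly)
    prots <- vapply(as.character(cds_all), function(s) {
      suppressWarnings(translate_cds(s))
    }, character(1))
    names(prots) <- names(cds_all)
    pep_support <- stage("evidence", peptide_support(peptides, prots)$supported)
  }
  cons <- optional("conservation")
  cons_tbl <- if (!is.null(cons)) read_tsv(cons) else NULL
  dom_path <- optional("domain_table")
  dom_tbl <- if (!is.null(dom_path)) read_tsv(dom_path) else NULL

  tx_support <- stage("evidence", {
    if (!is.null(res$transcripts)) {
      transcript_overlap(res$new_genes, res$transcripts, min_intron = min_intron)
    } else {
      gsum <- gene_summary(res$new_genes)
      m <- matrix(FALSE, nrow(gsum), 0, dimnames = list(gsum$gene_id, NULL))
      list(spliced = m, unspliced = m)
    }
  })
  hom_support <- if (!is.null(homologs)) {
    stage("evidence", homolog_overlap(res$new_genes, homologs))
  } else NULL
  res$evidence <- stage("evidence", build_evidence_matrix(
    res$new_genes, tx_support, pep_support, hom_support, cons_tbl, dom_tbl,
    tissues = tissues
  ))
  write_tsv(res$evidence, file.path(out_dir, "evidence_matrix.tsv"))

  res$report <- stage("report", build_report(
    res$classification$stringent, res$new_genes, res$cds$per_gene,
    res$splice$records, res$evidence, res$weighted_gc, res$enc
  ))
  write_tsv(res$report, file.path(out_dir, "report.tsv"))
  res$comparisons <- stage("stats", class_comparisons(
    res$classification$stringent, res$cds$per_gene, res$evidence,
    res$weighted_gc, res$enc
  ))
  write_tsv(res$comparisons, file.path(out_dir, "comparisons.tsv"))

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
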