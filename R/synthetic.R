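# Synthetic genomes with piecewise-homogeneous GC domains, AT-biased gene
# placement, a degraded "old" assembly and multi-library evidence, all with
# recorded ground truth so every pipeline stage has a known answer.

# Exact blocks shorter than this are invisible to the k-mer mapper and are
# therefore also excluded from the generator's mappable-retention bookkeeping
# (see map_cds); sharing the constant keeps truth and pipeline consistent.
MIN_MAP_BLOCK <- 25L

#' Specification for a simulated genome
#'
#' @param seed integer seed.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold (bp).
#' @param domain_length_mean mean compositional-domain length (bp).
#' @param gc_levels GC fractions of the domain classes (bimodal by default,
#'   emulating an AT-rich genome with distinct GC-poor and GC-average domains).
#' @param gene_density_per_mb genes per megabase.
#' @param low_gc_gene_bias probability that a gene is placed in a lowest-GC
#'   domain (genes preferentially occupy AT-rich domains).
#' @param exon_count_probs probabilities for 1..10 coding exons per gene.
#' @param cds_codons_min,cds_codons_mean minimum and mean CDS length in codons
#'   (the minimum honours a 75-nt CDS floor).
#' @param intron_length_min,intron_length_mean intron length model (bp).
#' @param noncanonical_intron_rate fraction of introns with a non-GT/AG donor.
#' @return a `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(seed = 1L,
                            n_scaffolds = 4L,
                            scaffold_length = 250000L,
                            domain_length_mean = 30000L,
                            gc_levels = c(0.20, 0.45),
                            gene_density_per_mb = 100,
                            low_gc_gene_bias = 0.7,
                            exon_count_probs = c(0.16, 0.15, 0.14, 0.12, 0.11,
                                                 0.10, 0.08, 0.06, 0.05, 0.03),
                            cds_codons_min = 25L,
                            cds_codons_mean = 400,
                            intron_length_min = 60L,
                            intron_length_mean = 300,
                            noncanonical_intron_rate = 0.02) {
  stopifnot_fraction(gc_levels, "gc_levels")
  stopifnot_fraction(low_gc_gene_bias, "low_gc_gene_bias")
  stopifnot_fraction(noncanonical_intron_rate, "noncanonical_intron_rate")
  stopifnot_positive(c(n_scaffolds, scaffold_length, domain_length_mean,
                       gene_density_per_mb, cds_codons_min, cds_codons_mean,
                       intron_length_min, intron_length_mean),
                     "lengths and densities")
  if (length(exon_count_probs) != 10 || any(exon_count_probs < 0)) {
    stop("exon_count_probs must be 10 non-negative weights")
  }
  structure(list(
    seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    domain_length_mean = as.integer(domain_length_mean),
    gc_levels = sort(gc_levels), gene_density_per_mb = gene_density_per_mb,
    low_gc_gene_bias = low_gc_gene_bias,
    exon_count_probs = exon_count_probs / sum(exon_count_probs),
    cds_codons_min = as.integer(cds_codons_min),
    cds_codons_mean = cds_codons_mean,
    intron_length_min = as.integer(intron_length_min),
    intron_length_mean = intron_length_mean,
    noncanonical_intron_rate = noncanonical_intron_rate
  ), class = "genome_sim_spec")
}

#' Specification for degrading a new assembly into an "old" assembly
#'
#' Deletions are biased toward low-GC domains (the documented failure mode of
#' early sequencing chemistry on AT-rich genomes), so genes residing there are
#' preferentially lost.  Retained genes enter the simulated old annotation
#' with a probability that increases with CDS length, emulating the tendency
#' of early gene predictors to miss short genes.
#'
#' @param seed integer seed.
#' @param deletion_rate_low_gc expected deleted fraction of lowest-GC domains.
#' @param deletion_rate_high_gc expected deleted fraction of the other domains
#'   (must not exceed `deletion_rate_low_gc`).
#' @param deletion_length_mean mean deletion length (bp).
#' @param scaffold_break_rate per-bp probability of an old-assembly scaffold
#'   break.
#' @param old_annotation_max ceiling on the probability a retained gene is in
#'   the old gene set.
#' @param old_annotation_midpoint,old_annotation_scale logistic midpoint and
#'   scale (in CDS bp) for the length-dependence of old-annotation emission.
#' @return a `degradation_spec` list.
#' @export
degradation_spec <- function(seed = 1L,
                             deletion_rate_low_gc = 0.30,
                             deletion_rate_high_gc = 0.05,
                             deletion_length_mean = 4000L,
                             scaffold_break_rate = 2e-6,
                             old_annotation_max = 0.92,
                             old_annotation_midpoint = 600,
                             old_annotation_scale = 250) {
  stopifnot_fraction(c(deletion_rate_low_gc, deletion_rate_high_gc,
                       scaffold_break_rate, old_annotation_max),
                     "rates")
  if (deletion_rate_low_gc < deletion_rate_high_gc) {
    stop("deletion_rate_low_gc must be >= deletion_rate_high_gc")
  }
  stopifnot_positive(c(deletion_length_mean, old_annotation_scale), "lengths")
  structure(list(
    seed = as.integer(seed),
    deletion_rate_low_gc = deletion_rate_low_gc,
    deletion_rate_high_gc = deletion_rate_high_gc,
    deletion_length_mean = as.integer(deletion_length_mean),
    scaffold_break_rate = scaffold_break_rate,
    old_annotation_max = old_annotation_max,
    old_annotation_midpoint = old_annotation_midpoint,
    old_annotation_scale = old_annotation_scale
  ), class = "degradation_spec")
}

#' Specification for simulated gene evidence
#'
#' @param seed integer seed.
#' @param tissue_names the four designated single-tissue libraries used for
#'   expression breadth.
#' @param expression_prob per-tissue probability a gene is expressed (scalar
#'   or one value per tissue).
#' @param spliced_fraction probability an expressed multi-exon gene yields a
#'   spliced (rather than unspliced) alignment.
#' @param antisense_noise_rate per-gene-per-library probability of a spurious
#'   opposite-strand spliced alignment.
#' @param homolog_coverage_prob probability a gene has a protein-homolog
#'   alignment (any source).
#' @param dmel_homolog_prob probability of a Dipteran-reference homolog
#'   alignment.
#' @param peptide_per_gene_rate probability a gene has peptide evidence.
#' @param conservation_prob named per-informant probabilities of cross-genome
#'   conservation support.
#' @param domain_prob probability a gene has a protein-domain table match.
#' @param extra_libraries additional mixed libraries (not used for breadth).
#' @param extra_library_expression_prob expression probability in those.
#' @return an `evidence_sim_spec` list.
#' @export
evidence_sim_spec <- function(seed = 1L,
                              tissue_names = c("brain", "antennae", "ovary", "testes"),
                              expression_prob = 0.55,
                              spliced_fraction = 0.85,
                              antisense_noise_rate = 0.02,
                              homolog_coverage_prob = 0.5,
                              dmel_homolog_prob = 0.12,
                              peptide_per_gene_rate = 0.35,
                              conservation_prob = c(aflo = 0.85, bter = 0.78),
                              domain_prob = 0.45,
                              extra_libraries = c("embryo", "larvae"),
                              extra_library_expression_prob = 0.4) {
  stopifnot_fraction(c(expression_prob, spliced_fraction, antisense_noise_rate,
                       homolog_coverage_prob, dmel_homolog_prob,
                       peptide_per_gene_rate, conservation_prob, domain_prob,
                       extra_library_expression_prob),
                     "probabilities")
  if (length(expression_prob) == 1) {
    expression_prob <- rep(expression_prob, length(tissue_names))
  }
  if (length(expression_prob) != length(tissue_names)) {
    stop("expression_prob must be scalar or one value per tissue")
  }
  structure(list(
    seed = as.integer(seed), tissue_names = tissue_names,
    expression_prob = stats::setNames(expression_prob, tissue_names),
    spliced_fraction = spliced_fraction,
    antisense_noise_rate = antisense_noise_rate,
    homolog_coverage_prob = homolog_coverage_prob,
    dmel_homolog_prob = dmel_homolog_prob,
    peptide_per_gene_rate = peptide_per_gene_rate,
    conservation_prob = conservation_prob,
    domain_prob = domain_prob,
    extra_libraries = extra_libraries,
    extra_library_expression_prob = extra_library_expression_prob
  ), class = "evidence_sim_spec")
}

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA")
)
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a genome of piecewise-homogeneous GC domains
#'
#' Each scaffold is a concatenation of domains; within a domain each base is
#' G or C with the domain's GC fraction, i.i.d.  The emitted domain truth
#' partitions every scaffold.
#'
#' @param spec a [genome_sim_spec()].
#' @return list with `assembly` (`DNAStringSet`) and `domains` (data frame:
#'   `scaffold`, `start`, `end`, `gc_level`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed(spec$seed, {
    seqs <- character(spec$n_scaffolds)
    names(seqs) <- sprintf("scf%02d", seq_len(spec$n_scaffolds))
    dom_rows <- list()
    for (s in seq_len(spec$n_scaffolds)) {
      L <- spec$scaffold_length
      lens <- integer(0)
      while (sum(lens) < L) {
        lens <- c(lens, max(1000L, round(stats::rexp(1, 1 / spec$domain_length_mean))))
      }
      lens[length(lens)] <- lens[length(lens)] - (sum(lens) - L)
      lens <- lens[lens > 0]
      # alternate-ish assignment so both classes are always represented
      gc <- sample(spec$gc_levels, length(lens), replace = TRUE)
      if (length(spec$gc_levels) > 1) {
        for (i in seq_along(gc)[-1]) {
          if (gc[i] == gc[i - 1] && stats::runif(1) < 0.6) {
            gc[i] <- sample(setdiff(spec$gc_levels, gc[i - 1]), 1)
          }
        }
      }
      ends <- cumsum(lens)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      base <- unlist(lapply(seq_along(lens), function(i) {
        is_gc <- stats::runif(lens[i]) < gc[i]
        ifelse(is_gc,
               ifelse(stats::runif(lens[i]) < 0.5, "G", "C"),
               ifelse(stats::runif(lens[i]) < 0.5, "A", "T"))
      }))
      seqs[s] <- paste(base, collapse = "")
      dom_rows[[s]] <- data.frame(
        scaffold = names(seqs)[s], start = starts, end = ends, gc_level = gc,
        stringsAsFactors = FALSE
      )
    }
    list(
      assembly = Biostrings::DNAStringSet(seqs),
      domains = do.call(rbind, dom_rows)
    )
  })
}

#' @keywords internal
build_gene_structure <- function(spec) {
  min_exon_codons <- 9L  # keeps every exon above the 25-bp mappable floor
  ncod <- spec$cds_codons_min +
    stats::rnbinom(1, size = 2, mu = spec$cds_codons_mean - spec$cds_codons_min)
  n_ex <- sample.int(10L, 1L, prob = spec$exon_count_probs)
  if (n_ex > 1L) n_ex <- min(n_ex, ncod %/% min_exon_codons)
  if (n_ex > 1) {
    rest <- ncod - min_exon_codons * n_ex
    cuts <- sort(sample.int(rest + 1L, n_ex - 1L, replace = TRUE) - 1L)
    exon_nt <- (min_exon_codons + diff(c(0L, cuts, rest))) * 3L
  } else {
    exon_nt <- ncod * 3L
  }
  intron_len <- if (n_ex > 1) {
    spec$intron_length_min +
      stats::rgeom(n_ex - 1L, 1 / (spec$intron_length_mean - spec$intron_length_min + 1))
  } else {
    integer(0)
  }
  list(ncod = ncod, exon_nt = exon_nt, intron_len = intron_len)
}

#' Place genes with real ORFs into a simulated genome
#'
#' Genes get 1-10 coding exons, an ATG start, a stop codon, no internal stops
#' and canonical GT/AG introns except a configurable minority.  The assembly
#' sequence under each gene is overwritten so the ORF is genuinely present.
#' Genes never overlap each other.  Placement is biased toward the lowest-GC
#' domain class with probability `low_gc_gene_bias` (the gene midpoint falls
#' inside a domain of that class).
#'
#' @param assembly `DNAStringSet` from [simulate_genome()].
#' @param domains domain truth from [simulate_genome()].
#' @param spec the same [genome_sim_spec()].
#' @return list with the modified `assembly` and `genes` (a [gene_set()]).
#' @export
place_genes <- function(assembly, domains, spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  seqs <- as_assembly_chars(assembly)
  lowest <- min(domains$gc_level)
  n_genes <- round(spec$gene_density_per_mb * sum(nchar(seqs)) / 1e6)
  occupied <- lapply(seqs, function(x) data.frame(start = integer(0), end = integer(0)))

  with_seed(spec$seed + 1L, {
    gene_rows <- list()
    for (g in seq_len(n_genes)) {
      st <- build_gene_structure(spec)
      span <- sum(st$exon_nt) + sum(st$intron_len)
      placed <- FALSE
      for (attempt in seq_len(400)) {
        use_low <- stats::runif(1) < spec$low_gc_gene_bias
        cand <- if (use_low) domains[domains$gc_level == lowest, ] else domains
        d <- cand[sample.int(nrow(cand), 1L, prob = cand$end - cand$start + 1), ]
        L <- nchar(seqs[[d$scaffold]])
        lo <- max(1L, ceiling(d$start - span / 2))
        hi <- min(L - span + 1L, floor(d$end - span / 2))
        if (hi < lo) next
        start <- sample(seq.int(lo, hi), 1L)
        end <- start + span - 1L
        occ <- occupied[[d$scaffold]]
        if (nrow(occ) > 0 && any(start <= occ$end + 10L & end >= occ$start - 10L)) next
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("gene%04d", g)
        codons <- c("ATG", sample(SENSE_CODONS, st$ncod - 2L, replace = TRUE),
                    sample(STOP_CODONS, 1L))
        cds <- paste(codons, collapse = "")
        exon_seq <- substring(cds, cumsum(c(1L, utils::head(st$exon_nt, -1))),
                              cumsum(st$exon_nt))
        intron_seq <- vapply(st$intron_len, function(il) {
          donor <- if (stats::runif(1) < spec$noncanonical_intron_rate) "GC" else "GT"
          mid <- il - 4L
          inner <- if (mid > 0) {
            paste(ifelse(stats::runif(mid) < d$gc_level,
                         ifelse(stats::runif(mid) < 0.5, "G", "C"),
                         ifelse(stats::runif(mid) < 0.5, "A", "T")),
                  collapse = "")
          } else ""
          paste0(donor, inner, "AG")
        }, character(1))
        parts <- character(0)
        for (i in seq_along(exon_seq)) {
          parts <- c(parts, exon_seq[i])
          if (i <= length(intron_seq)) parts <- c(parts, intron_seq[i])
        }
        gene_str <- paste(parts, collapse = "")
        stopifnot(nchar(gene_str) == span)
        written <- if (strand == "-") revcomp(gene_str) else gene_str
        substr(seqs[[d$scaffold]], start, end) <- written
        # exon offsets within the transcribed-orientation gene string
        off_start <- cumsum(c(1L, utils::head(st$exon_nt + c(st$intron_len, 0L), -1)))
        off_end <- off_start + st$exon_nt - 1L
        if (strand == "+") {
          ex_start <- start + off_start - 1L
          ex_end <- start + off_end - 1L
        } else {
          ex_start <- start + (span - off_end)
          ex_end <- start + (span - off_start)
        }
        gene_rows[[g]] <- data.frame(
          gene_id = gid, scaffold = d$scaffold, strand = strand,
          start = ex_start, end = ex_end, exon_rank = seq_along(ex_start),
          stringsAsFactors = FALSE
        )
        occupied[[d$scaffold]] <- rbind(occ, data.frame(start = start, end = end))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("place_genes: gene density too high to place gene ", g,
             " without overlap")
      }
    }
    list(
      assembly = Biostrings::DNAStringSet(seqs),
      genes = gene_set(do.call(rbind, gene_rows))
    )
  })
}

#' Degrade a new assembly into an old assembly with known gene fates
#'
#' Deletions are sampled per compositional domain at a rate depending on its
#' GC class; deleted flanks are rejoined within an old scaffold, and rare
#' scaffold breaks split old scaffolds.  The lift table maps surviving
#' new-assembly intervals to old-assembly coordinates.  The truth table
#' labels each gene Type I when its mappable retained CDS fraction (runs of
#' at least 25 bp on a single old scaffold) falls below 0.80 (stringent) or
#' 0.50 (relaxed); retained genes are Previously Known when emitted into the
#' simulated old gene set and Type II otherwise.
#'
#' @param assembly new assembly (`DNAStringSet`).
#' @param genes new [gene_set()].
#' @param domains domain truth from [simulate_genome()].
#' @param spec a [degradation_spec()].
#' @return list with `old_assembly`, `lift`, `truth`, `old_genes`.
#' @export
degrade_assembly <- function(assembly, genes, domains, spec) {
  stopifnot(inherits(spec, "degradation_spec"))
  seqs <- as_assembly_chars(assembly)
  lowest <- min(domains$gc_level)

  with_seed(spec$seed, {
    lift_rows <- list()
    old_seqs <- character(0)
    for (scf in names(seqs)) {
      L <- nchar(seqs[[scf]])
      dom <- domains[domains$scaffold == scf, , drop = FALSE]
      del <- IRanges::IRanges()
      for (i in seq_len(nrow(dom))) {
        rate <- if (dom$gc_level[i] == lowest) spec$deletion_rate_low_gc else spec$deletion_rate_high_gc
        dlen <- dom$end[i] - dom$start[i] + 1
        ndel <- stats::rpois(1, rate * dlen / spec$deletion_length_mean)
        if (ndel == 0) next
        lens <- pmax(50L, round(stats::rexp(ndel, 1 / spec$deletion_length_mean)))
        starts <- dom$start[i] + floor(stats::runif(ndel) * dlen)
        ends <- pmin(starts + lens - 1L, dom$end[i])
        del <- c(del, IRanges::IRanges(starts, ends))
      }
      del <- IRanges::reduce(del)
      kept <- IRanges::setdiff(IRanges::IRanges(1L, L), del)
      nbreak <- stats::rbinom(1, L, spec$scaffold_break_rate)
      breaks <- sort(unique(sample.int(L - 1L, nbreak)))
      chunk_bounds <- c(0L, breaks, L)
      for (ci in seq_len(length(chunk_bounds) - 1L)) {
        c_lo <- chunk_bounds[ci] + 1L
        c_hi <- chunk_bounds[ci + 1L]
        kc <- IRanges::intersect(kept, IRanges::IRanges(c_lo, c_hi))
        if (length(kc) == 0) next
        tot <- sum(IRanges::width(kc))
        if (tot < 200L) next
        old_name <- sprintf("old_%s_%d", scf, ci)
        old_pos <- cumsum(c(1L, utils::head(IRanges::width(kc), -1)))
        lift_rows[[length(lift_rows) + 1L]] <- data.frame(
          new_scaffold = scf,
          new_start = IRanges::start(kc), new_end = IRanges::end(kc),
          old_scaffold = old_name, old_start = old_pos,
          stringsAsFactors = FALSE
        )
        old_seqs[[old_name]] <- paste(
          substring(seqs[[scf]], IRanges::start(kc), IRanges::end(kc)),
          collapse = ""
        )
      }
    }
    lift <- do.call(rbind, lift_rows)

    # per-gene retention bookkeeping through the lift table
    gsum <- gene_summary(genes)
    truth_rows <- list()
    old_gene_rows <- list()
    for (i in seq_len(nrow(gsum))) {
      gid <- gsum$gene_id[i]
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      lf <- lift[lift$new_scaffold == gsum$scaffold[i], , drop = FALSE]
      pieces <- list()
      if (nrow(lf) > 0) {
        for (j in seq_len(nrow(ex))) {
          ov_lo <- pmax(ex$start[j], lf$new_start)
          ov_hi <- pmin(ex$end[j], lf$new_end)
          hit <- which(ov_lo <= ov_hi)
          for (h in hit) {
            pieces[[length(pieces) + 1L]] <- data.frame(
              old_scaffold = lf$old_scaffold[h],
              old_start = lf$old_start[h] + (ov_lo[h] - lf$new_start[h]),
              old_end = lf$old_start[h] + (ov_hi[h] - lf$new_start[h]),
              len = ov_hi[h] - ov_lo[h] + 1L,
              stringsAsFactors = FALSE
            )
          }
        }
      }
      cds_len <- gsum$cds_length[i]
      if (length(pieces)) {
        pc <- do.call(rbind, pieces)
        retained <- sum(pc$len) / cds_len
        map_by_scf <- tapply(pc$len[pc$len >= MIN_MAP_BLOCK],
                             pc$old_scaffold[pc$len >= MIN_MAP_BLOCK], sum)
        mappable <- if (length(map_by_scf)) max(map_by_scf) / cds_len else 0
      } else {
        pc <- NULL
        retained <- 0
        mappable <- 0
      }
      annotate <- FALSE
      if (mappable >= 0.5) {
        p <- spec$old_annotation_max *
          stats::plogis((cds_len - spec$old_annotation_midpoint) / spec$old_annotation_scale)
        annotate <- stats::runif(1) < p
      }
      cls <- function(thr) {
        if (mappable < thr) "TypeI" else if (annotate) "PreviouslyKnown" else "TypeII"
      }
      truth_rows[[i]] <- data.frame(
        gene_id = gid,
        class_stringent = cls(0.80), class_relaxed = cls(0.50),
        retained_fraction = retained, mappable_fraction = mappable,
        in_old_set = annotate, stringsAsFactors = FALSE
      )
      if (annotate && !is.null(pc)) {
        old_gene_rows[[length(old_gene_rows) + 1L]] <- data.frame(
          gene_id = paste0("old_", gid),
          scaffold = pc$old_scaffold, strand = gsum$strand[i],
          start = pc$old_start, end = pc$old_end,
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- do.call(rbind, truth_rows)
    old_genes <- NULL
    if (length(old_gene_rows)) {
      og <- do.call(rbind, old_gene_rows)
      lens <- tapply(og$end - og$start + 1, og$gene_id, sum)
      og$partial <- as.logical((lens %% 3L != 0L)[og$gene_id])
      # an old gene may be split across old scaffolds; keep one record per
      # (gene, scaffold) so the single-scaffold gene_set invariant holds
      og$gene_id <- paste0(og$gene_id, "@", og$scaffold)
      lens <- tapply(og$end - og$start + 1, og$gene_id, sum)
      og$partial <- og$partial | as.logical((lens %% 3L != 0L)[og$gene_id])
      old_genes <- gene_set(og)
    }
    list(
      old_assembly = Biostrings::DNAStringSet(old_seqs),
      lift = lift, truth = truth, old_genes = old_genes
    )
  })
}

#' Simulate transcript, peptide, homolog, conservation and domain evidence
#'
#' Expressed genes get spliced alignments whose intron coordinates match the
#' gene's introns exactly; unspliced alignments are single blocks inside an
#' exon; antisense noise is emitted on the opposite strand.  Peptides are
#' tryptic-like exact substrings (length >= 6) of the translated CDS.  The
#' breadth truth records, per gene, whether the emitted spliced sense
#' alignments cover none, exactly one, all four, or some other number of the
#' designated tissues.
#'
#' @param genes a [gene_set()].
#' @param assembly the (gene-bearing) new assembly.
#' @param spec an [evidence_sim_spec()].
#' @return list with `transcripts`, `homologs` ([aln_set()]s), `peptides`,
#'   `conservation`, `domains`, `breadth_truth` (data frames).
#' @export
simulate_evidence <- function(genes, assembly, spec) {
  stopifnot(inherits(spec, "evidence_sim_spec"))
  gsum <- gene_summary(genes)
  cds <- cds_sequences(genes, assembly)

  with_seed(spec$seed, {
    tr_rows <- list()
    breadth_count <- stats::setNames(integer(nrow(gsum)), gsum$gene_id)
    libs <- c(spec$tissue_names, spec$extra_libraries)
    lib_p <- c(spec$expression_prob,
               rep(spec$extra_library_expression_prob, length(spec$extra_libraries)))
    names(lib_p) <- libs
    aln_n <- 0L
    for (i in seq_len(nrow(gsum))) {
      gid <- gsum$gene_id[i]
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (lib in libs) {
        if (stats::runif(1) < lib_p[[lib]]) {
          aln_n <- aln_n + 1L
          spliced <- nrow(ex) >= 2 && stats::runif(1) < spec$spliced_fraction
          if (spliced) {
            tr_rows[[length(tr_rows) + 1L]] <- data.frame(
              aln_id = sprintf("tx%06d", aln_n),
              query_id = sprintf("tx_%s_%s", lib, gid),
              target = gsum$scaffold[i], strand = gsum$strand[i],
              start = ex$start, end = ex$end,
              library = lib, stringsAsFactors = FALSE
            )
            if (lib %in% spec$tissue_names) {
              breadth_count[gid] <- breadth_count[gid] + 1L
            }
          } else {
            j <- sample.int(nrow(ex), 1L)
            w <- ex$end[j] - ex$start[j] + 1L
            blen <- max(30L, min(w, round(stats::runif(1, 50, 400))))
            bstart <- ex$start[j] + sample.int(max(1L, w - blen + 1L), 1L) - 1L
            tr_rows[[length(tr_rows) + 1L]] <- data.frame(
              aln_id = sprintf("tx%06d", aln_n),
              query_id = sprintf("tx_%s_%s", lib, gid),
              target = gsum$scaffold[i],
              strand = sample(c("+", "-"), 1L),
              start = bstart, end = bstart + blen - 1L,
              library = lib, stringsAsFactors = FALSE
            )
          }
        }
        if (nrow(ex) >= 2 && stats::runif(1) < spec$antisense_noise_rate) {
          aln_n <- aln_n + 1L
          tr_rows[[length(tr_rows) + 1L]] <- data.frame(
            aln_id = sprintf("tx%06d", aln_n),
            query_id = sprintf("txas_%s_%s", lib, gid),
            target = gsum$scaffold[i],
            strand = if (gsum$strand[i] == "+") "-" else "+",
            start = ex$start, end = ex$end,
            library = lib, stringsAsFactors = FALSE
          )
        }
      }
    }
    transcripts <- if (length(tr_rows)) aln_set(do.call(rbind, tr_rows)) else NULL

    hom_rows <- list()
    hn <- 0L
    for (i in seq_len(nrow(gsum))) {
      gid <- gsum$gene_id[i]
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (src in c("metazoa", "dmel")) {
        p <- if (src == "dmel") spec$dmel_homolog_prob else spec$homolog_coverage_prob
        if (stats::runif(1) < p) {
          hn <- hn + 1L
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(
            aln_id = sprintf("hom%05d", hn),
            query_id = sprintf("prot_%s_%s", src, gid),
            target = gsum$scaffold[i], strand = gsum$strand[i],
            start = ex$start, end = ex$end,
            identity = round(stats::runif(1, 0.6, 0.98), 4),
            coverage = round(stats::runif(1, 0.6, 1.0), 4),
            source = src, stringsAsFactors = FALSE
          )
        }
      }
    }
    homologs <- if (length(hom_rows)) aln_set(do.call(rbind, hom_rows)) else NULL

    pep_rows <- list()
    for (i in seq_len(nrow(gsum))) {
      if (stats::runif(1) >= spec$peptide_per_gene_rate) next
      prot <- suppressWarnings(translate_cds(as.character(cds[[gsum$gene_id[i]]])))
      frags <- strsplit(gsub("([KR])", "\\1|", prot), "\\|")[[1]]
      frags <- frags[nchar(frags) >= 6]
      if (!length(frags)) next
      take <- sample(frags, min(length(frags), sample.int(3L, 1L)))
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        peptide = take, source_gene = gsum$gene_id[i], stringsAsFactors = FALSE
      )
    }
    peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else
      data.frame(peptide = character(0), source_gene = character(0))

    cons <- do.call(rbind, lapply(names(spec$conservation_prob), function(inf) {
      data.frame(
        gene_id = gsum$gene_id, informant = inf,
        supported = stats::runif(nrow(gsum)) < spec$conservation_prob[[inf]],
        stringsAsFactors = FALSE
      )
    }))

    dom_hit <- stats::runif(nrow(gsum)) < spec$domain_prob
    domains_tbl <- data.frame(
      gene_id = gsum$gene_id[dom_hit],
      domain_id = sprintf("DOM%04d", sample.int(200L, sum(dom_hit), replace = TRUE)),
      stringsAsFactors = FALSE
    )

    breadth <- ifelse(breadth_count == 0, "none",
                      ifelse(breadth_count == 1, "narrow",
                             ifelse(breadth_count == length(spec$tissue_names),
                                    "broad", "neither")))
    breadth_truth <- data.frame(gene_id = gsum$gene_id,
                                breadth = unname(breadth[gsum$gene_id]),
                                stringsAsFactors = FALSE)

    list(transcripts = transcripts, homologs = homologs, peptides = peptides,
         conservation = cons, domains = domains_tbl,
         breadth_truth = breadth_truth)
  })
}

#' Generate and write a complete synthetic fixture
#'
#' Runs [simulate_genome()], [place_genes()], [degrade_assembly()] and
#' [simulate_evidence()] and writes every artefact (FASTA, GFF3, TSV, JSON
#' metadata) into `dir`.  Identical specs produce byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param gspec,dspec,espec the three simulator specs.
#' @return (invisibly) the in-memory fixture bundle.
#' @export
simulate_fixture <- function(dir,
                             gspec = genome_sim_spec(),
                             dspec = degradation_spec(seed = gspec$seed + 2L),
                             espec = evidence_sim_spec(seed = gspec$seed + 3L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(gspec)
  pl <- place_genes(gen$assembly, gen$domains, gspec)
  deg <- degrade_assembly(pl$assembly, pl$genes, gen$domains, dspec)
  ev <- simulate_evidence(pl$genes, pl$assembly, espec)
  truth <- merge(deg$truth, ev$breadth_truth, by = "gene_id")

  write_assembly(pl$assembly, file.path(dir, "new_assembly.fa"))
  write_assembly(deg$old_assembly, file.path(dir, "old_assembly.fa"))
  write_gene_set(pl$genes, file.path(dir, "new_genes.gff3"))
  if (!is.null(deg$old_genes)) {
    write_gene_set(deg$old_genes, file.path(dir, "old_genes.gff3"))
  }
  if (!is.null(ev$transcripts)) {
    write_alignments(ev$transcripts, file.path(dir, "transcripts.gff3"), "gff3")
  }
  if (!is.null(ev$homologs)) {
    write_alignments(ev$homologs, file.path(dir, "homologs.gff3"), "gff3")
  }
  writeLines(ev$peptides$peptide, file.path(dir, "peptides.txt"))
  write_tsv(ev$conservation, file.path(dir, "conservation.tsv"))
  write_tsv(ev$domains, file.path(dir, "domain_matches.tsv"))
  write_tsv(gen$domains, file.path(dir, "domain_truth.tsv"))
  write_tsv(deg$lift, file.path(dir, "lift.tsv"))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(
    list(genome_sim_spec = unclass(gspec), degradation_spec = unclass(dspec),
         evidence_sim_spec = unclass(espec)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    assembly = pl$assembly, genes = pl$genes, domain_truth = gen$domains,
    old_assembly = deg$old_assembly, old_genes = deg$old_genes,
    lift = deg$lift, truth = truth, evidence = ev
  ))
}
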