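# End-to-end orchestration: filter -> association -> popgen -> CpG context
# -> annotation -> CNV -> DMR -> integration, with a summary report.

#' Pipeline configuration
#'
#' Collects input paths and per-stage parameters. All paths must exist at
#' validation time; stages can be toggled off.
#'
#' @param vcf,fasta,gff Paths to genotypes, genome and gene models.
#' @param groups Named character vector mapping samples to the two lines,
#'   or path to a two-column TSV (sample, group).
#' @param medip_reads Named character vector of per-sample read BED paths
#'   (may be `NULL` to skip the DMR stage).
#' @param input_a,input_b Pooled input read BEDs (`NULL` skips CNV).
#' @param qtl,repeats Optional interval BEDs.
#' @param outdir Output directory for stage TSVs (`NULL`: nothing written).
#' @param alpha Significance level used across stages (default 0.05).
#' @param n_perm Association permutations (default 1000; 0 disables).
#' @param min_maf,min_sample_callrate,min_locus_callrate Genotype filters.
#' @param tajima_window_bp Tajima's D window (default 10000).
#' @param promoter_flank,downstream_flank Annotation flanks (default 3000).
#' @param dmr_window_bp,min_row_sum DMR stage parameters (300, 10).
#' @param cnv_window_bp CNV window; `NULL` uses [recommend_window()].
#' @param seed Seed for the permutation stage.
#' @param run_cnv,run_dmr,run_integration Stage toggles.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, fasta, gff, groups,
                            medip_reads = NULL, input_a = NULL,
                            input_b = NULL, qtl = NULL, repeats = NULL,
                            outdir = NULL, alpha = 0.05, n_perm = 1000L,
                            min_maf = 0.02, min_sample_callrate = 0.20,
                            min_locus_callrate = 0.70,
                            tajima_window_bp = 10000L,
                            promoter_flank = 3000L, downstream_flank = 3000L,
                            dmr_window_bp = 300L, min_row_sum = 10L,
                            cnv_window_bp = NULL, seed = 1L,
                            run_cnv = TRUE, run_dmr = TRUE,
                            run_integration = TRUE) {
  cfg <- as.list(environment())
  paths <- c(vcf, fasta, gff, unlist(medip_reads), input_a, input_b,
             qtl, repeats,
             if (is.character(groups) && length(groups) == 1L) groups)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  stopifnot(alpha > 0, alpha <= 1)
  structure(cfg, class = "pipeline_config")
}

read_group_map <- function(groups) {
  if (!is.character(groups) || length(groups) > 1L || !file.exists(groups))
    return(groups)
  tab <- fread(groups, header = FALSE)
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Run the full pipeline
#'
#' Executes every enabled stage in order and aggregates a report with the
#' counts a study write-up needs: SNPs in/out of each filter, significant
#' SNPs, selection-class tallies, fixed-allele loci, the CpG enrichment
#' table, CNV and DMR counts with direction fractions, overlap and Venn
#' summaries and the repeat profile.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report` with one element per stage; TSV
#'   outputs are written under `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  emit <- function(x, name) {
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      fwrite(x, file.path(outdir, paste0(name, ".tsv")), sep = "\t")
    }
    x
  }
  genome <- read_fasta(config$fasta)
  genes <- read_gff_genes(config$gff)
  lens <- setNames(Biostrings::width(genome), names(genome))
  group_map <- read_group_map(config$groups)
  raw <- read_vcf(config$vcf, group_map)

  filt <- filter_genotypes(raw, config$min_maf, config$min_sample_callrate,
                           config$min_locus_callrate)
  report <- list(filter = attr(filt, "filter_report"))

  assoc <- allelic_association(filt)
  fdr <- bh_fdr(assoc$p, config$alpha)
  assoc$q <- fdr$q
  assoc$significant <- fdr$significant
  if (config$n_perm > 0L)
    assoc$p_perm <- permutation_pvalues(filt, config$n_perm, config$seed)
  pg <- popgen_stats(filt, lens, config$tajima_window_bp)
  assoc$fst <- pg$fst
  assoc$tajima_d_mean <- pg$tajima_d_mean
  assoc$class <- pg$class
  snp_gr <- GRanges(assoc$contig, IRanges(assoc$pos, width = 1L))
  ann <- annotate_features(snp_gr, genes, config$promoter_flank,
                           config$downstream_flank)
  assoc$feature <- ann$category
  cpg <- call_cpg_context(genome, assoc)
  assoc$cpg_context <- cpg$context
  emit(assoc, "snps")
  sig <- assoc[assoc$significant]
  report$association <- list(n_tested = nrow(assoc),
                             n_significant = nrow(sig),
                             global_fst = attr(pg, "global_fst"))
  report$selection_classes <- as.list(table(assoc$class))
  report$fixed_alleles <- emit(fixed_allele_differences(filt),
                               "fixed_alleles")
  report$enrichment <- emit(
    enrichment_table(sig$cpg_context == "CpG_loss", as.character(sig$feature)),
    "cpg_enrichment")

  cnv_calls <- NULL
  if (config$run_cnv && !is.null(config$input_a)) {
    ra <- read_bed(config$input_a, "generic", genome)
    rb <- read_bed(config$input_b, "generic", genome)
    w <- config$cnv_window_bp
    if (is.null(w))
      w <- recommend_window(genome_length(genome), length(ra), length(rb))
    cw <- window_log2_test(
      cnv_window_counts(ra, rb, tile_windows(genome, w)))
    cnv_calls <- call_cnvs(cw, config$alpha)
    emit(cnv_calls, "cnvs")
    report$cnv <- list(window_bp = w, n_windows = nrow(cw),
                       n_calls = nrow(cnv_calls),
                       gain_loss = if (nrow(cnv_calls))
                         as.list(gain_loss_summary(cnv_calls)) else NULL)
  }

  dmrs <- NULL
  if (config$run_dmr && length(config$medip_reads)) {
    reads <- lapply(config$medip_reads, read_bed, kind = "reads",
                    genome = genome)
    split_by_sample <- list()
    for (gr in reads) {
      for (s in unique(mcols(gr)$sample))
        split_by_sample[[s]] <- gr[mcols(gr)$sample == s]
    }
    dmr_res <- call_dmrs(split_by_sample, group_map, genome,
                         config$dmr_window_bp, config$min_row_sum,
                         config$alpha)
    dmrs <- dmr_res$dmrs
    emit(dmrs, "dmrs")
    report$dmr <- c(list(n_windows_tested = nrow(dmr_res$windows)),
                    dmr_res$direction)
  }

  if (config$run_integration) {
    sets <- list(SNP = GRanges(sig$contig, IRanges(sig$pos, width = 1L)))
    if (!is.null(cnv_calls) && nrow(cnv_calls))
      sets$CNV <- GRanges(cnv_calls$contig,
                          IRanges(cnv_calls$start, cnv_calls$end))
    if (!is.null(dmrs) && nrow(dmrs))
      sets$DMR <- GRanges(dmrs$contig, IRanges(dmrs$start, dmrs$end))
    if (!is.null(config$qtl))
      sets$QTL <- read_bed(config$qtl, "qtl", genome)
    if (length(sets) >= 2L) {
      pairs <- utils::combn(names(sets), 2L)
      ov <- lapply(seq_len(ncol(pairs)), function(k) {
        a <- pairs[1, k]; b <- pairs[2, k]
        res <- pairwise_overlap_test(sets[[a]], sets[[b]],
                                     genome_length = genome_length(genome))
        data.table(set_a = a, set_b = b, n_a = res$n_a, n_b = res$n_b,
                   n_overlap = res$n_overlap, universe_n = res$universe_n,
                   p = res$p_hypergeometric)
      })
      report$overlaps <- emit(data.table::rbindlist(ov), "overlaps")
      report$venn <- emit(multiway_venn(sets[seq_len(min(4L, length(sets)))]),
                          "venn")
    }
    if (!is.null(dmrs) && !is.null(cnv_calls)) {
      dmrs$in_cnv <- flag_dmr_in_cnv(dmrs, cnv_calls)
      report$dmr_in_cnv <- sum(dmrs$in_cnv)
    }
    if (!is.null(config$repeats)) {
      reps <- read_bed(config$repeats, "repeat", genome)
      bg <- list(genome = tile_windows(genome, 10000L))
      report$repeat_profile <- emit(
        repeat_profile(sets$SNP, reps, bg), "repeat_profile")
    }
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  filter: %d -> %d loci, %d/%d samples kept\n",
              x$filter$loci_in, x$filter$loci_out,
              x$filter$samples_in - x$filter$samples_dropped,
              x$filter$samples_in))
  cat(sprintf("  association: %d tested, %d significant; global Fst %.3f\n",
              x$association$n_tested, x$association$n_significant,
              x$association$global_fst))
  if (!is.null(x$cnv))
    cat(sprintf("  cnv: %d calls over %d windows of %d bp\n",
                x$cnv$n_calls, x$cnv$n_windows, x$cnv$window_bp))
  if (!is.null(x$dmr))
    cat(sprintf("  dmr: %d calls (%.1f%% hypo in B)\n",
                x$dmr$n, x$dmr$pct_hypo_in_b))
  invisible(x)
}
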