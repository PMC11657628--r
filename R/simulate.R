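# Synthetic two-line dataset generator: genome, genes, genotypes, MeDIP
# reads, pooled input depths, repeats, QTLs, plus a truth manifest. The
# stated world is desk-scale (about 1 Mb of genome) but keeps all absolute
# parameters of the real analysis (300 bp methylation windows, 3 kb
# promoter flanks) so printed pipeline parameters transfer unchanged.

#' Simulation configuration
#'
#' Defaults describe two populations of 10 and 7 diploid individuals that
#' diverged to a background Fst of 0.045, with small fractions of planted
#' fixed-differential and high-Fst loci, 30 planted DMRs over 300-bp windows
#' and 12 planted copy-ratio segments.
#'
#' @param seed Integer seed; fully determines every output.
#' @param n_contigs,contig_length Genome shape (default 5 x 200 kb).
#' @param gc_fraction Genome GC content (default 0.42).
#' @param n_genes Number of gene models (default 40).
#' @param promoter_flank Promoter half-width around the TSS in bp
#'   (default 3000); promoter CpG density is elevated >= 2x background.
#' @param n_samples_per_line Integer vector of two sample sizes
#'   (default `c(10, 7)`).
#' @param n_loci Number of biallelic loci (default 5000).
#' @param fraction_fixed,fraction_high_fst Fractions of loci planted as
#'   fixed-differential (default 0.002) and high-Fst (default 0.05).
#' @param fst_high,fst_background Balding-Nichols divergence parameters
#'   (defaults 0.30 and 0.045).
#' @param fraction_cpg_loss_loci,fraction_novel_cpg_loci Fractions of loci
#'   planted at reference CpG positions (CpG-loss candidates) and at
#'   positions where an alternate C creates a CpG (default 0.05 each).
#' @param missing_rate I.i.d. genotype missingness (default 0.05).
#' @param n_dmr,dmr_log2fc,window_bp Planted DMR count (30), total
#'   between-line log2 fold change (1.0) and methylation window width (300).
#' @param medip_mean_depth Mean MeDIP reads per window per sample (30).
#' @param medip_dispersion Negative-binomial dispersion (default 0.2).
#' @param n_cnv_segments,cnv_ratios Planted copy-ratio segments (12) and the
#'   ratio alphabet (0.5, 2, 3, 8).
#' @param cnv_segment_bp Length range of planted segments in bp.
#' @param input_total_reads Total pooled input reads across both lines
#'   (default 2e6).
#' @param repeat_classes Named genome fractions per repeat class.
#' @param n_qtl,qtl_length QTL count (5) and length range in bp.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 5L, contig_length = 200000L,
                       gc_fraction = 0.42,
                       n_genes = 40L, promoter_flank = 3000L,
                       n_samples_per_line = c(10L, 7L),
                       n_loci = 5000L,
                       fraction_fixed = 0.002, fraction_high_fst = 0.05,
                       fst_high = 0.30, fst_background = 0.045,
                       fraction_cpg_loss_loci = 0.05,
                       fraction_novel_cpg_loci = 0.05,
                       missing_rate = 0.05,
                       n_dmr = 30L, dmr_log2fc = 1.0, window_bp = 300L,
                       medip_mean_depth = 30, medip_dispersion = 0.2,
                       n_cnv_segments = 12L, cnv_ratios = c(0.5, 2, 3, 8),
                       cnv_segment_bp = c(2000L, 5000L),
                       input_total_reads = 2e6,
                       repeat_classes = c(Simple_repeat = 0.02, LINE = 0.05,
                                          LTR = 0.03, SINE = 0.01),
                       n_qtl = 5L, qtl_length = c(50000L, 100000L)) {
  cfg <- as.list(environment())
  fr <- c(gc_fraction, fraction_fixed, fraction_high_fst, missing_rate,
          fst_high, fst_background, fraction_cpg_loss_loci,
          fraction_novel_cpg_loci, repeat_classes)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (fraction_fixed + fraction_high_fst >= 1)
    stop("fraction_fixed + fraction_high_fst must be < 1")
  if (length(n_samples_per_line) != 2L || any(n_samples_per_line < 2L))
    stop("need two lines with >= 2 samples each")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# place n non-overlapping intervals of the given widths on the genome
place_disjoint <- function(lens, widths, occupied = NULL, max_try = 2000L) {
  taken <- lapply(lens, function(...) cbind(numeric(0), numeric(0)))
  if (!is.null(occupied) && length(occupied)) {
    for (ctg in unique(as.character(seqnames(occupied)))) {
      sub <- occupied[seqnames(occupied) == ctg]
      taken[[ctg]] <- cbind(start(sub), end(sub))
    }
  }
  res_ctg <- character(length(widths))
  res_st <- integer(length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]; ok <- FALSE
    for (i in seq_len(max_try)) {
      ctg <- sample(names(lens), 1L, prob = lens)
      if (lens[[ctg]] <= w) next
      st <- sample.int(lens[[ctg]] - w, 1L)
      tk <- taken[[ctg]]
      if (nrow(tk) && any(st <= tk[, 2] & st + w - 1L >= tk[, 1])) next
      taken[[ctg]] <- rbind(tk, c(st, st + w - 1L))
      res_ctg[k] <- ctg; res_st[k] <- st; ok <- TRUE
      break
    }
    if (!ok) stop("could not place a feature of width ", w,
                  "; genome too crowded")
  }
  gr <- GRanges(res_ctg, IRanges(res_st, res_st + widths - 1L))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  gr
}

#' Simulate a reference genome with genes, repeats and QTLs
#'
#' Promoter regions (within `promoter_flank` of every TSS) receive planted
#' CG dinucleotides so their CpG density is at least twice the genome
#' background, mimicking CpG-island-like promoters.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `genes` (list of
#'   `gene_model`), `repeats` and `qtls` (`GRanges`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  lens <- setNames(rep(config$contig_length, config$n_contigs),
                   paste0("chr", seq_len(config$n_contigs)))
  seqs <- vapply(lens, rand_seq, character(1), gc = config$gc_fraction)
  # genes: 3-6 exons of 100-400 bp separated by 200-2000 bp introns
  n_ex <- sample(3:6, config$n_genes, replace = TRUE)
  spans <- vapply(n_ex, function(k) {
    ex <- sample(100:400, k, replace = TRUE)
    sum(ex) + sum(sample(200:2000, k - 1L, replace = TRUE))
  }, numeric(1))
  if (config$n_genes * mean(spans) > sum(lens))
    stop("gene span budget exceeds genome length")
  gene_loc <- place_disjoint(lens, spans)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    k <- n_ex[i]
    ctg <- as.character(seqnames(gene_loc))[i]
    g_start <- start(gene_loc)[i]; g_end <- end(gene_loc)[i]
    ex_w <- sample(100:400, k, replace = TRUE)
    gaps <- sample(200:2000, k - 1L, replace = TRUE)
    scale <- (g_end - g_start + 1L - sum(ex_w)) / sum(gaps)
    gaps <- pmax(50L, as.integer(gaps * scale))
    st <- g_start + cumsum(c(0L, head(ex_w, -1L) + gaps))
    en <- pmin(st + ex_w - 1L, g_end)
    strand <- sample(c("+", "-"), 1L)
    exons <- GRanges(ctg, IRanges(st, en))
    first <- exons[1]; last <- exons[length(exons)]
    u5 <- resize(if (strand == "+") first else last, 50L,
                 fix = if (strand == "+") "start" else "end")
    u3 <- resize(if (strand == "+") last else first, 50L,
                 fix = if (strand == "+") "end" else "start")
    genes[[i]] <- gene_model(sprintf("gene%03d", i), ctg, strand, exons,
                             utr5 = u5, utr3 = u3)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  # plant CG dinucleotides inside promoter flanks (>= 2x background density)
  bg_cpg_rate <- (config$gc_fraction / 2)^2
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (m in genes) {
    lo <- max(1L, m$tss - config$promoter_flank)
    hi <- min(lens[[m$contig]] - 1L, m$tss + config$promoter_flank - 1L)
    span <- hi - lo + 1L
    n_plant <- rpois(1L, span * bg_cpg_rate * 4)
    if (n_plant == 0L) next
    at <- lo + sample.int(span - 1L, min(n_plant, span %/% 4L))
    ch <- chars[[m$contig]]
    gained <- sum(!ch[at] %in% c("C", "G")) + sum(!ch[at + 1L] %in% c("C", "G"))
    ch[at] <- "C"
    ch[at + 1L] <- "G"
    # compensate the GC gained by the planted CGs: demote other S bases in
    # the same promoter so the global base composition stays at gc_fraction
    cand <- setdiff(lo:hi, c(at, at + 1L))
    cand <- cand[ch[cand] %in% c("C", "G")]
    if (length(cand) && gained > 0) {
      demote <- sample(cand, min(gained, length(cand)))
      ch[demote] <- sample(c("A", "T"), length(demote), replace = TRUE)
    }
    chars[[m$contig]] <- ch
  }
  genome <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(lens)
  # repeats: class fractions realized as 200-2000 bp intervals
  rep_gr <- GRanges()
  for (cls in names(config$repeat_classes)) {
    target <- config$repeat_classes[[cls]] * sum(lens)
    widths <- integer(0)
    while (sum(widths) < target) widths <- c(widths, sample(200:2000, 1L))
    gr <- place_disjoint(lens, widths, occupied = rep_gr)
    mcols(gr)$class <- cls
    rep_gr <- c(rep_gr, gr)
  }
  qtl_w <- sample(config$qtl_length[1]:config$qtl_length[2], config$n_qtl,
                  replace = TRUE)
  qtls <- place_disjoint(lens, qtl_w)
  mcols(qtls)$name <- sprintf("QTL_FP%d", seq_len(config$n_qtl))
  list(genome = genome, genes = genes,
       repeats = GenomicRanges::sort(rep_gr, ignore.strand = TRUE),
       qtls = GenomicRanges::sort(qtls, ignore.strand = TRUE))
}

base_at <- function(genome, contig, pos) {
  as.character(subseq(genome[[contig]], pos, pos))
}

#' Simulate two-line genotypes under the Balding-Nichols model
#'
#' Neutral and high-Fst loci draw per-line allele frequencies from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral `p ~ U(0.05, 0.95)`,
#' with `F` set to the background or the elevated Fst. Fixed-differential
#' loci are hard-set to opposite homozygotes before missingness. Configured
#' fractions of loci sit at reference CpG positions (CpG-loss candidates)
#' or at positions where an alternate C creates a CpG (novel-CpG
#' candidates).
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet` from [simulate_genome()].
#' @return List with `table` (a `genotype_table`, groups `A` and `B`) and
#'   `truth` (`data.table`: contig, pos, ref, alt, class, planted context).
#' @export
simulate_genotypes <- function(config, genome) {
  set.seed(config$seed + 202L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  n <- config$n_loci
  n_fixed <- round(config$fraction_fixed * n)
  n_high <- round(config$fraction_high_fst * n)
  n_loss <- round(config$fraction_cpg_loss_loci * n)
  n_gain <- round(config$fraction_novel_cpg_loci * n)

  sites <- cpg_sites(genome)
  # CpG-loss candidates: the C (or, strand-complement, the G) of a CpG
  c_pos <- data.table(contig = as.character(seqnames(sites)),
                      pos = start(sites))
  g_pos <- data.table(contig = as.character(seqnames(sites)),
                      pos = start(sites) + 1L)
  loss_pool <- rbind(c_pos, g_pos)
  # novel-CpG candidates: ref != C immediately 5' of a reference G, and not
  # itself part of a CpG
  gain_pool <- data.table(contig = character(0), pos = integer(0))
  for (ctg in names(genome)) {
    s <- as.character(genome[[ctg]])
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    nxt <- c(ch[-1], "N"); prv <- c("N", ch[-length(ch)])
    # exclude the G of a reference CpG: an alternate C there would be a
    # CpG loss, not a gain, and truth labels must be mutually exclusive
    idx <- which(ch != "C" & ch != "N" & nxt == "G" &
                   !(ch == "G" & prv == "C"))
    if (length(idx))
      gain_pool <- rbind(gain_pool, data.table(contig = ctg, pos = idx))
  }
  pick <- function(pool, k, taken) {
    pool <- pool[!paste(pool$contig, pool$pos) %in% taken]
    pool[sample.int(nrow(pool), k)]
  }
  taken <- character(0)
  loss_loci <- pick(loss_pool, n_loss, taken)
  taken <- c(taken, paste(loss_loci$contig, loss_loci$pos))
  gain_loci <- pick(gain_pool, n_gain, taken)
  taken <- c(taken, paste(gain_loci$contig, gain_loci$pos))
  n_other <- n - n_loss - n_gain
  other <- data.table(
    contig = sample(names(lens), 3L * n_other, replace = TRUE, prob = lens))
  other$pos <- vapply(other$contig,
                      function(ctg) sample.int(lens[[ctg]] - 1L, 1L) + 1L,
                      integer(1))
  other <- unique(other)[!paste(contig, pos) %in% taken][seq_len(n_other)]
  loci <- rbind(cbind(loss_loci, context = "cpg_loss"),
                cbind(gain_loci, context = "novel_cpg"),
                cbind(other, context = "other"))
  setorder(loci, contig, pos)

  loci$ref <- mapply(base_at, loci$contig, loci$pos,
                     MoreArgs = list(genome = genome))
  alt_for <- function(ref, context) {
    if (context == "novel_cpg") return("C")
    if (context == "cpg_loss" && ref == "C")
      return(sample(c("T", "T", "T", "A", "G"), 1L))  # transitions dominate
    if (context == "cpg_loss" && ref == "G")
      return(sample(c("A", "A", "A", "T", "C"), 1L))
    sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  }
  loci$alt <- mapply(alt_for, loci$ref, loci$context)
  drop <- loci$ref == "N" | loci$ref == loci$alt
  loci <- loci[!drop]

  n_eff <- nrow(loci)
  cls <- rep("neutral", n_eff)
  cls[sample.int(n_eff, n_fixed + n_high)] <- c(rep("fixed", n_fixed),
                                                rep("high_fst", n_high))
  loci$class <- cls

  n_a <- config$n_samples_per_line[1]; n_b <- config$n_samples_per_line[2]
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  groups <- rep(c("A", "B"), c(n_a, n_b))
  geno <- matrix(NA_integer_, n_a + n_b, n_eff)
  p_anc <- runif(n_eff, 0.05, 0.95)
  Fval <- ifelse(cls == "high_fst", config$fst_high, config$fst_background)
  bn <- function(p, F) rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  p_a <- bn(p_anc, Fval); p_b <- bn(p_anc, Fval)
  for (j in seq_len(n_eff)) {
    if (cls[j] == "fixed") {
      alt_line <- sample(c("A", "B"), 1L)
      geno[, j] <- ifelse(groups == alt_line, 2L, 0L)
    } else {
      geno[seq_len(n_a), j] <- rbinom(n_a, 2L, p_a[j])
      geno[n_a + seq_len(n_b), j] <- rbinom(n_b, 2L, p_b[j])
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(geno)) < config$missing_rate, nrow(geno))
    geno[miss] <- NA_integer_
  }
  tab <- genotype_table(loci[, .(contig, pos, ref, alt)], geno,
                        samples, groups)
  list(table = tab,
       truth = loci[, .(contig, pos, ref, alt, class, context)])
}

#' Plant differentially methylated regions
#'
#' Picks `n_dmr` non-overlapping runs of 1-3 adjacent 300-bp windows with
#' non-zero CpG content and assigns each a direction (hypermethylated in
#' line A or line B) and the configured log2 fold change.
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet`.
#' @return `GRanges` with mcols `dmr_id`, `direction` (`hyper_in_A` /
#'   `hyper_in_B`) and `log2fc`.
#' @export
plant_dmrs <- function(config, genome) {
  set.seed(config$seed + 303L)
  win <- tile_windows(genome, config$window_bp)
  cf <- count_cpg(win, genome)
  eligible <- which(cf >= 5L & width(win) == config$window_bp)
  runs <- sample(1:3, config$n_dmr, replace = TRUE)
  chosen <- win[0]; used <- integer(0)
  for (i in seq_len(config$n_dmr)) {
    repeat {
      j <- sample(eligible, 1L)
      idx <- j:min(j + runs[i] - 1L, length(win))
      if (!any(idx %in% used) &&
          length(unique(as.character(seqnames(win[idx])))) == 1L) break
    }
    used <- c(used, idx, idx + 1L, idx - 1L)  # keep a 1-window buffer
    span <- reduce(win[idx])
    mcols(span)$dmr_id <- sprintf("dmr%02d", i)
    mcols(span)$direction <- sample(c("hyper_in_A", "hyper_in_B"), 1L)
    mcols(span)$log2fc <- config$dmr_log2fc
    chosen <- c(chosen, span)
  }
  GenomicRanges::sort(chosen, ignore.strand = TRUE)
}

#' Simulate per-sample MeDIP read intervals
#'
#' Expected window counts couple to CpG density through the saturating
#' `f(CF) = CF / (CF + 10)`, scaled so the realized mean equals
#' `medip_mean_depth`, multiplied by a per-sample size factor
#' `LogNormal(0, 0.1)` and, inside planted DMRs, by `2^(+/- log2fc / 2)`
#' for the hypermethylated and the other line respectively. Counts are
#' negative binomial with the configured dispersion and realized as 50-bp
#' reads placed uniformly inside the window.
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet`.
#' @param dmr_truth `GRanges` from [plant_dmrs()] (may be empty).
#' @return List with `reads` (named list of `GRanges`, one per sample),
#'   `samples`, `groups`.
#' @export
simulate_medip <- function(config, genome, dmr_truth) {
  set.seed(config$seed + 404L)
  win <- tile_windows(genome, config$window_bp)
  cf <- count_cpg(win, genome)
  f <- cf / (cf + 10)
  base_mu <- f / mean(f) * config$medip_mean_depth
  n_a <- config$n_samples_per_line[1]; n_b <- config$n_samples_per_line[2]
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  groups <- setNames(rep(c("A", "B"), c(n_a, n_b)), samples)
  size_factor <- setNames(rlnorm(length(samples), 0, 0.1), samples)
  shift <- matrix(0, nrow = length(win), ncol = length(samples),
                  dimnames = list(NULL, samples))
  if (length(dmr_truth)) {
    hit <- findOverlaps(win, dmr_truth)
    for (h in seq_along(hit)) {
      w_i <- queryHits(hit)[h]
      dir <- mcols(dmr_truth)$direction[subjectHits(hit)[h]]
      l2 <- mcols(dmr_truth)$log2fc[subjectHits(hit)[h]] / 2
      shift[w_i, groups == "A"] <- if (dir == "hyper_in_A") l2 else -l2
      shift[w_i, groups == "B"] <- if (dir == "hyper_in_B") l2 else -l2
    }
  }
  disp <- max(config$medip_dispersion, 1e-8)
  reads <- lapply(samples, function(s) {
    mu <- base_mu * size_factor[[s]] * 2^shift[, s]
    counts <- rnbinom(length(mu), mu = mu, size = 1 / disp)
    idx <- rep(seq_along(win), counts)
    if (!length(idx)) return(GRanges())
    offs <- floor(runif(length(idx)) * pmax(1, width(win)[idx] - 1L))
    st <- start(win)[idx] + offs
    ctg <- as.character(seqnames(win))[idx]
    lens <- seqlengths(genome_seqinfo(genome))[ctg]
    en <- pmin(st + 49L, lens)
    gr <- GRanges(ctg, IRanges(st, en),
                  strand = sample(c("+", "-"), length(idx), replace = TRUE))
    mcols(gr)$sample <- s
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
  names(reads) <- samples
  list(reads = reads, samples = samples, groups = groups)
}

#' Plant copy-ratio segments
#'
#' Non-overlapping segments with ratios drawn from the configured alphabet;
#' the ratio applies to line A relative to line B.
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet`.
#' @return `GRanges` with mcols `cnv_id` and `ratio`.
#' @export
plant_cnvs <- function(config, genome) {
  set.seed(config$seed + 505L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  widths <- sample(config$cnv_segment_bp[1]:config$cnv_segment_bp[2],
                   config$n_cnv_segments, replace = TRUE)
  gr <- place_disjoint(lens, widths)
  mcols(gr)$cnv_id <- sprintf("cnv%02d", seq_along(gr))
  mcols(gr)$ratio <- sample(config$cnv_ratios, length(gr), replace = TRUE)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate pooled input read intervals for the two lines
#'
#' Per-window counts are Poisson with mean proportional to library size x
#' window length, multiplied inside planted segments by the copy ratio (for
#' line A). Reads are 50 bp, placed uniformly.
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet`.
#' @param cnv_truth `GRanges` from [plant_cnvs()] (may be empty).
#' @param window_bp Internal simulation granularity (default 100 bp).
#' @return List of two `GRanges` named `A` and `B`.
#' @export
simulate_input_depth <- function(config, genome, cnv_truth,
                                 window_bp = 100L) {
  if (length(cnv_truth) &&
      any(countOverlaps(cnv_truth, cnv_truth) > 1L))
    stop("planted CNV segments overlap")
  set.seed(config$seed + 606L)
  win <- tile_windows(genome, window_bp)
  G <- genome_length(genome)
  n_per_line <- config$input_total_reads / 2
  ratio <- rep(1, length(win))
  if (length(cnv_truth)) {
    hit <- findOverlaps(win, cnv_truth)
    ratio[queryHits(hit)] <- mcols(cnv_truth)$ratio[subjectHits(hit)]
  }
  lens <- seqlengths(genome_seqinfo(genome))
  one_line <- function(r_mult) {
    mu <- n_per_line * width(win) / G * r_mult
    counts <- rpois(length(mu), mu)
    idx <- rep(seq_along(win), counts)
    offs <- floor(runif(length(idx)) * pmax(1, width(win)[idx] - 1L))
    st <- start(win)[idx] + offs
    ctg <- as.character(seqnames(win))[idx]
    en <- pmin(st + 49L, lens[ctg])
    GenomicRanges::sort(GRanges(ctg, IRanges(st, en)), ignore.strand = TRUE)
  }
  list(A = one_line(ratio), B = one_line(rep(1, length(win))))
}

#' Generate and write the full synthetic dataset
#'
#' Writes `genome.fa`, `genes.gff3`, `genotypes.vcf`, `reads_<sample>.bed`,
#' `input_A.bed`, `input_B.bed`, `repeats.bed`, `qtl.bed` and `truth.json`
#' under `outdir`. Identical config and seed give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @return Invisibly, a list with all in-memory objects and the truth
#'   manifest.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  gen <- simulate_genome(config)
  gt <- simulate_genotypes(config, gen$genome)
  dmr_truth <- plant_dmrs(config, gen$genome)
  medip <- simulate_medip(config, gen$genome, dmr_truth)
  cnv_truth <- plant_cnvs(config, gen$genome)
  input <- simulate_input_depth(config, gen$genome, cnv_truth)
  truth <- list(
    loci = as.data.frame(gt$truth),
    dmrs = data.frame(contig = as.character(seqnames(dmr_truth)),
                      start = start(dmr_truth), end = end(dmr_truth),
                      dmr_id = mcols(dmr_truth)$dmr_id,
                      direction = mcols(dmr_truth)$direction,
                      log2fc = mcols(dmr_truth)$log2fc),
    cnvs = data.frame(contig = as.character(seqnames(cnv_truth)),
                      start = start(cnv_truth), end = end(cnv_truth),
                      cnv_id = mcols(cnv_truth)$cnv_id,
                      ratio = mcols(cnv_truth)$ratio))
  out <- list(config = config, genome = gen$genome, genes = gen$genes,
              repeats = gen$repeats, qtls = gen$qtls,
              genotypes = gt$table, medip = medip, input = input,
              dmr_truth = dmr_truth, cnv_truth = cnv_truth, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_fasta(gen$genome, fp("genome.fa"))
    write_gff_genes(gen$genes, fp("genes.gff3"))
    write_vcf(gt$table, fp("genotypes.vcf"),
              contig_lengths = Biostrings::width(gen$genome) |>
                setNames(names(gen$genome)))
    for (s in medip$samples)
      write_bed(medip$reads[[s]], fp(sprintf("reads_%s.bed", s)))
    write_bed(input$A, fp("input_A.bed"))
    write_bed(input$B, fp("input_B.bed"))
    write_bed(gen$repeats, fp("repeats.bed"))
    write_bed(gen$qtls, fp("qtl.bed"))
    jsonlite::write_json(truth, fp("truth.json"), digits = NA,
                         dataframe = "columns")
  }
  invisible(out)
}
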