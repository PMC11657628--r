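# MeDIP-seq windowed differential methylation: stacked-read filter, 100-bp
# read extension, 300-bp window counts, CpG-coupling normalization, Welch
# test per window, 1-bp-gap merging, CpG enrichment scores.

#' Remove PCR stacks of identical reads
#'
#' The genome-wide Poisson model of read starts: `lambda` = total reads /
#' total genome positions; the cap is the largest stack size `k` with
#' `P(X >= k) >= p` under `Poisson(lambda)` (equivalently
#' `qpois(1 - p, lambda)`), with a floor of 1. Start positions (per contig,
#' start, strand) carrying more than the cap identical reads are truncated
#' to the cap.
#'
#' @param reads `GRanges` of one sample's reads (strand used).
#' @param genome_length Total genome length in bp.
#' @param p Poisson tail threshold (default 0.001).
#' @return List with `reads` (filtered `GRanges`), `cap`, `lambda`,
#'   `n_removed`.
#' @export
stacked_read_filter <- function(reads, genome_length, p = 0.001) {
  lambda <- length(reads) / genome_length
  cap <- max(1L, qpois(1 - p, lambda))
  if (!length(reads))
    return(list(reads = reads, cap = cap, lambda = lambda, n_removed = 0L))
  dt <- data.table(i = seq_along(reads),
                   pos_key = paste(seqnames(reads), start(reads),
                                   strand(reads)))
  dt[, rank := seq_len(.N), by = pos_key]
  idx <- dt$i[dt$rank <= cap]
  list(reads = GenomicRanges::sort(reads[sort(idx)], ignore.strand = TRUE),
       cap = cap, lambda = lambda,
       n_removed = length(reads) - length(idx))
}

#' Extend short reads 3'-ward to a target length
#'
#' Reads shorter than `target` are extended along their strand (plus-strand
#' reads grow to the right, minus-strand to the left), clipped at contig
#' ends; longer reads are untouched.
#'
#' @param reads `GRanges` with strand.
#' @param target Target length in bp (default 100).
#' @param contig_lengths Named contig lengths for clipping.
#' @return `GRanges`.
#' @export
extend_reads <- function(reads, target = 100L, contig_lengths) {
  if (!length(reads)) return(reads)
  short <- width(reads) < target
  plus <- as.character(strand(reads)) != "-"
  st <- start(reads); en <- end(reads)
  en[short & plus] <- st[short & plus] + target - 1L
  st[short & !plus] <- en[short & !plus] - target + 1L
  lens <- contig_lengths[as.character(seqnames(reads))]
  st <- pmax(1L, st)
  en <- pmin(en, lens)
  GRanges(seqnames(reads), IRanges(st, en), strand = strand(reads))
}

#' Window count matrix with CpG coupling factors
#'
#' A read increments every window its interval overlaps. The coupling
#' factor CF of a window is its count of CG dinucleotides fully inside.
#'
#' @param reads Named list of per-sample `GRanges` (already extended).
#' @param genome `DNAStringSet`.
#' @param window_bp Window width (default 300).
#' @return List of class `methyl_window_matrix`: `windows` (`GRanges`),
#'   `counts` (windows x samples), `cf` (CpG counts), `samples`.
#' @export
window_counts <- function(reads, genome, window_bp = 300L) {
  win <- tile_windows(genome, window_bp)
  counts <- vapply(reads, function(gr)
    countOverlaps(win, gr, ignore.strand = TRUE),
    integer(length(win)))
  structure(list(windows = win, counts = counts,
                 cf = count_cpg(win, genome), samples = names(reads)),
            class = "methyl_window_matrix")
}

#' CpG-coupling normalization to relative methylation scores
#'
#' Per sample, counts are scaled to counts-per-million; the expected CPM at
#' each CF level is the mean CPM over all windows (all samples pooled)
#' sharing that integer CF, smoothed to be non-decreasing in CF by isotonic
#' regression (the coupling between coverage and CpG density is assumed
#' monotone); CF levels with no windows are interpolated from neighbours.
#' The relative methylation score is CPM / expected(CF).
#'
#' @param matrix A `methyl_window_matrix`.
#' @return The matrix with an `rms` element (windows x samples) added.
#' @export
coupling_normalize <- function(matrix) {
  counts <- matrix$counts
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, pmax(lib, 1), "/") * 1e6
  cf <- matrix$cf
  lev <- sort(unique(cf))
  mean_by_cf <- vapply(lev, function(l) mean(cpm[cf == l, ]), numeric(1))
  iso <- isoreg(lev, mean_by_cf)
  fit <- setNames(iso$yf, lev)
  expected <- fit[as.character(cf)]
  # guard: strictly positive expectation
  floor_val <- max(min(fit[fit > 0], na.rm = TRUE) * 1e-3, 1e-8)
  expected <- pmax(expected, floor_val)
  matrix$rms <- cpm / expected
  matrix$expected_cpm <- unname(expected)
  matrix
}

#' Per-window differential methylation between the two groups
#'
#' Windows whose total raw count across all samples is below `min_row_sum`
#' are dropped. On the remainder a Welch two-sample t-test on
#' `log2(rms + 0.1)` compares the groups; `log2fc` is group B minus group A
#' of the mean transformed score. Zero variance in both groups gives p = 1
#' for equal means and a p at the numeric floor otherwise.
#'
#' @param matrix A normalized `methyl_window_matrix` (see
#'   [coupling_normalize()]).
#' @param groups Named group labels (two levels), one per sample.
#' @param min_row_sum Minimum total raw count per window (default 10).
#' @param alpha Per-window significance level (default 0.05).
#' @return `data.table`: contig, start, end, cf, mean_a, mean_b, log2fc,
#'   p, significant.
#' @export
differential_windows <- function(matrix, groups, min_row_sum = 10L,
                                 alpha = 0.05) {
  stopifnot(!is.null(matrix$rms))
  groups <- groups[matrix$samples]
  glev <- sort(unique(as.character(groups)))
  stopifnot(length(glev) == 2L)
  ia <- which(groups == glev[1]); ib <- which(groups == glev[2])
  stopifnot(length(ia) >= 2L, length(ib) >= 2L)
  keep <- rowSums(matrix$counts) >= min_row_sum
  x <- log2(matrix$rms[keep, ia, drop = FALSE] + 0.1)
  y <- log2(matrix$rms[keep, ib, drop = FALSE] + 0.1)
  na <- length(ia); nb <- length(ib)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (na - 1)
  vy <- rowSums((y - my)^2) / (nb - 1)
  se2 <- vx / na + vy / nb
  t_stat <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / na)^2 / (na - 1) + (vy / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  both_const <- se2 == 0
  p[both_const & abs(my - mx) < 1e-12] <- 1
  p[both_const & abs(my - mx) >= 1e-12] <- .Machine$double.xmin
  win <- matrix$windows[keep]
  data.table(contig = as.character(seqnames(win)),
             start = start(win), end = end(win),
             cf = matrix$cf[keep], mean_a = mx, mean_b = my,
             log2fc = my - mx, p = p, significant = p <= alpha)
}

#' Merge significant windows into DMRs
#'
#' Same-direction significant windows whose gap is at most `max_gap` bp are
#' merged; the CpG count is recomputed on the merged span. Direction is
#' relative to group B (`hyper_in_B` when `log2fc > 0`).
#'
#' @param diff Output of [differential_windows()].
#' @param genome `DNAStringSet` (for the merged-span CpG count).
#' @param max_gap Maximum merge gap in bp (default 1).
#' @return `data.table`: contig, start, end, n_windows, log2fc (mean over
#'   member windows), p (minimum over members), direction, n_cpgs.
#' @export
merge_dmrs <- function(diff, genome, max_gap = 1L) {
  sig <- diff[diff$significant & diff$log2fc != 0, ]
  empty <- data.table(contig = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      log2fc = numeric(0), p = numeric(0),
                      direction = character(0), n_cpgs = integer(0))
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (up in c(TRUE, FALSE)) {
    sub <- sig[if (up) log2fc > 0 else log2fc < 0]
    if (nrow(sub) == 0L) next
    gr <- GRanges(sub$contig, IRanges(sub$start, sub$end))
    merged <- reduce(gr, min.gapwidth = max_gap + 1L)
    hit <- findOverlaps(gr, merged)
    cpgs <- count_cpg(merged, genome)
    for (m in seq_along(merged)) {
      members <- sub[queryHits(hit)[subjectHits(hit) == m]]
      out[[length(out) + 1L]] <- data.table(
        contig = as.character(seqnames(merged))[m],
        start = start(merged)[m], end = end(merged)[m],
        n_windows = nrow(members), log2fc = mean(members$log2fc),
        p = min(members$p),
        direction = if (up) "hyper_in_B" else "hypo_in_B",
        n_cpgs = cpgs[m])
    }
  }
  res <- data.table::rbindlist(out)
  setorder(res, contig, start)
  res
}

#' Direction bookkeeping for a DMR set
#' @param dmrs Output of [merge_dmrs()].
#' @return List with counts and percentages of hypo/hyper (in group B)
#'   DMRs.
#' @export
dmr_direction_summary <- function(dmrs) {
  n <- nrow(dmrs)
  n_hypo <- sum(dmrs$direction == "hypo_in_B")
  list(n = n, n_hypo_in_b = n_hypo, n_hyper_in_b = n - n_hypo,
       pct_hypo_in_b = if (n) 100 * n_hypo / n else NA_real_,
       pct_hyper_in_b = if (n) 100 * (n - n_hypo) / n else NA_real_)
}

#' CpG enrichment score of a region set
#'
#' Density ratio variants comparing the regions with the genome: the
#' relH-like score is (CpG per bp in regions) / (CpG per bp genome-wide);
#' the observed/expected (GoGe-like) score compares `CpG * L / (C * G)`
#' within regions against the same quantity genome-wide.
#'
#' @param regions `GRanges` (non-empty, positive widths).
#' @param genome `DNAStringSet`.
#' @return List with `relH` and `GoGe` scores.
#' @export
cpg_enrichment_score <- function(regions, genome) {
  if (!length(regions) || any(width(regions) <= 0))
    stop("regions must be non-empty with positive widths")
  regions <- reduce(regions, ignore.strand = TRUE)
  seqs <- DNAStringSet(lapply(seq_along(regions), function(i)
    subseq(genome[[as.character(seqnames(regions))[i]]],
           start(regions)[i], end(regions)[i])))
  count_in <- function(ss) {
    di <- sum(Biostrings::vcountPattern("CG", ss))
    bases <- colSums(letterFrequency(ss, c("C", "G")))
    c(cpg = di, c = bases[["C"]], g = bases[["G"]],
      len = sum(Biostrings::width(ss)))
  }
  reg <- count_in(seqs); gen <- count_in(genome)
  relh <- (reg[["cpg"]] / reg[["len"]]) / (gen[["cpg"]] / gen[["len"]])
  goge_reg <- reg[["cpg"]] * reg[["len"]] / (reg[["c"]] * reg[["g"]])
  goge_gen <- gen[["cpg"]] * gen[["len"]] / (gen[["c"]] * gen[["g"]])
  list(relH = unname(relh), GoGe = unname(goge_reg / goge_gen))
}

#' End-to-end DMR calling from per-sample reads
#'
#' Applies the stacked-read filter, 100-bp extension, window counting,
#' coupling normalization, per-window testing and merging in sequence.
#'
#' @param reads Named list of per-sample `GRanges`.
#' @param groups Named group labels per sample.
#' @param genome `DNAStringSet`.
#' @param window_bp Window width (default 300).
#' @param min_row_sum Minimum window count sum (default 10).
#' @param alpha Window significance level (default 0.05).
#' @param stack_p Stacked-read Poisson threshold (default 0.001).
#' @param extend_to Read extension target (default 100).
#' @param max_gap DMR merge gap (default 1).
#' @return List with `windows` (the tested `data.table`), `dmrs`,
#'   `direction` summary and the window `matrix`.
#' @export
call_dmrs <- function(reads, groups, genome, window_bp = 300L,
                      min_row_sum = 10L, alpha = 0.05, stack_p = 0.001,
                      extend_to = 100L, max_gap = 1L) {
  G <- genome_length(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  prepped <- lapply(reads, function(gr) {
    extend_reads(stacked_read_filter(gr, G, stack_p)$reads,
                 extend_to, lens)
  })
  mat <- coupling_normalize(window_counts(prepped, genome, window_bp))
  diff <- differential_windows(mat, groups, min_row_sum, alpha)
  dmrs <- merge_dmrs(diff, genome, max_gap)
  list(windows = diff, dmrs = dmrs,
       direction = dmr_direction_summary(dmrs), matrix = mat)
}
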