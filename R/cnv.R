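# Window-based copy-number detection from two pooled libraries: the
# best-window recommendation, the Gaussian (Geary-Hinkley) approximation of
# the Poisson count ratio, Bonferroni thresholding and merging into calls.

#' Recommended detection window size for two pooled libraries
#'
#' The smallest window at which a true log2 ratio of `+/- log2_threshold`
#' attains the p-value threshold under the Gaussian approximation of the
#' Poisson count-ratio test, computed for both directions and both library
#' orientations, taken at the maximum and multiplied by the enlargement
#' factor. With the customary defaults (log2 threshold 0.6, p 0.001,
#' enlargement 1.5), a 1.05-Gb genome with 64.9 and 60.9 million reads
#' yields about 3,410 bp.
#'
#' @param genome_length Genome size G in bp.
#' @param n_reads_a,n_reads_b Library sizes (read counts).
#' @param log2_threshold Minimum detectable |log2 ratio| (default 0.6).
#' @param p_threshold Per-window p-value threshold (default 0.001).
#' @param bigger Window enlargement factor (default 1.5).
#' @return Recommended window size in bp (rounded to integer).
#' @export
recommend_window <- function(genome_length, n_reads_a, n_reads_b,
                             log2_threshold = 0.6, p_threshold = 0.001,
                             bigger = 1.5) {
  stopifnot(genome_length > 0, n_reads_a > 0, n_reads_b > 0,
            log2_threshold > 0, p_threshold > 0, p_threshold < 1)
  z <- qnorm(1 - p_threshold / 2)
  w_min <- function(N1, N2, r)
    genome_length * z^2 * (r^2 * N1 / N2 + 1) / (N1 * (r - 1)^2)
  r_up <- 2^log2_threshold; r_dn <- 2^-log2_threshold
  w <- max(w_min(n_reads_a, n_reads_b, r_up),
           w_min(n_reads_a, n_reads_b, r_dn),
           w_min(n_reads_b, n_reads_a, r_up),
           w_min(n_reads_b, n_reads_a, r_dn))
  round(bigger * w)
}

#' Count pooled reads in genome windows
#' @param reads_a,reads_b `GRanges` of pooled reads per line.
#' @param windows `GRanges` tiling of the genome.
#' @return `data.table`: contig, start, end, count_a, count_b.
#' @export
cnv_window_counts <- function(reads_a, reads_b, windows) {
  data.table(contig = as.character(seqnames(windows)),
             start = start(windows), end = end(windows),
             count_a = countOverlaps(windows, reads_a, ignore.strand = TRUE),
             count_b = countOverlaps(windows, reads_b, ignore.strand = TRUE))
}

#' Per-window log2 ratio and Gaussian-approximation p-value
#'
#' The library-size-normalized ratio `r = (a/N_a)/(b/N_b)` with a
#' two-sided p-value from the Geary-Hinkley transformation
#' `t = (lambda_b z - lambda_a)/sqrt(lambda_b z^2 + lambda_a)` of the raw
#' count ratio `z = a/b`, where `lambda` are the expected per-window counts
#' under no copy difference; `t` is standard normal under the null. Windows
#' with a zero count have that count floored at 0.5 for the ratio and are
#' flagged.
#'
#' @param counts `data.table` from [cnv_window_counts()].
#' @param n_reads_a,n_reads_b Library sizes; default to the column sums.
#' @return The input with columns `log2_ratio`, `p`, `zero_flag` added.
#' @export
window_log2_test <- function(counts, n_reads_a = NULL, n_reads_b = NULL) {
  counts <- data.table::copy(counts)
  if (is.null(n_reads_a)) n_reads_a <- sum(counts$count_a)
  if (is.null(n_reads_b)) n_reads_b <- sum(counts$count_b)
  a <- counts$count_a; b <- counts$count_b
  zero <- a == 0 | b == 0
  af <- pmax(a, 0.5); bf <- pmax(b, 0.5)
  w_frac <- (counts$end - counts$start + 1)
  # expected counts under H0, apportioned by window length
  lam_a <- n_reads_a * w_frac / sum(as.numeric(w_frac))
  lam_b <- n_reads_b * w_frac / sum(as.numeric(w_frac))
  z <- af / bf
  t_stat <- (lam_b * z - lam_a) / sqrt(lam_b * z^2 + lam_a)
  counts[, `:=`(log2_ratio = log2((af / n_reads_a) / (bf / n_reads_b)),
                p = pmin(1, 2 * pnorm(-abs(t_stat))),
                zero_flag = zero)]
  counts[]
}

#' Merge significant windows into CNV calls
#'
#' Windows below the Bonferroni threshold `alpha / n_windows` are kept,
#' split by ratio direction, and adjacent same-direction windows merged.
#' `is_top` marks calls whose fold change reaches `top_fold` in either
#' direction. The call-level fold is the median window log2 ratio over
#' non-zero-flagged members (robust to the partial windows at segment
#' boundaries, which dilute the mean systematically), measured relative
#' to the genome-wide median log2 ratio: copy-number differences
#' contribute reads to one library only, so library-size normalization
#' shifts every window ratio by the genome-wide copy imbalance, and
#' median-centering restores the neutral baseline to 0.
#'
#' @param windows Output of [window_log2_test()].
#' @param alpha Family-wise error target (default 0.05).
#' @param top_fold Fold-change threshold for top calls (default 8).
#' @return `data.table`: contig, start, end, n_windows, mean_log2_ratio,
#'   direction (`gain_in_A`/`gain_in_B`), is_top, p_threshold attribute.
#' @export
call_cnvs <- function(windows, alpha = 0.05, top_fold = 8) {
  thr <- alpha / nrow(windows)
  baseline <- median(windows$log2_ratio)
  sig <- windows[windows$p < thr & windows$log2_ratio != 0, ]
  empty <- data.table(contig = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      mean_log2_ratio = numeric(0),
                      median_log2_ratio = numeric(0),
                      direction = character(0), is_top = logical(0))
  if (nrow(sig) == 0L) { attr(empty, "p_threshold") <- thr; return(empty) }
  out <- list()
  for (dir_up in c(TRUE, FALSE)) {
    sub <- sig[if (dir_up) log2_ratio > 0 else log2_ratio < 0]
    if (nrow(sub) == 0L) next
    gr <- GRanges(sub$contig, IRanges(sub$start, sub$end))
    merged <- reduce(gr, min.gapwidth = 1L)
    hit <- findOverlaps(gr, merged)
    for (m in seq_along(merged)) {
      members <- sub[queryHits(hit)[subjectHits(hit) == m]]
      usable <- members[!members$zero_flag]
      mlr <- mean(members$log2_ratio)
      out[[length(out) + 1L]] <- data.table(
        contig = as.character(seqnames(merged))[m],
        start = start(merged)[m], end = end(merged)[m],
        n_windows = nrow(members), mean_log2_ratio = mlr,
        median_log2_ratio = median(members$log2_ratio),
        direction = if (mlr > 0) "gain_in_A" else "gain_in_B",
        is_top = nrow(usable) > 0 &&
          abs(median(usable$log2_ratio) - baseline) >= log2(top_fold))
    }
  }
  res <- data.table::rbindlist(out)
  setorder(res, contig, start)
  attr(res, "p_threshold") <- thr
  res
}

#' Gain/loss fractions for line A
#' @param calls Output of [call_cnvs()] (non-empty).
#' @return Named vector `c(gain, loss)` of fractions summing to 1.
#' @export
gain_loss_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no CNV calls")
  gain <- mean(calls$direction == "gain_in_A")
  c(gain = gain, loss = 1 - gain)
}
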