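# Per-SNP Weir-Cockerham Fst, windowed Tajima's D and the ten-category
# selection-signature classification.

#' Weir-Cockerham (1984) Fst from genotype counts
#'
#' Two-population estimator built from the variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals). Per locus `fst = a / (a + b + c)`; the global estimate is
#' `sum(a) / sum(a + b + c)` over loci. A locus needs at least two
#' non-missing diploid calls per group, else its Fst is `NA`; a locus
#' monomorphic overall gets Fst 0 by convention. Negative estimates are
#' retained (clamping happens only in [classify_selection()]).
#'
#' @param table A `genotype_table`.
#' @return List with `fst` (per-locus vector), `global`, and the component
#'   sums `sum_a`, `sum_abc`.
#' @export
wc_fst <- function(table) {
  gi <- group_index(table)
  r <- 2
  stat <- function(idx) {
    g <- table$geno[idx, , drop = FALSE]
    n <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * n)
    h <- colSums(g == 1L, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  }
  s1 <- stat(gi[[1]]); s2 <- stat(gi[[2]])
  n1 <- s1$n; n2 <- s2$n
  valid <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- nbar / nc *
    (s2v - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  fst <- ifelse(tot == 0, 0, a / tot)  # monomorphic -> 0 by convention
  fst[!valid] <- NA_real_
  a[!valid] <- NA_real_; tot[!valid] <- NA_real_
  list(fst = fst,
       global = sum(a, na.rm = TRUE) / sum(tot, na.rm = TRUE),
       sum_a = sum(a, na.rm = TRUE), sum_abc = sum(tot, na.rm = TRUE))
}

tajima_constants <- function(n_chrom) {
  n <- n_chrom
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D over non-overlapping genome windows
#'
#' Genotypes are treated as `2n` chromosomes per window. Allele
#' frequencies are computed per locus from the available (non-missing)
#' calls, loci with fewer than two called samples are skipped, and the
#' sample-size constants use `n` = the median number of called samples
#' over the window's loci (a documented simplification of
#' likelihood-based estimation; exact when data are complete). Per
#' window, `S` counts polymorphic loci,
#' `pi = sum(2 p (1-p)) * 2n/(2n-1)` and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants. `D` is `NA` when `S = 0` or `n < 2`.
#'
#' @param table A `genotype_table` (both groups pooled).
#' @param contig_lengths Named vector of contig lengths.
#' @param window_bp Window width (default 10000).
#' @return `data.table`: contig, start, end (1-based closed), n_chrom, S,
#'   pi, D.
#' @export
tajima_d_windows <- function(table, contig_lengths, window_bp = 10000L) {
  win <- tile_windows(contig_lengths, window_bp)
  loci_gr <- GRanges(table$loci$contig, IRanges(table$loci$pos, width = 1L))
  hits <- findOverlaps(loci_gr, win)
  out <- data.table(contig = as.character(seqnames(win)),
                    start = start(win), end = end(win),
                    n_chrom = NA_integer_, S = NA_integer_,
                    pi = NA_real_, D = NA_real_)
  for (w in unique(subjectHits(hits))) {
    li <- queryHits(hits)[subjectHits(hits) == w]
    g <- table$geno[, li, drop = FALSE]
    n_called <- colSums(!is.na(g))
    use <- n_called >= 2L
    if (!any(use)) next
    n <- floor(median(n_called[use]))
    out$n_chrom[w] <- 2L * n
    if (n < 2L) next
    p <- colSums(g[, use, drop = FALSE], na.rm = TRUE) /
      (2 * n_called[use])
    poly <- p > 0 & p < 1
    S <- sum(poly)
    out$S[w] <- S
    if (S == 0L) next
    nch <- 2 * n
    pi <- sum(2 * p[poly] * (1 - p[poly])) * nch / (nch - 1)
    k <- tajima_constants(nch)
    out$pi[w] <- pi
    out$D[w] <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  out$S[is.na(out$S) & !is.na(out$n_chrom)] <- 0L
  out
}

#' Attach window-mean Tajima's D to SNPs
#'
#' Per SNP, the mean of `D` over all windows containing it (windows are
#' treated as 1-based closed intervals; a SNP lies in exactly one window of
#' a non-overlapping tiling). `NA` when no containing window has defined D.
#'
#' @param table A `genotype_table` (for the loci).
#' @param windows Output of [tajima_d_windows()].
#' @return Numeric vector of per-SNP mean D.
#' @export
attach_tajima <- function(table, windows) {
  win_gr <- GRanges(windows$contig, IRanges(windows$start, windows$end))
  loci_gr <- GRanges(table$loci$contig, IRanges(table$loci$pos, width = 1L))
  hits <- findOverlaps(loci_gr, win_gr)
  d <- rep(NA_real_, length(loci_gr))
  dt <- data.table(snp = queryHits(hits), D = windows$D[subjectHits(hits)])
  agg <- dt[!is.na(D), .(m = mean(D)), by = snp]
  d[agg$snp] <- agg$m
  d
}

#' Ten-category selection-signature classes
#' @export
selection_classes <- c("FixedAllele", "PositiveSelection",
                       "BalancingSelection", "HighFstNeutralTajima",
                       "NegativeSelection",
                       "PossiblePopulationStructureExpansion", "Neutral",
                       "NonSelected", "HighFstNoTajimaData",
                       "SharedNeutrality")

#' Classify SNPs by Fst and window-mean Tajima's D
#'
#' The rule list, evaluated in order with first match winning:
#' \enumerate{
#'   \item Fixed Allele: Fst = 1
#'   \item Positive Selection: Fst > 0.25 and D < 0
#'   \item Balancing Selection: Fst > 0.25 and D > 0
#'   \item High Fst - Neutral Tajima: Fst > 0.25 and D = 0
#'   \item Negative Selection: Fst < 0.05 and D < 0
#'   \item Possible Population Structure/Expansion: Fst < 0.05 and D > 0
#'   \item Neutral: 0.05 <= Fst <= 0.25
#'   \item Non-Selected: Fst < 0.05 with no Tajima's D data
#'   \item High Fst - No Tajima's Data: Fst >= 0.05 with no Tajima's D data
#'   \item Shared Neutrality: all remaining SNPs
#' }
#' Negative Fst estimates are clamped to 0 for classification only;
#' `|D| < d_tol` is treated as exactly 0.
#'
#' @param fst Per-locus Fst (may contain `NA`: those come back unclassified
#'   as `NA`).
#' @param tajima_d_mean Per-locus mean D (`NA` = no data).
#' @param d_tol Tolerance for "D = 0" (default 1e-9).
#' @return Factor with levels [selection_classes].
#' @export
classify_selection <- function(fst, tajima_d_mean, d_tol = 1e-9) {
  stopifnot(length(fst) == length(tajima_d_mean))
  f <- pmax(fst, 0)
  d <- tajima_d_mean
  d[!is.na(d) & abs(d) < d_tol] <- 0
  cls <- rep(NA_character_, length(f))
  has_d <- !is.na(d)
  rule <- function(cond) !is.na(f) & is.na(cls) & cond
  cls[rule(f == 1)] <- "FixedAllele"
  cls[rule(has_d & f > 0.25 & d < 0)] <- "PositiveSelection"
  cls[rule(has_d & f > 0.25 & d > 0)] <- "BalancingSelection"
  cls[rule(has_d & f > 0.25 & d == 0)] <- "HighFstNeutralTajima"
  cls[rule(has_d & f < 0.05 & d < 0)] <- "NegativeSelection"
  cls[rule(has_d & f < 0.05 & d > 0)] <- "PossiblePopulationStructureExpansion"
  cls[rule(f >= 0.05 & f <= 0.25)] <- "Neutral"
  cls[rule(!has_d & f < 0.05)] <- "NonSelected"
  cls[rule(!has_d & f >= 0.05)] <- "HighFstNoTajimaData"
  cls[rule(TRUE)] <- "SharedNeutrality"
  factor(cls, levels = selection_classes)
}

#' Per-SNP population-genetic statistics
#'
#' Convenience wrapper: Weir-Cockerham Fst, windowed Tajima's D, window
#' matching and classification in one call.
#'
#' @param table A `genotype_table`.
#' @param contig_lengths Named contig lengths.
#' @param window_bp Tajima window width (default 10000).
#' @return `data.table` with loci, `fst`, `tajima_d_mean`, `class`; global
#'   Fst as attribute `global_fst`.
#' @export
popgen_stats <- function(table, contig_lengths, window_bp = 10000L) {
  fst <- wc_fst(table)
  win <- tajima_d_windows(table, contig_lengths, window_bp)
  d <- attach_tajima(table, win)
  out <- data.table(table$loci, fst = fst$fst, tajima_d_mean = d,
                    class = classify_selection(fst$fst, d))
  attr(out, "global_fst") <- fst$global
  attr(out, "tajima_windows") <- win
  out
}
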