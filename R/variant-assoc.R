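# Genotype QC and allele-based association between the two lines.

#' Subset a genotype table
#' @param table A `genotype_table`.
#' @param samples Logical or integer index over samples.
#' @param loci Logical or integer index over loci.
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(table, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_along(table$samples)
  if (is.null(loci)) loci <- seq_len(nrow(table$loci))
  genotype_table(table$loci[loci], table$geno[samples, loci, drop = FALSE],
                 table$samples[samples], table$groups[samples])
}

#' Minor allele frequency per locus
#' @param table A `genotype_table`.
#' @return Numeric vector; `NA` where no calls.
#' @export
locus_maf <- function(table) {
  p <- colMeans(table$geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Quality-filter genotypes
#'
#' Samples below the sample call-rate are dropped first; then loci below the
#' locus call-rate or below the minor-allele-frequency threshold are
#' dropped. All thresholds are inclusive ("at least").
#'
#' @param table A `genotype_table`.
#' @param min_maf Minimum minor allele frequency (default 0.02).
#' @param min_sample_callrate Minimum per-sample call rate (default 0.20).
#' @param min_locus_callrate Minimum per-locus call rate (default 0.70).
#' @return The filtered `genotype_table` with a `filter_report` attribute
#'   (list of counts dropped at each step).
#' @export
filter_genotypes <- function(table, min_maf = 0.02,
                             min_sample_callrate = 0.20,
                             min_locus_callrate = 0.70) {
  n0_samp <- length(table$samples); n0_loci <- nrow(table$loci)
  cr_sample <- rowMeans(!is.na(table$geno))
  keep_s <- cr_sample >= min_sample_callrate
  if (!any(keep_s)) stop("all samples removed by sample call-rate filter")
  tab <- subset_genotypes(table, samples = which(keep_s))
  cr_locus <- colMeans(!is.na(tab$geno))
  maf <- locus_maf(tab)
  keep_l <- cr_locus >= min_locus_callrate & !is.na(maf) & maf >= min_maf
  report <- list(samples_in = n0_samp,
                 samples_dropped = sum(!keep_s),
                 loci_in = n0_loci,
                 loci_dropped_callrate = sum(cr_locus < min_locus_callrate),
                 loci_dropped_maf = sum(cr_locus >= min_locus_callrate &
                                          (is.na(maf) | maf < min_maf)),
                 loci_out = sum(keep_l))
  if (!any(keep_l)) stop("all loci removed by filters; report: ",
                         paste(names(report), unlist(report),
                               sep = "=", collapse = ", "))
  out <- subset_genotypes(tab, loci = which(keep_l))
  if (length(unique(out$groups)) != 2L)
    stop("a whole group was removed by the sample filter")
  attr(out, "filter_report") <- report
  out
}

#' Allele-count 2x2 tables per locus
#'
#' Each non-missing diploid call contributes two alleles.
#'
#' @param table A `genotype_table`.
#' @return List of matrices `alt_a`, `ref_a`, `alt_b`, `ref_b` (vectors per
#'   locus), groups in sorted label order.
#' @keywords internal
allele_counts <- function(table) {
  gi <- group_index(table)
  cnt <- function(idx) {
    g <- table$geno[idx, , drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    n2 <- 2 * colSums(!is.na(g))
    list(alt = alt, ref = n2 - alt)
  }
  a <- cnt(gi[[1]]); b <- cnt(gi[[2]])
  list(alt_a = a$alt, ref_a = a$ref, alt_b = b$alt, ref_b = b$ref)
}

chi2_from_counts <- function(alt_a, ref_a, alt_b, ref_b) {
  n <- alt_a + ref_a + alt_b + ref_b
  ra <- alt_a + ref_a; rb <- alt_b + ref_b
  ca <- alt_a + alt_b; cb <- ref_a + ref_b
  # Pearson chi-squared, 1 df, no continuity correction
  num <- (alt_a * ref_b - ref_a * alt_b)^2 * n
  den <- ra * rb * ca * cb
  chi2 <- ifelse(den == 0, 0, num / den)
  chi2
}

#' Allele-based chi-squared association between the two lines
#'
#' Per locus, a Pearson chi-squared statistic (1 df, no continuity
#' correction) on the 2x2 allele-count table of alt/ref by group. A locus
#' monomorphic after filtering gets chi2 = 0, p = 1.
#'
#' @param table A filtered `genotype_table`.
#' @return `data.table` with per-locus columns: contig, pos, ref, alt,
#'   allele counts, `chi2`, `p`.
#' @export
allelic_association <- function(table) {
  ac <- allele_counts(table)
  chi2 <- chi2_from_counts(ac$alt_a, ac$ref_a, ac$alt_b, ac$ref_b)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[chi2 == 0] <- 1
  data.table(table$loci,
             alt_a = ac$alt_a, ref_a = ac$ref_a,
             alt_b = ac$alt_b, ref_b = ac$ref_b,
             chi2 = chi2, p = p)
}

#' Permutation empirical p-values for the association chi-squared
#'
#' Group labels are permuted jointly across all loci per replicate;
#' empirical `p = (1 + #permuted chi2 >= observed) / (1 + n_perm)`.
#'
#' @param table A filtered `genotype_table`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Numeric vector of empirical p-values, one per locus.
#' @export
permutation_pvalues <- function(table, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  set.seed(seed)
  obs <- allelic_association(table)$chi2
  exceed <- integer(length(obs))
  groups <- table$groups
  for (r in seq_len(n_perm)) {
    perm <- table
    perm$groups <- setNames(sample(groups), names(groups))
    exceed <- exceed +
      (allelic_association(perm)$chi2 >= obs - 1e-12)
  }
  (1 + exceed) / (1 + n_perm)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Own implementation of the standard step-up procedure with monotonicity
#' enforcement (tested against `stats::p.adjust` as an independent route).
#'
#' @param p Vector of p-values in (0, 1].
#' @param alpha Significance level on the adjusted values (default 0.05).
#' @return List with `q` (adjusted p-values) and `significant` (logical,
#'   `q <= alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0L) return(list(q = numeric(0), significant = logical(0)))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  list(q = q, significant = q <= alpha)
}

#' Pairwise linkage-disequilibrium r-squared summary
#'
#' r-squared is the squared Pearson correlation of alt-allele dosages
#' (composite LD; genotypes are unphased). Pairs are subsampled
#' deterministically under `seed` when the number of pairs exceeds
#' `max_pairs`.
#'
#' @param table A filtered `genotype_table`.
#' @param max_pairs Maximum number of locus pairs to evaluate.
#' @param seed Integer seed for pair subsampling.
#' @return List with `r2` (vector), `mean`, `median`, `q25`, `q75`, `n_pairs`.
#' @export
ld_summary <- function(table, max_pairs = 10000L, seed = 1L) {
  m <- ncol(table$geno)
  if (m < 2L) stop("need >= 2 loci for LD")
  n_all <- m * (m - 1) / 2
  set.seed(seed)
  if (n_all <= max_pairs) {
    pairs <- t(utils::combn(m, 2L))
  } else {
    i <- sample.int(m, max_pairs, replace = TRUE)
    j <- sample.int(m, max_pairs, replace = TRUE)
    keep <- i != j
    pairs <- cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE]
    pairs <- unique(pairs)
  }
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- table$geno[, pairs[k, 1]]; y <- table$geno[, pairs[k, 2]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }, numeric(1))
  r2 <- r2[!is.na(r2)]
  list(r2 = r2, mean = mean(r2), median = median(r2),
       q25 = unname(quantile(r2, 0.25)), q75 = unname(quantile(r2, 0.75)),
       n_pairs = length(r2))
}
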