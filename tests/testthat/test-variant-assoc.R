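# brute-force Pearson chi-squared on a 2x2 table from expected counts,
# the independent oracle for the association statistic
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  if (any(e == 0)) return(0)
  sum((tab - e)^2 / e)
}

test_that("genotype filters drop samples first, then loci, inclusively", {
  # 10 samples, 4 loci; sample s10 almost entirely missing
  set.seed(1)
  geno <- matrix(1L, 10, 4)
  geno[, 1] <- c(1L, rep(0L, 9))                 # MAF 0.056 after drop
  geno[, 2] <- rep(0L, 10); geno[2, 2] <- 1L     # MAF 0.05
  geno[, 3] <- rep(0L, 10)                       # monomorphic, MAF 0
  geno[1:4, 4] <- NA                             # call rate 60% (<70%)
  geno[10, 1:3] <- NA                            # s10 call rate 25%
  tab <- make_table(geno, rep(c("A", "B"), each = 5))

  out <- filter_genotypes(tab, min_maf = 0.02,
                          min_sample_callrate = 0.30,
                          min_locus_callrate = 0.70)
  rep_ <- attr(out, "filter_report")
  expect_equal(rep_$samples_dropped, 1L)
  # after s10 drops: locus 4 has 5/9 calls = 56% -> dropped by call rate;
  # locus 3 monomorphic -> dropped by MAF; loci 1, 2 retained
  expect_equal(rep_$loci_dropped_callrate, 1L)
  expect_equal(rep_$loci_dropped_maf, 1L)
  expect_equal(out$loci$pos, c(10L, 20L))

  # MAF exactly at the threshold is retained (inclusive)
  g2 <- matrix(0L, 25, 1); g2[1, 1] <- 1L        # MAF = 1/50 = 0.02
  t2 <- make_table(g2, rep(c("A", "B"), length.out = 25))
  expect_equal(nrow(filter_genotypes(t2)$loci), 1L)
  g2[1, 1] <- 0L                                 # monomorphic now
  expect_error(filter_genotypes(make_table(g2, rep(c("A", "B"), length.out = 25))),
               "all loci removed")

  # complete table above thresholds is untouched
  g3 <- matrix(rep(c(0L, 1L, 2L), length.out = 60), 6, 10)
  t3 <- make_table(g3, rep(c("A", "B"), 3))
  expect_identical(filter_genotypes(t3)$geno, t3$geno)
})

test_that("allelic chi-squared matches the brute-force oracle", {
  # worked example: A (10 alt, 0 ref) vs B (0 alt, 10 ref) -> chi2 20
  t1 <- make_table(rbind(2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L),
                   rep(c("A", "B"), each = 5))
  res <- allelic_association(t1)
  expect_equal(res$chi2, 20)

  # equal counts -> chi2 0, p 1
  t0 <- make_table(rbind(1L, 1L, 1L, 1L), rep(c("A", "B"), 2))
  r0 <- allelic_association(t0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # oracle over 1000 random 2x2 tables realized as genotype tables
  set.seed(11)
  for (i in 1:1000) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    geno <- rbind(matrix(sample(0:2, na, TRUE), ncol = 1),
                  matrix(sample(0:2, nb, TRUE), ncol = 1))
    tt <- make_table(geno, rep(c("A", "B"), c(na, nb)))
    got <- allelic_association(tt)
    ac <- rbind(c(got$alt_a, got$ref_a), c(got$alt_b, got$ref_b))
    expect_equal(got$chi2, oracle_chi2(ac), tolerance = 1e-12)
  }
})

test_that("chi-squared is invariant to group-label and ref/alt swaps", {
  set.seed(5)
  geno <- matrix(sample(c(0:2, NA), 60, TRUE), 10, 6)
  tab <- make_table(geno, rep(c("A", "B"), 5))
  swapped_groups <- make_table(geno, rep(c("B", "A"), 5))
  swapped_alleles <- make_table(2L - geno, rep(c("A", "B"), 5))
  base <- allelic_association(tab)$chi2
  expect_equal(allelic_association(swapped_groups)$chi2, base)
  expect_equal(allelic_association(swapped_alleles)$chi2, base)
})

test_that("permutation p-values behave at the extremes and under the null", {
  # chi2 = 0 -> empirical p = 1
  t0 <- make_table(rbind(1L, 1L, 1L, 1L), rep(c("A", "B"), 2))
  expect_equal(permutation_pvalues(t0, 199, seed = 1), 1)

  # perfectly separating locus, 10 vs 10, n_perm 999 -> p <= 0.01
  sep <- make_table(matrix(rep(c(2L, 0L), each = 10), ncol = 1),
                    rep(c("A", "B"), each = 10))
  expect_lte(permutation_pvalues(sep, 999, seed = 1), 0.01)

  # null locus with exact Hardy-Weinberg dosage counts: the empirical p
  # must converge to the exact permutation p (independent brute-force
  # oracle below) and agree with the analytic chi-squared p up to the
  # discreteness half-atom of the permutation distribution
  geno <- matrix(c(rep(0L, 20), rep(1L, 55), rep(2L, 25),
                   rep(0L, 30), rep(1L, 45), rep(2L, 25)), ncol = 1)
  tt <- make_table(geno, rep(c("A", "B"), each = 100))
  p_analytic <- allelic_association(tt)$p
  n_perm <- 10000
  p_emp <- permutation_pvalues(tt, n_perm, seed = 2)

  # oracle: direct label-resampling with plain-R chi-squared on counts
  set.seed(99)
  d <- geno[, 1]
  obs_chi2 <- allelic_association(tt)$chi2
  n_oracle <- 20000
  hits <- 0L
  for (r in seq_len(n_oracle)) {
    lab <- sample(rep(c(TRUE, FALSE), each = 100))
    tab2 <- rbind(c(sum(d[lab]), 200 - sum(d[lab])),
                  c(sum(d[!lab]), 200 - sum(d[!lab])))
    if (oracle_chi2(tab2) >= obs_chi2 - 1e-12) hits <- hits + 1L
  }
  p_oracle <- (1 + hits) / (1 + n_oracle)
  joint_se <- sqrt(p_oracle * (1 - p_oracle)) *
    sqrt(1 / n_perm + 1 / n_oracle)
  expect_close(p_emp, p_oracle, 3 * joint_se + 2 / n_perm)
  # analytic anchor: the continuous chi-squared p differs from the exact
  # permutation p by at most about half the atom mass at the observed
  # statistic (~0.05 here); allow that on top of the MC error
  expect_close(p_emp, p_analytic, 3 * sqrt(p_analytic / n_perm) + 0.06)
})

test_that("BH step-up matches hand computation and reference implementation", {
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bh_fdr(rep(1, 5))$significant))

  # hand-worked step-up: p=(.01,.02,.03,.04), m=4 -> all q = .04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))

  expect_length(bh_fdr(numeric(0))$q, 0)

  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("BH significant set shrinks as alpha decreases", {
  set.seed(41)
  p <- runif(200)^2
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  sizes <- vapply(alphas, function(a) sum(bh_fdr(p, a)$significant),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("LD r-squared: identity, symmetry, and near-independence scale", {
  set.seed(51)
  x <- sample(0:2, 20, TRUE)
  tab <- make_table(cbind(x, x), rep(c("A", "B"), 10))
  expect_equal(ld_summary(tab)$r2, 1)

  geno <- cbind(sample(0:2, 20, TRUE), sample(0:2, 20, TRUE))
  t2 <- make_table(geno, rep(c("A", "B"), 10))
  t2r <- make_table(geno[, 2:1], rep(c("A", "B"), 10))
  expect_equal(ld_summary(t2)$r2, ld_summary(t2r)$r2)

  expect_error(ld_summary(make_table(matrix(0L, 4, 1), rep(c("A", "B"), 2))),
               ">= 2 loci")

  # independent loci: E[r2] ~ 1/(n-1) for n samples
  set.seed(61)
  n <- 30
  geno <- matrix(rbinom(n * 200, 2, 0.5), n, 200)
  tl <- make_table(geno, rep(c("A", "B"), n / 2))
  s <- ld_summary(tl, max_pairs = 5000, seed = 1)
  expect_close(s$mean, 1 / (n - 1), 0.02)
})
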