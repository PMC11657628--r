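# independent Weir-Cockerham (1984) oracle, written directly from the
# two-population variance-component formulas with scalar arithmetic
oracle_wc <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2); r <- 2
  p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
  h1 <- mean(d1 == 1); h2 <- mean(d2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(0)
  a / (a + b + cc)
}

test_that("Weir-Cockerham Fst: identity, fixation, and random-table oracle", {
  # identical HWE frequencies and heterozygosities in both groups -> ~0
  # (the estimator is slightly negative at the exact symmetric realization)
  hwe <- rep(c(0L, 1L, 2L), c(25, 50, 25))
  t0 <- make_table(matrix(c(hwe, hwe), ncol = 1),
                   rep(c("A", "B"), each = 100))
  expect_lt(abs(wc_fst(t0)$fst[1]), 0.01)

  # opposite fixation -> exactly 1 (9 vs 7 samples)
  tf <- make_table(matrix(rep(c(0L, 2L), c(9, 7)), ncol = 1),
                   rep(c("A", "B"), c(9, 7)))
  expect_equal(wc_fst(tf)$fst, 1)

  # random tables against the scalar oracle
  set.seed(71)
  for (i in 1:200) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    geno <- matrix(c(rbinom(n1, 2, runif(1, .1, .9)),
                     rbinom(n2, 2, runif(1, .1, .9))), ncol = 1)
    tt <- make_table(geno, rep(c("A", "B"), c(n1, n2)))
    expect_equal(wc_fst(tt)$fst,
                 oracle_wc(geno[seq_len(n1), 1], geno[n1 + seq_len(n2), 1]),
                 tolerance = 1e-12)
  }

  # fewer than 2 calls in a group -> NA
  gm <- matrix(c(0L, 0L, NA, 2L, NA, NA), ncol = 1)
  tm <- make_table(gm, rep(c("A", "B"), each = 3))
  expect_true(is.na(wc_fst(tm)$fst))
})

test_that("Tajima's D matches pairwise-difference enumeration on few haplotypes", {
  # brute-force oracle: enumerate all chromosome pairs
  oracle_tajima <- function(hap) {
    nch <- nrow(hap)
    S <- sum(apply(hap, 2, function(col) length(unique(col)) > 1))
    if (S == 0) return(NA_real_)
    pairs <- utils::combn(nch, 2)
    pi <- mean(vapply(seq_len(ncol(pairs)), function(k)
      sum(hap[pairs[1, k], ] != hap[pairs[2, k], ]), numeric(1)))
    a1 <- sum(1 / seq_len(nch - 1)); a2 <- sum(1 / seq_len(nch - 1)^2)
    b1 <- (nch + 1) / (3 * (nch - 1))
    b2 <- 2 * (nch^2 + nch + 3) / (9 * nch * (nch - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (nch + 2) / (a1 * nch) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }

  # printed toy configuration: 4 haplotypes, 2 segregating sites
  hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(0, 0))
  tab <- table_from_haplotypes(hap, groups = c("A", "B"))
  win <- tajima_d_windows(tab, c(c1 = 100), window_bp = 100)
  expect_equal(win$S, 2L)
  expect_equal(win$D, oracle_tajima(hap), tolerance = 1e-12)

  # random configurations with up to 6 haplotypes
  set.seed(81)
  for (i in 1:50) {
    nch <- sample(c(4, 6), 1)
    hap <- matrix(rbinom(nch * 8, 1, 0.4), nch, 8)
    tab <- table_from_haplotypes(hap)
    win <- tajima_d_windows(tab, c(c1 = 100), window_bp = 100)
    exp_d <- oracle_tajima(hap)
    if (is.na(exp_d)) expect_true(is.na(win$D))
    else expect_equal(win$D, exp_d, tolerance = 1e-12)
  }

  # S = 0 -> D undefined
  tab0 <- table_from_haplotypes(matrix(0, 4, 3))
  expect_true(is.na(tajima_d_windows(tab0, c(c1 = 100), 100)$D))
})

test_that("windowed D is calibrated near zero on a neutral SFS", {
  # sites with derived-allele counts drawn from the neutral 1/i spectrum
  # for 2n = 34 chromosomes; windowed D should then centre near 0
  set.seed(101)
  nch <- 34L; n_loci <- 5000L
  counts <- sample(1:(nch - 1), n_loci, replace = TRUE,
                   prob = 1 / (1:(nch - 1)))
  hap <- vapply(counts, function(k)
    sample(rep(c(1L, 0L), c(k, nch - k))), integer(nch))
  tab <- table_from_haplotypes(hap)
  tab$loci$pos <- sort(sample.int(1000000L, n_loci))
  win <- tajima_d_windows(tab, c(c1 = 1000000), window_bp = 10000)
  expect_gte(sum(!is.na(win$D)), 50)
  expect_lt(abs(mean(win$D, na.rm = TRUE)), 0.5)
})

test_that("attach_tajima uses containing windows and handles gaps", {
  tab <- make_table(matrix(c(0L, 1L, 2L, 1L), ncol = 2),
                    c("A", "B"), pos = c(50L, 150L))
  win <- data.table::data.table(contig = "c1", start = c(1L, 101L),
                                end = c(100L, 200L), D = c(-0.4, NA))
  d <- attach_tajima(tab, win)
  expect_equal(d[1], -0.4)
  expect_true(is.na(d[2]))    # only containing window has undefined D

  # boundary: position 101 belongs to the second window only
  tb <- make_table(matrix(c(0L, 1L, 2L, 1L), 2), c("A", "B"),
                   pos = c(100L, 101L))
  win2 <- data.table::data.table(contig = "c1", start = c(1L, 101L),
                                 end = c(100L, 200L), D = c(1, 2))
  expect_equal(attach_tajima(tb, win2), c(1, 2))
})

test_that("selection classification follows the ordered rule list", {
  cases <- list(
    list(1,    -0.3, "FixedAllele"),
    list(0.30, -0.4, "PositiveSelection"),
    list(0.30,  0.4, "BalancingSelection"),
    list(0.30,  0.0, "HighFstNeutralTajima"),
    list(0.03, -0.2, "NegativeSelection"),
    list(0.03,  0.2, "PossiblePopulationStructureExpansion"),
    list(0.15,  0.2, "Neutral"),
    list(0.03,  NA,  "NonSelected"),
    list(0.15,  NA,  "Neutral"),
    list(0.30,  NA,  "HighFstNoTajimaData"),
    list(0.30,  NA,  "HighFstNoTajimaData"),
    list(-0.02, -0.2, "NegativeSelection"))  # clamped to 0 first
  for (cs in cases)
    expect_equal(as.character(classify_selection(cs[[1]], cs[[2]])), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))

  # totality: every (fst, D) combination gets exactly one class
  set.seed(91)
  fst <- runif(500, -0.05, 1)
  fst[sample(500, 20)] <- 1
  d <- runif(500, -2, 2)
  d[sample(500, 60)] <- NA
  d[sample(500, 10)] <- 0
  cls <- classify_selection(fst, d)
  expect_false(anyNA(cls))
})

test_that("planted fixed loci are recovered as FixedAllele", {
  sim <- default_sim()
  pg <- popgen_stats(sim$genotypes,
                     setNames(Biostrings::width(sim$genome),
                              names(sim$genome)))
  fixed_truth <- sim$truth$loci$class == "fixed"
  expect_gte(sum(fixed_truth), 10)
  got <- as.character(pg$class[fixed_truth])
  expect_gte(mean(got == "FixedAllele"), 0.8)  # missing_rate 0.05 world
})
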