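gr_reads <- function(starts, width = 50L, strand = "+", contig = "c1") {
  GenomicRanges::GRanges(contig, IRanges::IRanges(starts, width = width),
                         strand = strand)
}

test_that("stacked-read filter caps duplicates via the Poisson tail", {
  # all unique starts -> nothing removed
  r <- gr_reads(seq(1, 2000, by = 50))
  out <- stacked_read_filter(r, genome_length = 4000)
  expect_equal(out$n_removed, 0L)
  expect_equal(length(out$reads), length(r))

  # lambda ~ 0.1: P(X>=2)=4.7e-3 >= 1e-3, P(X>=3)=1.5e-4 < 1e-3 -> cap 2
  r2 <- gr_reads(c(rep(100L, 50), sample(1:4000, 350)))
  out2 <- stacked_read_filter(r2, genome_length = 4000, p = 0.001)
  expect_equal(out2$cap, 2L)
  expect_equal(sum(GenomicRanges::start(out2$reads) == 100L), 2L)

  # cap grows monotonically with lambda
  caps <- vapply(c(0.01, 0.1, 1, 5, 20), function(lam)
    max(1L, as.integer(qpois(1 - 0.001, lam))), integer(1))
  expect_true(all(diff(caps) >= 0))
  # and matches the package on a grid of depths
  for (lam in c(0.05, 0.5, 2)) {
    rr <- gr_reads(sample(1:1000, round(lam * 1000), replace = TRUE))
    expect_equal(stacked_read_filter(rr, 1000)$cap,
                 max(1L, qpois(0.999, length(rr) / 1000)))
  }
})

test_that("reads extend 3'-ward to 100 bp and clip at contig ends", {
  lens <- c(c1 = 1000L)
  plus <- extend_reads(gr_reads(101L), 100L, lens)
  expect_equal(c(GenomicRanges::start(plus), GenomicRanges::end(plus)),
               c(101L, 200L))
  minus <- extend_reads(gr_reads(101L, strand = "-"), 100L, lens)
  expect_equal(c(GenomicRanges::start(minus), GenomicRanges::end(minus)),
               c(51L, 150L))
  long <- extend_reads(gr_reads(101L, width = 120L), 100L, lens)
  expect_equal(GenomicRanges::width(long), 120L)
  edge <- extend_reads(gr_reads(980L), 100L, lens)
  expect_equal(GenomicRanges::end(edge), 1000L)
  edge2 <- extend_reads(gr_reads(10L, strand = "-"), 100L, lens)
  expect_equal(GenomicRanges::start(edge2), 1L)
})

test_that("window counting uses any-overlap", {
  g <- tiny_genome(c(c1 = paste(rep("ACGT", 200), collapse = "")))  # 800 bp
  # one read exactly spanning window 1, one straddling windows 1-2
  reads <- list(s1 = gr_reads(c(1L, 280L), width = c(300L, 40L)))
  m <- window_counts(reads, g, window_bp = 300L)
  expect_equal(m$counts[, "s1"], c(2L, 1L, 0L))
  expect_gte(sum(m$counts), 2)   # total increments >= total reads
})

test_that("coupling normalization is flat, CPM-invariant, and decorrelates", {
  sim <- default_sim()
  mat <- window_counts(sim$medip$reads, sim$genome, 300L)
  norm <- coupling_normalize(mat)

  # raw coverage correlates with CF; rms does not (mean over samples to
  # average out counting noise)
  cpm <- rowMeans(sweep(mat$counts, 2, colSums(mat$counts), "/"))
  rho_before <- abs(cor(cpm, mat$cf, method = "spearman"))
  rho_after <- abs(cor(rowMeans(norm$rms), norm$cf, method = "spearman"))
  expect_gte(rho_before, 0.5)
  expect_lt(rho_after, 0.1)

  # doubling one sample's counts leaves its rms unchanged
  mat2 <- mat
  mat2$counts[, 1] <- mat$counts[, 1] * 2L
  norm2 <- coupling_normalize(mat2)
  expect_equal(norm2$rms[, 1], norm$rms[, 1], tolerance = 1e-8)

  # identical CF and counts everywhere -> rms = 1
  flat <- structure(list(windows = mat$windows[1:50],
                         counts = matrix(7L, 50, 3,
                                         dimnames = list(NULL, c("a", "b", "c"))),
                         cf = rep(5L, 50), samples = c("a", "b", "c")),
                    class = "methyl_window_matrix")
  expect_equal(unname(coupling_normalize(flat)$rms),
               matrix(1, 50, 3), tolerance = 1e-12)
})

test_that("near-zero dispersion behaves as Poisson", {
  cfg <- sim_config(seed = 7, n_contigs = 1L, contig_length = 100000L,
                    n_genes = 8L, medip_dispersion = 1e-6, n_dmr = 0L,
                    n_samples_per_line = c(2L, 2L), n_qtl = 1L,
                    qtl_length = c(5000L, 10000L))
  gen <- simulate_genome(cfg)
  md <- simulate_medip(cfg, gen$genome, plant_dmrs(cfg, gen$genome)[0])
  m <- window_counts(md$reads, gen$genome, 300L)
  # variance/mean across windows of similar CF should be ~1; bin by CF
  cf_bin <- cut(m$cf, breaks = quantile(m$cf, 0:5 / 5), include.lowest = TRUE)
  vm <- vapply(split(seq_along(m$cf), cf_bin), function(i) {
    x <- as.vector(m$counts[i, ])
    stats::var(x) / mean(x)
  }, numeric(1))
  expect_lt(median(vm, na.rm = TRUE), 1.6)
})

test_that("differential windows drop low-count rows and control the null", {
  sim <- default_sim()
  mat <- coupling_normalize(window_counts(sim$medip$reads, sim$genome, 300L))

  # windows with total count 9 dropped, 10 kept
  tot <- rowSums(mat$counts)
  d <- differential_windows(mat, sim$medip$groups, min_row_sum = 10L)
  expect_equal(nrow(d), sum(tot >= 10))

  # zero variance in both groups with equal means -> p = 1
  z <- structure(list(windows = mat$windows[1:2],
                      counts = matrix(10L, 2, 4,
                                      dimnames = list(NULL, letters[1:4])),
                      cf = c(3L, 3L), samples = letters[1:4]),
                 class = "methyl_window_matrix")
  z <- coupling_normalize(z)
  dz <- differential_windows(z, setNames(c("A", "A", "B", "B"), letters[1:4]),
                             min_row_sum = 1L)
  expect_equal(dz$p, c(1, 1))
})

test_that("null window p-values are uniform (KS at 1%)", {
  # a null world with no planted DMRs and ~5,300 windows
  cfg <- sim_config(seed = 13, n_contigs = 8L, n_dmr = 0L)
  gen <- simulate_genome(cfg)
  md <- simulate_medip(cfg, gen$genome, plant_dmrs(cfg, gen$genome)[0])
  res <- call_dmrs(md$reads, md$groups, gen$genome)
  expect_gte(nrow(res$windows), 5000)
  ks <- suppressWarnings(stats::ks.test(res$windows$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DMRs merge same-direction windows within a 1 bp gap", {
  base <- data.table::data.table(
    contig = "c1",
    start = c(1L, 301L, 901L, 1201L, 1801L),
    end = c(300L, 600L, 1200L, 1500L, 2100L),
    cf = 5L, mean_a = 0, mean_b = 1,
    log2fc = c(1, 1, 1, -1, 1), p = 0.01, significant = TRUE)
  g <- tiny_genome(c(c1 = paste(rep("ACGT", 600), collapse = "")))
  dmrs <- merge_dmrs(base, g)
  # windows 1+2 adjacent same direction -> one 600 bp DMR; windows 3 and 4
  # adjacent but opposite direction -> separate; window 5 isolated
  expect_equal(nrow(dmrs), 4L)
  expect_equal(dmrs$end[1] - dmrs$start[1] + 1L, 600L)
  expect_equal(dmrs$n_windows, c(2L, 1L, 1L, 1L))
  expect_equal(sum(dmrs$direction == "hypo_in_B"), 1L)
  # CpG count recomputed on the merged span: ACGT repeats have CG at 2-3
  # of every 4-mer -> 150 per 600 bp
  expect_equal(dmrs$n_cpgs[1], 150L)

  # two significant windows separated by a non-significant one stay apart
  gap <- base[c(1, 3)]
  expect_equal(nrow(merge_dmrs(gap, g)), 2L)
})

test_that("direction bookkeeping percentages add up", {
  d <- data.table::data.table(direction = rep(c("hypo_in_B", "hyper_in_B"),
                                              c(107, 125)))
  s <- dmr_direction_summary(d)
  expect_equal(s$n, 232L)
  expect_equal(round(s$pct_hypo_in_b, 1), 46.1)
  expect_equal(s$n_hypo_in_b + s$n_hyper_in_b, s$n)
})

test_that("CpG enrichment scores: identity, islands, and split invariance", {
  sim <- default_sim()
  g <- sim$genome
  whole <- GenomicRanges::GRanges(names(g),
                                  IRanges::IRanges(1L, Biostrings::width(g)))
  sc <- cpg_enrichment_score(whole, g)
  expect_equal(sc$relH, 1, tolerance = 1e-12)
  expect_equal(sc$GoGe, 1, tolerance = 1e-12)

  # promoter regions were CpG-enriched by construction
  tss <- vapply(sim$genes, `[[`, numeric(1), "tss")
  ctg <- vapply(sim$genes, `[[`, character(1), "contig")
  prom <- GenomicRanges::GRanges(ctg, IRanges::IRanges(pmax(1, tss - 1000),
                                                       tss + 1000))
  expect_gt(cpg_enrichment_score(prom, g)$relH, 1.5)

  # splitting a region into adjacent halves changes nothing
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1001, 2001),
                                                        c(2000, 3000)))
  expect_equal(cpg_enrichment_score(r1, g)$relH,
               cpg_enrichment_score(r2, g)$relH, tolerance = 1e-12)
  expect_error(cpg_enrichment_score(r1[0], g), "non-empty")
})

test_that("planted DMRs are recovered at the stated power", {
  sim <- default_sim()
  res <- call_dmrs(sim$medip$reads, sim$medip$groups, sim$genome)
  truth <- sim$dmr_truth
  tg <- GenomicRanges::GRanges(GenomicRanges::seqnames(truth),
                               IRanges::IRanges(GenomicRanges::start(truth),
                                                GenomicRanges::end(truth)))
  if (nrow(res$dmrs)) {
    cg <- GenomicRanges::GRanges(res$dmrs$contig,
                                 IRanges::IRanges(res$dmrs$start, res$dmrs$end))
    rec <- mean(GenomicRanges::countOverlaps(tg, cg) > 0)
  } else rec <- 0
  expect_gte(rec, 0.6)

  # recovered direction matches the planted direction
  hit <- GenomicRanges::findOverlaps(tg, cg)
  planted_dir <- S4Vectors::mcols(truth)$direction[S4Vectors::queryHits(hit)]
  called_dir <- res$dmrs$direction[S4Vectors::subjectHits(hit)]
  # groups sorted A < B: hyper_in_B <=> log2fc (B - A) > 0
  expect_gte(mean((planted_dir == "hyper_in_B") ==
                    (called_dir == "hyper_in_B")), 0.9)
})
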