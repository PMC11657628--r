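# Shared fixtures, built in code and memoized for the test session.

.fixtures <- new.env(parent = emptyenv())

# the default stated-world dataset (seed 42), computed once per run
default_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_dataset(sim_config(seed = 42))
  .fixtures$sim
}

# a tiny handcrafted genome for string-level tests
tiny_genome <- function(seqs = c(c1 = "AACGTTACGTAACCGGTT",
                                 c2 = "TTTTACGCGTTTTTTTTT")) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# build a genotype table from a dosage matrix (samples x loci)
make_table <- function(geno, groups,
                       contig = "c1",
                       pos = seq_len(ncol(geno)) * 10L,
                       ref = rep("A", ncol(geno)),
                       alt = rep("G", ncol(geno))) {
  samples <- sprintf("s%02d", seq_len(nrow(geno)))
  genotype_table(data.table::data.table(contig = contig, pos = pos,
                                        ref = ref, alt = alt),
                 geno, samples, groups)
}

# genotype table realizing a given haplotype matrix (2n haplotypes x loci),
# consecutive haplotypes paired into diploids
table_from_haplotypes <- function(hap, groups = NULL) {
  stopifnot(nrow(hap) %% 2 == 0)
  n <- nrow(hap) / 2
  geno <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = n)
  make_table(geno, groups)
}

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
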