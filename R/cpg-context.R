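# CpG context of SNPs against the reference genome: fixed allele
# differences between lines, CpG loss (CpG-SNPs), CpG gain (novel CpGs) and
# the 1/16-expectancy enrichment statistics.

#' Loci with differentially fixed alleles between the lines
#'
#' A locus is reported iff every non-missing call in one line is homozygous
#' for one allele, every non-missing call in the other line is homozygous
#' for the other allele, and each line has at least one non-missing call
#' (allele frequency exactly 0 or 1 per line, opposite alleles).
#'
#' @param table A `genotype_table`.
#' @return `data.table` of the qualifying loci with the fixed allele per
#'   line (columns `allele_a`, `allele_b` holding the base fixed in each
#'   group, `change` like `"G>A"`).
#' @export
fixed_allele_differences <- function(table) {
  gi <- group_index(table)
  summ <- function(idx) {
    g <- table$geno[idx, , drop = FALSE]
    n <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    het <- colSums(g == 1L, na.rm = TRUE)
    list(n = n, freq = alt / (2 * n), het = het)
  }
  a <- summ(gi[[1]]); b <- summ(gi[[2]])
  hom_a <- a$n >= 1 & a$het == 0 & (a$freq == 0 | a$freq == 1)
  hom_b <- b$n >= 1 & b$het == 0 & (b$freq == 0 | b$freq == 1)
  sel <- which(hom_a & hom_b & a$freq != b$freq)
  loci <- table$loci[sel]
  base <- function(freq, i) ifelse(freq[sel] == 1, loci$alt, loci$ref)
  out <- data.table(loci,
                    allele_a = ifelse(a$freq[sel] == 1, loci$alt, loci$ref),
                    allele_b = ifelse(b$freq[sel] == 1, loci$alt, loci$ref))
  out$change <- paste0(out$ref, ">", out$alt)
  out
}

# vectorized +/- 1 bp reference context for a set of loci
ref_context <- function(genome, loci) {
  seqs <- as.character(genome)
  s <- seqs[loci$contig]
  len <- nchar(s)
  pos <- loci$pos
  list(here = substr(s, pos, pos),
       prev = ifelse(pos > 1L, substr(s, pos - 1L, pos - 1L), NA),
       nxt = ifelse(pos < len, substr(s, pos + 1L, pos + 1L), NA))
}

#' Call CpG loss (CpG-SNP) context for loci
#'
#' A locus is a CpG loss when its reference base is the C of a reference
#' CpG and the alternate allele is not C (plus strand), or — the strand
#' complement — the reference base is the G of a CpG and the alternate is
#' not G (minus strand). Loci at contig edges with no neighbour are
#' `other` and flagged.
#'
#' @param genome `DNAStringSet`.
#' @param loci `data.table` with contig, pos, ref, alt.
#' @return `data.table`: `context` (`CpG_loss`/`other`), `strand_of_cpg`
#'   (`+`, `-`, `n/a`), `change_type`, `edge_flag`.
#' @export
call_cpg_loss <- function(genome, loci) {
  n <- nrow(loci)
  cx <- ref_context(genome, loci)
  bad <- which(loci$ref != cx$here)
  if (length(bad))
    stop("ref allele does not match genome at ", loci$contig[bad[1]], ":",
         loci$pos[bad[1]])
  context <- rep("other", n); strand <- rep("n/a", n)
  plus <- loci$ref == "C" & !is.na(cx$nxt) & cx$nxt == "G" & loci$alt != "C"
  minus <- loci$ref == "G" & !is.na(cx$prev) & cx$prev == "C" &
    loci$alt != "G"
  context[plus | minus] <- "CpG_loss"
  strand[plus] <- "+"; strand[minus] <- "-"
  edge <- (loci$ref == "C" & is.na(cx$nxt)) |
    (loci$ref == "G" & is.na(cx$prev))
  data.table(context = context, strand_of_cpg = strand,
             change_type = paste0(loci$ref, "→", loci$alt),
             edge_flag = edge)
}

#' Call novel-CpG (CpG gain) context for loci
#'
#' A locus is a novel CpG when the alternate allele is C, the reference
#' 3-prime neighbour is G and the reference base is not C (the alternate C
#' completes a CpG absent from the reference). Only the C-containing case
#' counts; G-side gains are not called.
#'
#' @inheritParams call_cpg_loss
#' @return `data.table`: `context` (`novel_CpG`/`other`), `strand_of_cpg`,
#'   `change_type`, `edge_flag`.
#' @export
call_novel_cpg <- function(genome, loci) {
  n <- nrow(loci)
  cx <- ref_context(genome, loci)
  context <- rep("other", n); strand <- rep("n/a", n)
  gain <- loci$alt == "C" & loci$ref != "C" & !is.na(cx$nxt) & cx$nxt == "G"
  context[gain] <- "novel_CpG"
  strand[gain] <- "+"
  data.table(context = context, strand_of_cpg = strand,
             change_type = paste0(loci$ref, "→", loci$alt),
             edge_flag = is.na(cx$nxt))
}

#' Combined CpG context call
#'
#' CpG loss takes precedence (the two are mutually exclusive by
#' construction: a loss requires ref C/G of a reference CpG, a gain
#' requires alt C with ref not C and no reference C at the position).
#'
#' @inheritParams call_cpg_loss
#' @return `data.table` with a single `context` column in
#'   `{CpG_loss, novel_CpG, other}` plus strand, change type and edge flag.
#' @export
call_cpg_context <- function(genome, loci) {
  loss <- call_cpg_loss(genome, loci)
  gain <- call_novel_cpg(genome, loci)
  context <- ifelse(loss$context == "CpG_loss", "CpG_loss",
                    ifelse(gain$context == "novel_CpG", "novel_CpG", "other"))
  strand <- ifelse(context == "CpG_loss", loss$strand_of_cpg,
                   ifelse(context == "novel_CpG", gain$strand_of_cpg, "n/a"))
  data.table(context = context, strand_of_cpg = strand,
             change_type = loss$change_type,
             edge_flag = loss$edge_flag | gain$edge_flag)
}

#' Most frequent allele per line at each locus
#'
#' Dosage-weighted allele frequencies per line; ties break toward the
#' reference allele. Lines with no calls at the locus come back `NA`.
#'
#' @param table A `genotype_table`.
#' @return `data.table` with columns `most_frequent_a`, `most_frequent_b`
#'   (bases), one row per locus.
#' @export
most_frequent_allele_by_line <- function(table) {
  gi <- group_index(table)
  mf <- function(idx) {
    g <- table$geno[idx, , drop = FALSE]
    n <- colSums(!is.na(g))
    freq_alt <- colSums(g, na.rm = TRUE) / (2 * n)
    out <- ifelse(freq_alt > 0.5, table$loci$alt, table$loci$ref)
    out[n == 0] <- NA_character_
    out
  }
  data.table(most_frequent_a = mf(gi[[1]]), most_frequent_b = mf(gi[[2]]))
}

#' 1/16-expectancy CpG-SNP enrichment table
#'
#' For each feature category and overall: expected CpG-SNPs = n/16 (the
#' probability that a uniform random dinucleotide is CpG), fold =
#' observed/expected, and a 1-df goodness-of-fit chi-squared on the 2-cell
#' table (CpG-SNP vs non-CpG-SNP against expectancies n/16 and 15n/16).
#'
#' @param is_cpg Logical vector: SNP is a CpG-SNP.
#' @param category Character/factor vector of feature categories, parallel
#'   to `is_cpg`.
#' @return `data.table`: feature_category, n_snps, expected_cpg,
#'   observed_cpg, fold, chi2, p (a `Total` row last). Categories with
#'   n = 0 get `NA` fold.
#' @export
enrichment_table <- function(is_cpg, category) {
  stopifnot(length(is_cpg) == length(category))
  category <- as.character(category)
  cats <- unique(category)
  row_for <- function(n, obs, name) {
    exp_cpg <- n / 16
    if (n == 0)
      return(data.table(feature_category = name, n_snps = 0L,
                        expected_cpg = 0, observed_cpg = 0L,
                        fold = NA_real_, chi2 = NA_real_, p = NA_real_))
    chi2 <- (obs - exp_cpg)^2 / exp_cpg +
      ((n - obs) - 15 * n / 16)^2 / (15 * n / 16)
    data.table(feature_category = name, n_snps = as.integer(n),
               expected_cpg = exp_cpg, observed_cpg = as.integer(obs),
               fold = obs / exp_cpg, chi2 = chi2,
               p = pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  rows <- lapply(cats, function(cc)
    row_for(sum(category == cc), sum(is_cpg[category == cc]), cc))
  rows <- c(rows, list(row_for(length(is_cpg), sum(is_cpg), "Total")))
  data.table::rbindlist(rows)
}
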