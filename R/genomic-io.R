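#' @import methods
#' @importFrom stats cor isoreg median pchisq pnorm pt phyper
#'   qnorm qpois quantile rbeta rbinom rlnorm rnbinom rpois runif sd
#'   setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table fread fwrite setkey setorder := .N .SD
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce tileGenome sort resize shift
#'   "start<-" "end<-" "strand<-"
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqlevels
#'   "seqinfo<-" "seqlevels<-"
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   vmatchPattern letterFrequency subseq width reverseComplement
NULL

# ---- FASTA ------------------------------------------------------------------

#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased on load; the result is a `DNAStringSet` whose
#' names form the contig registry used by every other module.
#'
#' @param path Path to a FASTA file (plain text; CRLF tolerated).
#' @return A `DNAStringSet`, one element per contig.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  genome <- readDNAStringSet(path, format = "fasta")
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate contig name in ", path)
  if (any(Biostrings::width(genome) == 0L))
    stop("empty sequence in ", path)
  toupper_dss(genome)
}

toupper_dss <- function(x) {
  nm <- names(x)
  x <- DNAStringSet(toupper(as.character(x)))
  names(x) <- nm
  x
}

#' Write a genome to FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

#' Seqinfo for a loaded genome
#' @param genome A `DNAStringSet` from [read_fasta()].
#' @return A `Seqinfo` with one entry per contig.
#' @export
genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = Biostrings::width(genome))
}

#' Total genome length in bp
#' @param genome A `DNAStringSet`.
#' @export
genome_length <- function(genome) sum(as.numeric(Biostrings::width(genome)))

# ---- genotype table ---------------------------------------------------------

#' Construct a genotype table
#'
#' The container for diploid biallelic genotypes of two labelled groups.
#' Calls are stored as alt-allele dosage (0, 1, 2) with `NA` for missing.
#'
#' @param loci `data.table` with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param geno Integer matrix, samples x loci, entries in `{0, 1, 2, NA}`.
#' @param samples Character vector of sample ids (rows of `geno`).
#' @param groups Character vector, one group label per sample; exactly two
#'   distinct labels are required.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(loci, geno, samples, groups) {
  loci <- data.table::as.data.table(loci)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(loci)),
            nrow(geno) == length(samples), ncol(geno) == nrow(loci),
            length(groups) == length(samples))
  if (anyDuplicated(loci[, paste(contig, pos)]))
    stop("loci must be unique by (contig, pos)")
  glev <- sort(unique(as.character(groups)))
  if (length(glev) != 2L) stop("exactly two groups required")
  geno <- matrix(as.integer(geno), nrow = nrow(geno),
                 dimnames = list(samples, NULL))
  if (any(!is.na(geno) & (geno < 0L | geno > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  structure(list(loci = loci, geno = geno, samples = samples,
                 groups = setNames(as.character(groups), samples),
                 group_levels = glev),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("genotype_table: %d samples (%s) x %d loci, missingness %.3f\n",
              length(x$samples),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$geno), mean(is.na(x$geno))))
  invisible(x)
}

#' Sample indices of each group
#' @param table A `genotype_table`.
#' @return List of two integer vectors named by group label.
#' @export
group_index <- function(table) {
  lapply(setNames(table$group_levels, table$group_levels),
         function(g) which(table$groups == g))
}

# ---- VCF --------------------------------------------------------------------

#' Read biallelic SNPs from a VCF into a genotype table
#'
#' Only biallelic SNP records are kept; multi-allelic records are skipped and
#' counted. Half-missing diploid calls (e.g. `0/.`) are treated as fully
#' missing.
#'
#' @param path VCF path (v4.2, GT field).
#' @param group_map Named character vector mapping every sample in the VCF to
#'   one of two group labels.
#' @return A `genotype_table`; the number of skipped multi-allelic records is
#'   attached as attribute `n_skipped_multiallelic`.
#' @export
read_vcf <- function(path, group_map) {
  stopifnot(file.exists(path))
  vcf <- VariantAnnotation::readVcf(path, genome = "user")
  samples <- colnames(vcf)
  missing_map <- setdiff(samples, names(group_map))
  if (length(missing_map))
    stop("samples absent from group_map: ", paste(missing_map, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  n_alt <- S4Vectors::elementNROWS(alt)
  alt_chr <- rep(NA_character_, length(n_alt))
  alt_chr[n_alt == 1L] <- as.character(unlist(alt[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & nchar(alt_chr) == 1L &
    alt_chr %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip) message(n_skip, " non-biallelic-SNP record(s) skipped")
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  loci <- data.table(contig = as.character(seqnames(rr))[keep],
                     pos = start(rr)[keep],
                     ref = ref[keep], alt = alt_chr[keep])
  tab <- genotype_table(loci, t(dos), samples, group_map[samples])
  attr(tab, "n_skipped_multiallelic") <- n_skip
  tab
}

gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- suppressWarnings(as.integer(a1) + as.integer(a2))
  d[a1 == "." | a2 == "."] <- NA_integer_   # half-calls fully missing
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype table as VCF v4.2
#' @param table A `genotype_table`.
#' @param path Output path.
#' @param contig_lengths Optional named lengths for `##contig` headers.
#' @export
write_vcf <- function(table, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divomics",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", table$samples),
                      collapse = "\t"))
  gt <- c("0/0", "0/1", "1/1")[table$geno + 1L]
  gt[is.na(gt)] <- "./."
  gt <- matrix(gt, nrow = nrow(table$geno))
  body <- vapply(seq_len(nrow(table$loci)), function(i) {
    paste(c(table$loci$contig[i], table$loci$pos[i], ".",
            table$loci$ref[i], table$loci$alt[i], ".", "PASS", ".",
            "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- BED --------------------------------------------------------------------

#' Read a BED file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention on read; [write_bed()] converts back, so round trips are
#' exact. Intervals are sorted per contig on load.
#'
#' @param path BED path (3+ columns, tab separated).
#' @param kind One of `"generic"`, `"qtl"` (column 4 is the interval name),
#'   `"repeat"` (column 4 is the repeat class), `"reads"` (column 6 is strand,
#'   column 7 the sample id).
#' @param genome Optional `DNAStringSet`; intervals extending past a contig
#'   end are clipped with a warning.
#' @return A sorted `GRanges`, with metadata columns according to `kind`.
#' @export
read_bed <- function(path, kind = c("generic", "qtl", "repeat", "reads"),
                     genome = NULL) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  bed <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(bed) < 3L) stop("BED needs >= 3 columns: ", path)
  st <- as.numeric(bed[[2]]); en <- as.numeric(bed[[3]])
  bad <- which(en <= st)
  if (length(bad))
    stop("end <= start at line ", bad[1], " of ", path)
  gr <- GRanges(as.character(bed[[1]]), IRanges(st + 1, en))
  if (kind == "qtl" && ncol(bed) >= 4L) mcols(gr)$name <- as.character(bed[[4]])
  if (kind == "repeat") {
    if (ncol(bed) < 4L) stop("repeat BED needs a class column: ", path)
    mcols(gr)$class <- as.character(bed[[4]])
  }
  if (kind == "reads") {
    if (ncol(bed) < 7L) stop("reads BED needs 7 columns: ", path)
    strand(gr) <- as.character(bed[[6]])
    mcols(gr)$sample <- as.character(bed[[7]])
  }
  if (!is.null(genome)) {
    si <- genome_seqinfo(genome)
    unknown <- setdiff(unique(as.character(seqnames(gr))), seqlevels(si))
    if (length(unknown))
      stop("contig(s) not in genome: ", paste(unknown, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- seqlevels(si)
    lens <- seqlengths(si)[as.character(seqnames(gr))]
    over <- end(gr) > lens
    if (any(over)) {
      warning(sum(over), " interval(s) clipped at contig end in ", path)
      end(gr)[over] <- lens[over]
    }
    seqinfo(gr) <- si
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Emits sorted 0-based half-open records. A `name`/`class` metadata column
#' becomes column 4; for `reads`-style ranges with a `sample` column a BED6+1
#' layout (name, score 0, strand, sample) is produced.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  dt <- data.table(V1 = as.character(seqnames(gr)),
                   V2 = start(gr) - 1L, V3 = end(gr))
  mc <- mcols(gr)
  if ("sample" %in% names(mc)) {
    dt$V4 <- if ("name" %in% names(mc)) mc$name else "read"
    dt$V5 <- 0L
    dt$V6 <- as.character(strand(gr))
    dt$V7 <- mc$sample
  } else if ("name" %in% names(mc)) {
    dt$V4 <- mc$name
  } else if ("class" %in% names(mc)) {
    dt$V4 <- mc$class
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons `GRanges` of exons (non-overlapping; sorted on construction).
#' @param utr5,utr3 Optional `GRanges` of untranslated regions.
#' @return An object of class `gene_model`. The TSS is the leftmost exon
#'   start on `+`, the rightmost exon end on `-`.
#' @export
gene_model <- function(gene_id, contig, strand, exons,
                       utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"), length(exons) >= 1L)
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  if (length(exons) > 1L &&
      any(start(exons)[-1] <= end(exons)[-length(exons)]))
    stop("exons overlap in gene ", gene_id)
  tss <- if (strand == "+") min(start(exons)) else max(end(exons))
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 tss = tss, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

#' Read gene models from GFF3
#'
#' Expects `gene` rows with `ID=` attributes and `exon`,
#' `five_prime_UTR`/`three_prime_UTR` rows with `Parent=` attributes, the
#' layout [write_gff_genes()] emits.
#'
#' @param path GFF3 path.
#' @return A list of `gene_model` objects, named by gene id.
#' @export
read_gff_genes <- function(path) {
  stopifnot(file.exists(path))
  gff <- fread(path, header = FALSE, sep = "\t", skip = "#",
               col.names = c("contig", "source", "type", "start", "end",
                             "score", "strand", "phase", "attr"))
  attr_field <- function(a, key)
    sub(paste0(".*", key, "=([^;]+).*"), "\\1", a)
  genes <- gff[gff$type == "gene", ]
  parts <- gff[gff$type %in% c("exon", "five_prime_UTR", "three_prime_UTR"), ]
  parts$parent <- attr_field(parts$attr, "Parent")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- attr_field(genes$attr[i], "ID")
    p <- parts[parts$parent == gid, ]
    as_gr <- function(sub) {
      if (nrow(sub) == 0L) return(NULL)
      GRanges(sub$contig, IRanges(sub$start, sub$end))
    }
    gene_model(gid, genes$contig[i], genes$strand[i],
               exons = as_gr(p[p$type == "exon", ]),
               utr5 = as_gr(p[p$type == "five_prime_UTR", ]),
               utr3 = as_gr(p[p$type == "three_prime_UTR", ]))
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

#' Write gene models as GFF3
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff_genes <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(start(m$exons)), max(end(m$exons)))
    lines <- c(lines, sprintf("%s\tdivomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              m$contig, span[1], span[2], m$strand, m$gene_id))
    emit <- function(gr, type) {
      if (is.null(gr) || length(gr) == 0L) return(character(0))
      sprintf("%s\tdivomics\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
              m$contig, type, start(gr), end(gr), m$strand, m$gene_id)
    }
    lines <- c(lines, emit(m$exons, "exon"),
               emit(m$utr5, "five_prime_UTR"), emit(m$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- windows and CpG counting ----------------------------------------------

#' Tile a genome into fixed-width windows
#'
#' Adjacent non-overlapping windows; the last window of each contig is
#' truncated at the contig end.
#'
#' @param genome A `DNAStringSet` (or a named vector of contig lengths).
#' @param window_bp Window width in bp.
#' @return A `GRanges` of windows.
#' @export
tile_windows <- function(genome, window_bp) {
  lens <- if (is.numeric(genome)) genome else
    setNames(Biostrings::width(genome), names(genome))
  tileGenome(lens, tilewidth = window_bp, cut.last.tile.in.chrom = TRUE)
}

#' Locate every CpG dinucleotide in a genome
#' @param genome A `DNAStringSet`.
#' @return `GRanges` of width-2 CG sites.
#' @export
cpg_sites <- function(genome) {
  hits <- vmatchPattern("CG", genome)
  st <- lapply(seq_along(genome), function(i) start(hits[[i]]))
  gr <- GRanges(rep(names(genome), lengths(st)),
                IRanges(unlist(st), width = 2L))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  gr
}

#' Count CpGs fully inside each window
#'
#' The coupling factor (CF) of MeDIP normalization: the number of CG
#' dinucleotides lying entirely within each window.
#'
#' @param windows `GRanges` of windows.
#' @param genome A `DNAStringSet` (or a precomputed `GRanges` from
#'   [cpg_sites()]).
#' @return Integer vector parallel to `windows`.
#' @export
count_cpg <- function(windows, genome) {
  sites <- if (inherits(genome, "GRanges")) genome else cpg_sites(genome)
  hits <- findOverlaps(sites, windows, type = "within", ignore.strand = TRUE)
  tabulate(subjectHits(hits), nbins = length(windows))
}
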