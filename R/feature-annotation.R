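# Single-category genomic feature annotation with deterministic precedence,
# in the style of peak annotators: Promoter > 5'UTR > 3'UTR > Exon >
# Intron > Downstream > Distal Intergenic.

#' Feature categories emitted by [annotate_features()]
#' @export
feature_categories <- c("Promoter", "5' UTR", "3' UTR", "Exon", "Intron",
                        "Downstream", "Distal Intergenic")

#' Annotate positions or intervals with one genomic feature category
#'
#' Intervals are annotated by their midpoint. The promoter is the
#' strand-aware window `[TSS - flank, TSS + flank)`; Downstream is the
#' `downstream_flank` window past the gene's 3' end. Precedence is
#' Promoter > 5' UTR > 3' UTR > Exon > Intron > Downstream > Distal
#' Intergenic; within a category the gene with the nearest TSS wins.
#' `distance_to_tss` is signed along the gene's strand (negative upstream
#' of the TSS).
#'
#' @param query `GRanges` of positions/intervals to annotate.
#' @param gene_models List of `gene_model` objects.
#' @param promoter_flank Promoter half-width in bp (default 3000).
#' @param downstream_flank Downstream window in bp (default 3000).
#' @return `data.table`: `category` (factor over [feature_categories]),
#'   `gene_id` (nearest gene, `NA` if none), `distance_to_tss`.
#' @export
annotate_features <- function(query, gene_models, promoter_flank = 3000L,
                              downstream_flank = 3000L) {
  n <- length(query)
  midp <- GRanges(seqnames(query),
                  IRanges(floor((start(query) + end(query)) / 2), width = 1L))
  if (length(gene_models) == 0L) {
    warning("empty gene model: everything Distal Intergenic")
    return(data.table(category = factor(rep("Distal Intergenic", n),
                                        levels = feature_categories),
                      gene_id = NA_character_,
                      distance_to_tss = NA_real_))
  }
  gdt <- data.table(
    gene_id = vapply(gene_models, `[[`, character(1), "gene_id"),
    contig = vapply(gene_models, `[[`, character(1), "contig"),
    strand = vapply(gene_models, `[[`, character(1), "strand"),
    tss = vapply(gene_models, function(m) as.numeric(m$tss), numeric(1)))
  cat_granges <- function(extract) {
    grs <- lapply(gene_models, extract)
    keep <- !vapply(grs, is.null, logical(1))
    if (!any(keep)) return(GRanges())
    gr <- suppressWarnings(do.call(c, unname(grs[keep])))
    mcols(gr)$gene_id <- rep(gdt$gene_id[keep],
                             vapply(grs[keep], length, integer(1)))
    gr
  }
  promoters <- with(gdt, GRanges(contig, IRanges(pmax(1, tss - promoter_flank),
                                                 tss + promoter_flank - 1)))
  mcols(promoters)$gene_id <- gdt$gene_id
  bodies <- cat_granges(function(m)
    GRanges(m$contig, IRanges(min(start(m$exons)), max(end(m$exons)))))
  exons <- cat_granges(function(m) m$exons)
  utr5 <- cat_granges(function(m) m$utr5)
  utr3 <- cat_granges(function(m) m$utr3)
  downstream <- cat_granges(function(m) {
    lo <- min(start(m$exons)); hi <- max(end(m$exons))
    if (m$strand == "+") GRanges(m$contig, IRanges(hi + 1, hi + downstream_flank))
    else GRanges(m$contig, IRanges(pmax(1, lo - downstream_flank), lo - 1))
  })
  layers <- list(Promoter = promoters, `5' UTR` = utr5, `3' UTR` = utr3,
                 Exon = exons, Intron = bodies, Downstream = downstream)
  category <- rep(NA_character_, n)
  gene_hit <- rep(NA_character_, n)
  tss_of <- setNames(gdt$tss, gdt$gene_id)
  strand_of <- setNames(gdt$strand, gdt$gene_id)
  for (nm in names(layers)) {
    layer <- layers[[nm]]
    if (!length(layer)) next
    hits <- findOverlaps(midp, layer, ignore.strand = TRUE)
    if (!length(hits)) next
    hd <- data.table(q = queryHits(hits),
                     gene = mcols(layer)$gene_id[subjectHits(hits)])
    hd$dist <- abs(start(midp)[hd$q] - tss_of[hd$gene])
    setorder(hd, q, dist)
    hd <- hd[!duplicated(q)]
    todo <- is.na(category[hd$q])
    category[hd$q[todo]] <- nm
    gene_hit[hd$q[todo]] <- hd$gene[todo]
  }
  category[is.na(category)] <- "Distal Intergenic"
  # nearest gene for distal queries: closest TSS on the same contig
  need <- which(is.na(gene_hit))
  if (length(need)) {
    qc <- as.character(seqnames(midp))[need]
    qp <- start(midp)[need]
    for (k in seq_along(need)) {
      cand <- gdt[gdt$contig == qc[k]]
      if (nrow(cand) == 0L) next
      gene_hit[need[k]] <- cand$gene_id[which.min(abs(cand$tss - qp[k]))]
    }
  }
  qp_all <- start(midp)
  dist <- ifelse(is.na(gene_hit), NA_real_,
                 ifelse(strand_of[gene_hit] == "+",
                        qp_all - tss_of[gene_hit],
                        tss_of[gene_hit] - qp_all))
  data.table(category = factor(category, levels = feature_categories),
             gene_id = gene_hit, distance_to_tss = dist)
}
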