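# Cross-omic interval integration: hypergeometric overlap testing, Venn
# cell counts, DMR-in-CNV confounding flags and repeat-class profiles.

#' Hypergeometric overlap test between two interval sets
#'
#' The overlap count is the number of elements of the smaller set
#' intersecting at least one element of the other (any-overlap, >= 1 bp;
#' abutting half-open intervals do not overlap). The p-value is the
#' upper-tail hypergeometric probability
#' `P(X >= n_overlap | universe_n, n_a, n_b)`.
#'
#' @param set_a,set_b `GRanges`.
#' @param universe_n Universe size; when `NULL` it is derived as
#'   genome_length divided by the mean feature width of the union of both
#'   sets (and echoed in the result).
#' @param genome_length Required when `universe_n` is `NULL`.
#' @return List: `n_a`, `n_b`, `n_overlap`, `universe_n`,
#'   `p_hypergeometric`.
#' @export
pairwise_overlap_test <- function(set_a, set_b, universe_n = NULL,
                                  genome_length = NULL) {
  n_a <- length(set_a); n_b <- length(set_b)
  if (is.null(universe_n)) {
    stopifnot(!is.null(genome_length))
    mw <- mean(width(c(set_a, set_b)))
    universe_n <- max(round(genome_length / mw), n_a + n_b)
  }
  if (universe_n < max(n_a, n_b))
    stop("universe_n smaller than a set")
  smaller <- if (n_a <= n_b) set_a else set_b
  other <- if (n_a <= n_b) set_b else set_a
  k <- sum(countOverlaps(smaller, other, ignore.strand = TRUE) > 0L)
  p <- phyper(k - 1, n_a, universe_n - n_a, n_b, lower.tail = FALSE)
  list(n_a = n_a, n_b = n_b, n_overlap = k,
       universe_n = universe_n, p_hypergeometric = min(1, p))
}

#' Venn intersection-pattern counts for 2-4 interval sets
#'
#' Every feature of every set is assigned to exactly one cell: the full
#' pattern of sets it overlaps (any-overlap). A feature overlapping sets
#' A, B and C is counted once, in the ABC cell; cell counts therefore sum
#' to the total number of features across all sets.
#'
#' @param sets Named list of 2-4 `GRanges`.
#' @return `data.table`: `pattern` (set names joined by `&`), `count`.
#' @export
multiway_venn <- function(sets) {
  stopifnot(length(sets) >= 2L, length(sets) <= 4L,
            !is.null(names(sets)))
  nm <- names(sets)
  assign_pattern <- function(i) {
    q <- sets[[i]]
    member <- vapply(seq_along(sets), function(j) {
      if (j == i) rep(TRUE, length(q))
      else countOverlaps(q, sets[[j]], ignore.strand = TRUE) > 0L
    }, logical(length(q)))
    if (length(q) == 1L) member <- matrix(member, nrow = 1L)
    apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  }
  pat <- unlist(lapply(seq_along(sets), assign_pattern))
  all_pat <- unlist(lapply(seq_len(length(sets)), function(k)
    utils::combn(nm, k, paste, collapse = "&")))
  counts <- table(factor(pat, levels = all_pat))
  data.table(pattern = names(counts), count = as.integer(counts))
}

#' Flag DMRs whose span intersects any CNV call
#'
#' CNVs encompassing DMRs may confound a copy-number difference with a
#' methylation difference; flagged DMRs should be interpreted with care.
#'
#' @param dmrs `data.table` with contig/start/end (from [merge_dmrs()]).
#' @param cnvs `data.table` with contig/start/end (from [call_cnvs()]).
#' @return Logical vector parallel to `dmrs` rows.
#' @export
flag_dmr_in_cnv <- function(dmrs, cnvs) {
  if (nrow(dmrs) == 0L) return(logical(0))
  if (nrow(cnvs) == 0L) return(rep(FALSE, nrow(dmrs)))
  d <- GRanges(dmrs$contig, IRanges(dmrs$start, dmrs$end))
  cn <- GRanges(cnvs$contig, IRanges(cnvs$start, cnvs$end))
  countOverlaps(d, cn, ignore.strand = TRUE) > 0L
}

#' Repeat-class overlap profile of a query set
#'
#' Per repeat class, the count and fraction of query features overlapping
#' that class (a query overlapping several classes counts once per class),
#' with fold enrichment against one or more background interval sets
#' profiled the same way.
#'
#' @param queries `GRanges`.
#' @param repeats `GRanges` with a `class` metadata column.
#' @param backgrounds Named list of background `GRanges` (e.g. genome
#'   tiles, the assayed fraction).
#' @return `data.table`: class, n, fraction, then one `fold_<name>` column
#'   per background.
#' @export
repeat_profile <- function(queries, repeats, backgrounds = list()) {
  cls <- mcols(repeats)$class
  if (is.null(cls)) stop("repeats need a 'class' metadata column")
  cls[is.na(cls) | cls == ""] <- "Other"
  classes <- sort(unique(cls))
  frac_for <- function(gr) {
    vapply(classes, function(cc)
      mean(countOverlaps(gr, repeats[cls == cc], ignore.strand = TRUE) > 0L),
      numeric(1))
  }
  fr <- frac_for(queries)
  out <- data.table(class = classes,
                    n = as.integer(round(fr * length(queries))),
                    fraction = fr)
  for (bn in names(backgrounds)) {
    bf <- frac_for(backgrounds[[bn]])
    out[[paste0("fold_", bn)]] <- ifelse(bf > 0, fr / bf, NA_real_)
  }
  out
}
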