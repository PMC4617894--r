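# Enhancer-load pipeline: replicate-reproducible peak regions, fixed-length
# extension, single-nearest-gene assignment within a distance cap, per-gene
# regulatory load and high-regulatory-load (HRL) selection, and expression
# shift testing.
#
# Intervals are data.frames (chrom, start, end), 0-based half-open; BED
# files map onto this directly. GenomicRanges provides the overlap engine.

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Read / write BED interval files
#'
#' Only the first three BED columns are used; coordinates stay 0-based
#' half-open.
#'
#' @param path file path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = d[[1]], start = as.integer(d[[2]]),
             end = as.integer(d[[3]]), stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param regions interval data.frame.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Replicate-reproducible regions
#'
#' Returns the intervals of the first (reference) replicate that overlap by
#' at least one nucleotide with at least one interval in every other
#' replicate. The alternative merged representation (union of all pairwise
#' intersections) is available via \code{mode = "intersect"}.
#'
#' @param replicates list (length >= 2) of interval data.frames.
#' @param mode "reference" (default) or "intersect".
#' @return interval data.frame.
#' @export
reproducible_regions <- function(replicates, mode = c("reference",
                                                      "intersect")) {
  mode <- match.arg(mode)
  stopifnot(length(replicates) >= 2)
  ref <- replicates[[1]]
  gref <- intervals_to_granges(ref)
  keep <- rep(TRUE, nrow(ref))
  for (other in replicates[-1]) {
    hits <- suppressWarnings(
      IRanges::overlapsAny(gref, intervals_to_granges(other)))
    keep <- keep & hits
  }
  out <- ref[keep, , drop = FALSE]
  if (mode == "intersect" && nrow(out)) {
    for (other in replicates[-1]) {
      g <- intervals_to_granges(out)
      go <- intervals_to_granges(other)
      first_hit <- GenomicRanges::findOverlaps(g, go, select = "first")
      out$start <- pmax(out$start, other$start[first_hit])
      out$end <- pmin(out$end, other$end[first_hit])
    }
  }
  rownames(out) <- NULL
  out
}

#' Extend short intervals symmetrically to a target length
#'
#' Intervals shorter than \code{target_length} grow on both sides (the odd
#' base going to the end side); intervals already at or above the target are
#' unchanged. Extensions running past position 0 are clipped by shifting the
#' deficit to the end so the target length is preserved.
#'
#' @param regions interval data.frame.
#' @param target_length target in bp (default 450).
#' @return interval data.frame.
#' @export
extend_to_length <- function(regions, target_length = 450) {
  len <- regions$end - regions$start
  deficit <- pmax(0, target_length - len)
  left <- floor(deficit / 2)
  right <- ceiling(deficit / 2)
  s <- regions$start - left
  e <- regions$end + right
  under <- s < 0
  e[under] <- e[under] - s[under]
  s[under] <- 0
  out <- regions
  out$start <- as.integer(s)
  out$end <- as.integer(e)
  out
}

#' Assign each region to its single nearest gene within a distance cap
#'
#' Distance is measured from the region midpoint to the TSS; regions whose
#' nearest TSS is farther than \code{max_distance} stay unassigned (NA).
#' Equidistant TSSs are broken deterministically by lexicographic gene id,
#' with a warning.
#'
#' @param regions interval data.frame.
#' @param tss data.frame with \code{gene_id}, \code{chrom}, \code{tss} (bp),
#'   \code{strand}.
#' @param max_distance cap in bp (default 500 kb).
#' @return \code{regions} with added columns \code{gene} and \code{distance}.
#' @export
assign_nearest_gene <- function(regions, tss, max_distance = 5e5) {
  mid <- floor((regions$start + regions$end) / 2)
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  tied <- 0L
  for (i in seq_len(nrow(regions))) {
    cand <- tss[tss$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- abs(cand$tss - mid[i])
    dmin <- min(d)
    if (dmin > max_distance) next
    hits <- cand$gene_id[d == dmin]
    if (length(hits) > 1) {
      tied <- tied + 1L
      hits <- sort(hits)
    }
    gene[i] <- hits[1]
    dist[i] <- dmin
  }
  if (tied > 0)
    warning(sprintf("%d region(s) equidistant to multiple TSSs; ties broken by gene id", tied))
  out <- regions
  out$gene <- gene
  out$distance <- dist
  out
}

#' Per-gene regulatory load table
#'
#' Counts assigned regions per gene (unassigned regions are ignored) and
#' ranks genes by descending count with average ranks for ties.
#'
#' @param assignments data.frame from [assign_nearest_gene()].
#' @return data.frame with \code{gene}, \code{count}, \code{rank}, sorted by
#'   descending count.
#' @export
regulatory_load <- function(assignments) {
  g <- assignments$gene[!is.na(assignments$gene)]
  tab <- table(g)
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$count, ties.method = "average")
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select high-regulatory-load genes
#'
#' A gene is HRL when it sits in the top \code{top_fraction} of genes by
#' enhancer count (ties at the boundary included) AND has at least
#' \code{min_count} enhancers.
#'
#' @param table data.frame from [regulatory_load()].
#' @param top_fraction fraction of genes forming the top stratum (default
#'   0.10).
#' @param min_count minimal enhancer count (default 7).
#' @return character vector of HRL gene ids.
#' @export
select_hrl <- function(table, top_fraction = 0.10, min_count = 7) {
  stopifnot(nrow(table) > 0)
  counts <- sort(table$count, decreasing = TRUE)
  k <- max(1L, ceiling(top_fraction * nrow(table)))
  cutoff <- counts[k]
  table$gene[table$count >= max(cutoff, min_count)]
}

#' Expression shift between HRL and other genes
#'
#' Two-sample Kolmogorov-Smirnov comparison of expression-level
#' distributions.
#'
#' @param hrl_expr,other_expr numeric expression vectors (non-empty).
#' @return list with \code{D} and \code{p}.
#' @export
expression_shift <- function(hrl_expr, other_expr) {
  stopifnot(length(hrl_expr) > 0, length(other_expr) > 0)
  ks <- suppressWarnings(stats::ks.test(hrl_expr, other_expr))
  list(D = unname(ks$statistic), p = ks$p.value)
}
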