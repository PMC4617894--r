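# Barcode-style expression discretization: z-scores measured against a
# platform-wide unexpressed reference are collapsed to trinary scores,
# summarized across arrays (ubiquity) and called by consensus.

#' Discretize z-scores into trinary expression calls
#'
#' A z-score at or below 0 (the mean of the unexpressed reference
#' distribution) scores -1 (inactive); a z-score strictly above 5 (the
#' benchmarked expression threshold) scores +1 (expressed); anything in
#' between, including exactly 5, is undetermined and scores 0.
#'
#' @param z numeric vector or matrix of z-scores. NA/NaN entries raise an
#'   error unless \code{na_drop = TRUE}, in which case the offending genes
#'   (rows) are dropped with a warning.
#' @param na_drop drop rows containing missing values instead of erroring.
#' @return trinary scores in {-1, 0, 1}, same shape as \code{z}.
#' @export
discretize <- function(z, na_drop = FALSE) {
  if (any(!is.finite(z))) {
    if (!na_drop || is.null(dim(z)))
      stop("non-finite z-score encountered", call. = FALSE)
    bad <- apply(z, 1, function(r) any(!is.finite(r)))
    warning(sprintf("dropping %d gene(s) with missing z-scores", sum(bad)))
    z <- z[!bad, , drop = FALSE]
  }
  s <- ifelse(z <= 0, -1, ifelse(z > 5, 1, 0))
  if (!is.null(dim(z))) dimnames(s) <- dimnames(z)
  s
}

#' z-score of an intensity against an unexpressed reference
#'
#' @param intensity normalized probe/gene intensity.
#' @param ref_mean,ref_sd mean and standard deviation of the same probe in
#'   the unexpressed reference context; \code{ref_sd} must be positive.
#' @return number of standard deviations above the unexpressed mean.
#' @export
zscore_from_reference <- function(intensity, ref_mean, ref_sd) {
  if (any(ref_sd <= 0))
    stop("ref_sd must be positive", call. = FALSE)
  (intensity - ref_mean) / ref_sd
}

#' Ubiquity of expression
#'
#' Sum of a gene's trinary discretization scores over all arrays; bounded by
#' plus/minus the number of arrays and measuring expression breadth.
#'
#' @param scores vector of trinary scores in {-1, 0, 1}.
#' @return integer sum (0 for an empty vector).
#' @export
ubiquity <- function(scores) {
  stopifnot(all(scores %in% c(-1, 0, 1)))
  sum(scores)
}

#' Consensus trinary call across samples
#'
#' Returns +1 when the share of +1 scores reaches \code{active_fraction}
#' (e.g. 3 of 4 donors at 0.75, or >= 90 % of arrays at 0.9), -1 when the
#' share of -1 scores reaches \code{inactive_fraction}, and 0 otherwise.
#'
#' @param scores vector of trinary scores for one gene (or reaction) across
#'   samples.
#' @param active_fraction,inactive_fraction proportions in (0, 1].
#' @return single consensus score in {-1, 0, 1} (0 for an empty vector).
#' @export
consensus <- function(scores, active_fraction = 0.9,
                      inactive_fraction = active_fraction) {
  stopifnot(active_fraction > 0, active_fraction <= 1,
            inactive_fraction > 0, inactive_fraction <= 1,
            all(scores %in% c(-1, 0, 1)))
  n <- length(scores)
  if (n == 0) return(0)
  if (sum(scores == 1) / n >= active_fraction) return(1)
  if (sum(scores == -1) / n >= inactive_fraction) return(-1)
  0
}

#' Per-gene consensus over a score matrix
#'
#' @param score_matrix genes x samples trinary matrix.
#' @param active_fraction,inactive_fraction passed to [consensus()].
#' @return named vector of consensus scores per gene.
#' @export
consensus_scores <- function(score_matrix, active_fraction = 0.9,
                             inactive_fraction = active_fraction) {
  apply(score_matrix, 1, consensus, active_fraction = active_fraction,
        inactive_fraction = inactive_fraction)
}

#' Collapse probe-level z-scores to gene level
#'
#' Takes the maximum z across a gene's probes (favoring detection).
#'
#' @param z probes x samples matrix.
#' @param probe_gene named character vector mapping probe id to gene id.
#' @return genes x samples matrix of collapsed z-scores.
#' @export
collapse_probes <- function(z, probe_gene) {
  genes <- unique(probe_gene[rownames(z)])
  out <- matrix(NA_real_, length(genes), ncol(z),
                dimnames = list(genes, colnames(z)))
  for (g in genes) {
    rows <- rownames(z)[probe_gene[rownames(z)] == g]
    out[g, ] <- apply(z[rows, , drop = FALSE], 2, max)
  }
  out
}
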