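# Comparative and statistical analyses over context models.

#' Pairwise Jaccard similarity of retained-reaction sets
#'
#' J(A, B) = |A intersect B| / |A union B|. Also returns an average-linkage
#' hierarchical clustering order on 1 - J.
#'
#' @param models named list of \code{context_model}s (or of character vectors
#'   of retained reaction ids).
#' @return list with \code{matrix} (symmetric, unit diagonal) and
#'   \code{order} (clustering leaf order; NULL for fewer than 3 models).
#' @export
jaccard_matrix <- function(models) {
  sets <- lapply(models, function(m)
    if (inherits(m, "context_model")) m$retained else m)
  k <- length(sets)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("model", seq_len(k))
  J <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    u <- length(union(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- if (u == 0) 1 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  ord <- NULL
  if (k >= 3) {
    hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
    ord <- hc$order
  }
  list(matrix = J, order = ord)
}

#' Per-subsystem activity of a context model
#'
#' Fraction of each parent subsystem's reactions retained in the context
#' model.
#'
#' @param context a \code{context_model}.
#' @param parent the parent \code{metabolic_model}.
#' @param min_reactions subsystems with fewer parent reactions are dropped
#'   (default 1; the comparative heat maps use 4).
#' @return data.frame with \code{subsystem}, \code{n_parent}, \code{n_retained},
#'   \code{fraction}.
#' @export
pathway_activity <- function(context, parent, min_reactions = 1) {
  sub <- parent$reactions$subsystem
  keep <- sub != ""
  tab <- table(sub[keep])
  retained <- parent$reactions$id %in% context$retained
  rtab <- table(sub[keep & retained])
  out <- data.frame(subsystem = names(tab),
                    n_parent = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$n_retained <- as.integer(rtab[out$subsystem])
  out$n_retained[is.na(out$n_retained)] <- 0L
  out <- out[out$n_parent >= min_reactions, , drop = FALSE]
  out$fraction <- out$n_retained / out$n_parent
  rownames(out) <- NULL
  out
}

#' Per-subsystem regulation score
#'
#' (number of up-regulated reactions - number of down-regulated reactions)
#' divided by the subsystem size; bounded in [-1, 1].
#'
#' @param context a \code{context_model} (defines the reaction universe via
#'   its parent reactions).
#' @param parent the parent \code{metabolic_model}.
#' @param up,down character vectors of up-/down-regulated reaction ids
#'   (typically from [propagate_de_labels()]).
#' @param min_reactions drop smaller subsystems (default 1).
#' @return data.frame with \code{subsystem}, \code{n}, \code{score}.
#' @export
pathway_regulation <- function(context, parent, up, down,
                               min_reactions = 1) {
  sub <- parent$reactions$subsystem
  ids <- parent$reactions$id
  keep <- sub != ""
  out <- lapply(unique(sub[keep]), function(s) {
    members <- ids[sub == s]
    n <- length(members)
    if (n < min_reactions) return(NULL)
    data.frame(subsystem = s, n = n,
               score = (length(intersect(up, members)) -
                        length(intersect(down, members))) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank conditions by a gene's expression
#'
#' Replicate arrays are averaged per condition, then for each gene the
#' conditions are ranked from highest (rank 1) to lowest expression with
#' average ranks for ties.
#'
#' @param expr genes x samples expression matrix.
#' @param sample_conditions character vector (length = ncol(expr)) mapping
#'   each sample to its condition.
#' @return genes x conditions matrix of ranks.
#' @export
condition_rank <- function(expr, sample_conditions) {
  stopifnot(ncol(expr) == length(sample_conditions))
  conds <- unique(sample_conditions)
  agg <- sapply(conds, function(cc)
    rowMeans(expr[, sample_conditions == cc, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(rownames(expr), conds))
  ranks <- t(apply(agg, 1, function(v) rank(-v, ties.method = "average")))
  if (nrow(expr) == 1) {
    ranks <- matrix(ranks, nrow = 1, dimnames = list(rownames(expr), conds))
  }
  colnames(ranks) <- conds
  ranks
}

#' In silico single-gene knockouts with FBA
#'
#' For each gene, every reaction whose GPR rule evaluates to FALSE with that
#' gene deleted (AND loses the complex, OR survives on isozymes) is silenced,
#' and growth is re-optimized. A gene is essential when the growth decrease
#' exceeds \code{threshold} (default 1 %) of the wild-type optimum.
#'
#' @param model a \code{metabolic_model} with a feasible biomass reaction.
#' @param biomass biomass reaction id (default \code{model$objective}).
#' @param genes genes to test (default: all model genes).
#' @param threshold essentiality cutoff as a fraction of wild-type growth.
#' @return data.frame with \code{gene}, \code{wt_growth}, \code{ko_growth},
#'   \code{decrease} (fraction) and \code{essential}.
#' @export
gene_knockouts <- function(model, biomass = model$objective,
                           genes = model_genes(model), threshold = 0.01) {
  wt <- maximize_flux(model, biomass)$objective
  if (wt <= 0)
    stop("wild-type growth is zero; knockout screen is meaningless",
         call. = FALSE)
  rows <- lapply(genes, function(g) {
    off <- vapply(seq_along(model$gpr_rules), function(j) {
      rule <- model$gpr_rules[[j]]
      !is.null(rule) && !evaluate_gpr_boolean(rule, g)
    }, logical(1))
    ko <- if (any(off)) {
      m2 <- zero_reactions(model, reaction_ids(model)[off])
      tryCatch(maximize_flux(m2, biomass)$objective, error = function(e) 0)
    } else wt
    dec <- (wt - ko) / wt
    data.frame(gene = g, wt_growth = wt, ko_growth = ko, decrease = dec,
               essential = dec > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-based enrichment of a gene set (KS + permutation null)
#'
#' Compares the ranks of a member set against the remaining ranks with a
#' two-sample Kolmogorov-Smirnov test and, in addition, estimates an
#' empirical p-value as the fraction of \code{n_null} random same-size sets
#' drawn from the pooled ranks achieving a KS statistic at least as large.
#'
#' @param member_ranks,other_ranks numeric rank vectors from a common list.
#' @param n_null number of random sets (default 1e4; 1e6 reproduces the
#'   full-scale analysis but is slow).
#' @param set_size size of random sets (default: length of
#'   \code{member_ranks}).
#' @param seed integer seed for reproducibility.
#' @return list with \code{D}, \code{p_ks}, \code{p_perm}.
#' @export
rank_set_enrichment <- function(member_ranks, other_ranks, n_null = 1e4,
                                set_size = length(member_ranks), seed = 1L) {
  ks <- suppressWarnings(stats::ks.test(member_ranks, other_ranks))
  pool <- c(member_ranks, other_ranks)
  set.seed(seed)
  npool <- length(pool)
  dnull <- vapply(seq_len(n_null), function(i) {
    idx <- sample.int(npool, set_size)
    suppressWarnings(stats::ks.test(pool[idx], pool[-idx])$statistic)
  }, numeric(1))
  # the observed statistic belongs to the null's support; a strict floating
  # point comparison at that atom would bias the estimate downwards
  list(D = unname(ks$statistic), p_ks = ks$p.value,
       p_perm = mean(dnull >= unname(ks$statistic) - 1e-9))
}

#' Hypergeometric upper-tail enrichment probability
#'
#' P(X >= k) for X ~ Hypergeometric(N population, K successes, n draws).
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n number of draws.
#' @param k observed successes.
#' @return upper-tail probability.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(K, n))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
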