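# Deterministic fixture generators: toy metabolic networks with known ground
# truth, synthetic discretized-expression tables, and synthetic enhancer peak
# sets with planted per-gene loads. Every stage of the pipeline is testable
# from these without any external download.

#' The canonical two-compartment toy network (TOY1)
#'
#' Nine reactions over seven metabolites in two compartments:
#' exchange \code{R_EXA} for extracellular A, transporter \code{R_TA}
#' (A moves e -> c), chain \code{R1} (A -> B) and \code{R2} (B -> C) in
#' subsystem PathX, branch \code{R3} (B -> D) in PathY, demands \code{R_EXC}
#' and \code{R_EXD}, and a planted dead-end pair \code{R4}, \code{R4b}
#' (E -> F -> C with E never produced, hence both blocked).
#'
#' Ground truth is attached as attribute \code{"truth"}: the blocked set,
#' the transporter set, and the unique minimal support of core \code{R2}.
#'
#' @param uptake_cap maximal uptake rate of A (default 10).
#' @return a \code{metabolic_model} with a \code{"truth"} attribute.
#' @export
make_toy_model <- function(uptake_cap = 10) {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "C_c", "D_c", "E_c", "F_c"),
    species = c("A", "A", "B", "C", "D", "E", "F"),
    compartment = c("e", "c", "c", "c", "c", "c", "c"),
    stringsAsFactors = FALSE)
  rxns <- list(
    R_EXA = list(mets = c(A_e = -1), lb = -uptake_cap, ub = 1000,
                 subsystem = "Exchange"),
    R_TA  = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
                 gpr = "GT", subsystem = "Transport"),
    R1    = list(mets = c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
                 gpr = "G1", subsystem = "PathX"),
    R2    = list(mets = c(B_c = -1, C_c = 1), lb = 0, ub = 1000,
                 gpr = "G2", subsystem = "PathX"),
    R3    = list(mets = c(B_c = -1, D_c = 1), lb = 0, ub = 1000,
                 gpr = "G3", subsystem = "PathY"),
    R_EXC = list(mets = c(C_c = -1), lb = 0, ub = 1000,
                 subsystem = "Exchange"),
    R_EXD = list(mets = c(D_c = -1), lb = 0, ub = 1000,
                 subsystem = "Exchange"),
    R4    = list(mets = c(E_c = -1, F_c = 1), lb = 0, ub = 1000,
                 gpr = "G4", subsystem = "PathZ"),
    R4b   = list(mets = c(F_c = -1, C_c = 1), lb = 0, ub = 1000,
                 gpr = "G4", subsystem = "PathZ"))
  m <- build_model(mets, rxns, id = "TOY1")
  attr(m, "truth") <- list(
    blocked = c("R4", "R4b"),
    transporters = "R_TA",
    min_support_R2 = c("R_EXA", "R_TA", "R1", "R2", "R_EXC"))
  m
}

#' Randomized small fixture model with known blocked set
#'
#' Builds \code{n_pathways} independent linear pathways, each consisting of
#' an exchange reaction, a transporter into the cytosol and a chain of
#' conversions ending in a demand, then appends \code{n_blocked} dead-end
#' reactions consuming metabolites that are never produced. Some chain
#' reactions are made reversible at random. Reaction order is shuffled so
#' order-independence is exercised.
#'
#' @param seed integer seed (drives all randomness).
#' @param n_pathways number of parallel pathways (default 2).
#' @param chain_len reactions per chain (default 2).
#' @param n_blocked planted dead-end reactions (default 2).
#' @return a \code{metabolic_model}; attribute \code{"truth"} holds the
#'   planted blocked set, transporter set and the per-pathway reaction lists.
#' @export
make_random_model <- function(seed, n_pathways = 2, chain_len = 2,
                              n_blocked = 2) {
  set.seed(seed)
  mets <- list()
  rxns <- list()
  pathway_rxns <- list()
  for (p in seq_len(n_pathways)) {
    pv <- character(0)
    sp0 <- sprintf("P%dM0", p)
    mets[[length(mets) + 1]] <- data.frame(
      id = paste0(sp0, "_e"), species = sp0, compartment = "e")
    mets[[length(mets) + 1]] <- data.frame(
      id = paste0(sp0, "_c"), species = sp0, compartment = "c")
    ex <- sprintf("EX_P%d", p)
    tr <- sprintf("T_P%d", p)
    rxns[[ex]] <- list(mets = stats::setNames(-1, paste0(sp0, "_e")),
                       lb = -1000, ub = 1000, subsystem = "Exchange")
    rxns[[tr]] <- list(mets = stats::setNames(c(-1, 1),
                                              paste0(sp0, c("_e", "_c"))),
                       lb = 0, ub = 1000, gpr = sprintf("G_T%d", p),
                       subsystem = "Transport")
    pv <- c(pv, ex, tr)
    prev <- paste0(sp0, "_c")
    for (k in seq_len(chain_len)) {
      spk <- sprintf("P%dM%d", p, k)
      mets[[length(mets) + 1]] <- data.frame(
        id = paste0(spk, "_c"), species = spk, compartment = "c")
      rid <- sprintf("R_P%d_%d", p, k)
      rev <- stats::runif(1) < 0.3
      rxns[[rid]] <- list(
        mets = stats::setNames(c(-1, 1), c(prev, paste0(spk, "_c"))),
        lb = if (rev) -1000 else 0, ub = 1000,
        gpr = sprintf("G_P%d_%d", p, k), subsystem = sprintf("Path%d", p))
      pv <- c(pv, rid)
      prev <- paste0(spk, "_c")
    }
    dm <- sprintf("DM_P%d", p)
    rxns[[dm]] <- list(mets = stats::setNames(-1, prev), lb = 0, ub = 1000,
                       subsystem = "Exchange")
    pv <- c(pv, dm)
    pathway_rxns[[p]] <- pv
  }
  blocked <- character(0)
  for (b in seq_len(n_blocked)) {
    bx <- sprintf("XDead%d", b)
    by <- sprintf("YDead%d", b)
    mets[[length(mets) + 1]] <- data.frame(id = paste0(bx, "_c"),
                                           species = bx, compartment = "c")
    mets[[length(mets) + 1]] <- data.frame(id = paste0(by, "_c"),
                                           species = by, compartment = "c")
    rid <- sprintf("RB_%d", b)
    rxns[[rid]] <- list(
      mets = stats::setNames(c(-1, 1), paste0(c(bx, by), "_c")),
      lb = 0, ub = 1000, gpr = sprintf("G_B%d", b),
      subsystem = "PathDead")
    blocked <- c(blocked, rid)
  }
  metdf <- do.call(rbind, mets)
  ord <- sample(seq_along(rxns))
  rxns <- rxns[ord]
  m <- build_model(metdf, rxns, id = sprintf("RAND%d", seed))
  attr(m, "truth") <- list(
    blocked = blocked,
    transporters = grep("^T_P", names(rxns), value = TRUE),
    pathways = pathway_rxns)
  m
}

#' Simulate a discretized expression table for a fixture model
#'
#' Genes controlling the reactions of the chosen active pathways draw
#' z-scores from the "expressed" distribution N(8, 1) (mass almost entirely
#' above the +1 threshold of 5); all other genes draw from the "unexpressed"
#' distribution N(-1, 1) (mass mostly below the 0 threshold). These defaults
#' straddle the discretization thresholds with known tail mass.
#'
#' @param model a fixture \code{metabolic_model}.
#' @param active_reactions reaction ids whose genes are expressed.
#' @param n_samples number of arrays/donors (default 4).
#' @param seed integer seed.
#' @param active_mean,active_sd,inactive_mean,inactive_sd z distributions.
#' @return list with matrices \code{z} and \code{score} (genes x samples).
#' @export
simulate_expression <- function(model, active_reactions, n_samples = 4,
                                seed = 1, active_mean = 8, active_sd = 1,
                                inactive_mean = -1, inactive_sd = 1) {
  set.seed(seed)
  genes <- model_genes(model)
  active_genes <- unique(unlist(
    lapply(rxn_index(model, active_reactions),
           function(j) gpr_genes(model$gpr_rules[[j]]))))
  z <- matrix(NA_real_, length(genes), n_samples,
              dimnames = list(genes, paste0("S", seq_len(n_samples))))
  for (g in genes) {
    if (g %in% active_genes)
      z[g, ] <- stats::rnorm(n_samples, active_mean, active_sd)
    else
      z[g, ] <- stats::rnorm(n_samples, inactive_mean, inactive_sd)
  }
  list(z = z, score = discretize(z))
}

#' Simulate replicate enhancer peak sets with planted per-gene loads
#'
#' Genes are placed 1 Mb apart along one chromosome; gene \code{i} receives
#' \code{loads[i]} enhancer regions of \code{region_length} bp within a few
#' hundred kb of its TSS, so single-nearest-gene assignment within 500 kb is
#' unambiguous. Each replicate jitters every region by at most \code{jitter}
#' bp; with \code{jitter < region_length} the replicate-reproducible set
#' recovers the planted counts exactly.
#'
#' @param loads integer vector of planted enhancer counts (one per gene).
#' @param n_replicates number of biological replicates (default 3).
#' @param jitter maximal per-replicate coordinate shift in bp (default 10).
#' @param region_length peak length in bp before extension (default 200).
#' @param seed integer seed.
#' @param drop list of \code{c(replicate, gene, region)} triples to delete,
#'   for constructing irreproducible-region cases.
#' @return list with \code{replicates} (list of data.frames with chrom,
#'   start, end; 0-based half-open) and \code{tss} (gene_id, chrom, tss,
#'   strand).
#' @export
simulate_peaks <- function(loads, n_replicates = 3, jitter = 10,
                           region_length = 200, seed = 1, drop = NULL) {
  set.seed(seed)
  n_genes <- length(loads)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  tss_pos <- 5e5 + (seq_len(n_genes) - 1) * 1e6
  base <- list()
  for (i in seq_len(n_genes)) {
    if (loads[i] < 1) next
    starts <- tss_pos[i] + 2000 * seq_len(loads[i])
    base[[i]] <- data.frame(chrom = "chr1", start = starts,
                            end = starts + region_length, gene = genes[i],
                            region = seq_len(loads[i]),
                            stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, base)
  reps <- lapply(seq_len(n_replicates), function(r) {
    off <- sample(seq(-jitter, jitter), nrow(base), replace = TRUE)
    d <- data.frame(chrom = base$chrom, start = base$start + off,
                    end = base$end + off, stringsAsFactors = FALSE)
    if (!is.null(drop)) {
      for (dd in drop) {
        if (dd[1] == r) {
          hit <- which(base$gene == genes[dd[2]] & base$region == dd[3])
          if (length(hit)) d <- d[-hit, , drop = FALSE]
        }
      }
    }
    d
  })
  list(replicates = reps,
       tss = data.frame(gene_id = genes, chrom = "chr1", tss = tss_pos,
                        strand = "+", stringsAsFactors = FALSE))
}
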