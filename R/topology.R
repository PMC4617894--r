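# Network-position analysis: transporter classification, FVA-based flux
# directions, pathway entry-point calls with cofactor filtering, and
# hypergeometric positional enrichment of high-regulatory-load reactions.

#' Default cofactor filtering configuration
#'
#' The canonical cofactor couples (each treated as a pair that is dropped
#' when both members sit on opposite sides of a reaction), the inorganic /
#' ubiquitous metabolites that are always ignored, and CO2. The acetyl-CoA
#' rule treats acetyl-CoA as a cofactor only when it acts as the CoA donor,
#' i.e. when CoA appears on the opposite side. All lists are
#' compartment-stripped species identifiers and fully overridable.
#'
#' @param pairs list of 2-element character vectors (cofactor couples).
#' @param inorganic character vector of species always dropped.
#' @param co2 species identifiers treated as CO2.
#' @param acetyl_coa_rule apply the CoA-donor special case (default TRUE).
#' @return object of class \code{cofactor_config}.
#' @export
cofactor_config <- function(pairs = list(c("atp", "adp"), c("atp", "amp"),
                                         c("gtp", "gdp"), c("utp", "udp"),
                                         c("ctp", "cdp"),
                                         c("nad", "nadh"),
                                         c("nadp", "nadph"),
                                         c("fad", "fadh2"),
                                         c("accoa", "coa")),
                            inorganic = c("h", "h2o", "pi", "ppi", "o2",
                                          "na1", "k", "cl", "ca2", "mg2",
                                          "fe2", "fe3", "zn2", "so4", "nh4"),
                            co2 = c("co2", "hco3"),
                            acetyl_coa_rule = TRUE) {
  structure(list(pairs = pairs, inorganic = inorganic, co2 = co2,
                 acetyl_coa_rule = acetyl_coa_rule),
            class = "cofactor_config")
}

#' Classify transport reactions
#'
#' A reaction is a transporter iff at least one chemical species (matched by
#' its compartment-stripped identifier) appears as substrate in one
#' compartment and as product in a different one.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of transporter reaction ids.
#' @export
classify_transporters <- function(model) {
  sp <- model$metabolites$species
  cp <- model$metabolites$compartment
  out <- vapply(seq_len(n_reactions(model)), function(j) {
    col <- model$S[, j]
    cons <- which(col < 0)
    prod <- which(col > 0)
    if (!length(cons) || !length(prod)) return(FALSE)
    for (i in cons) {
      hit <- prod[sp[prod] == sp[i] & cp[prod] != cp[i]]
      if (length(hit)) return(TRUE)
    }
    FALSE
  }, logical(1))
  reaction_ids(model)[out]
}

#' Feasible flux direction per reaction
#'
#' Uses [fva()]: forward if only a positive flux of magnitude >= eps is
#' attainable, backward if only negative, both if both, blocked otherwise.
#' Bounds alone understate this: neighbouring irreversibilities constrain the
#' attainable direction as well, which the LP captures.
#'
#' @param model a \code{metabolic_model}.
#' @param policy an [epsilon_policy()].
#' @return named character vector in {"forward", "backward", "both",
#'   "blocked"}.
#' @export
flux_directions <- function(model, policy = epsilon_policy()) {
  r <- fva(model)
  fwd <- r$vmax >= policy$eps
  bwd <- r$vmin <= -policy$eps
  dir <- ifelse(fwd & bwd, "both",
                ifelse(fwd, "forward", ifelse(bwd, "backward", "blocked")))
  stats::setNames(dir, r$reaction)
}

# metabolites consumed / produced by reaction j under one orientation
orient_mets <- function(model, j, orientation) {
  col <- model$S[, j]
  if (orientation == "forward")
    list(consumed = which(col < 0), produced = which(col > 0))
  else
    list(consumed = which(col > 0), produced = which(col < 0))
}

# indices of non-cofactor consumed metabolites for reaction j, orientation o
filter_cofactors <- function(model, j, orientation, cof) {
  om <- orient_mets(model, j, orientation)
  sp <- tolower(model$metabolites$species)
  drop <- sp[om$consumed] %in% tolower(c(cof$inorganic, cof$co2))
  consumed <- om$consumed[!drop]
  prod_sp <- sp[om$produced]
  keep <- logical(length(consumed))
  for (k in seq_along(consumed)) {
    s <- sp[consumed[k]]
    is_pair <- FALSE
    for (p in cof$pairs) {
      p <- tolower(p)
      if (s == p[1] && p[2] %in% prod_sp) is_pair <- TRUE
      if (s == p[2] && p[1] %in% prod_sp) is_pair <- TRUE
    }
    if (!cof$acetyl_coa_rule && s == "accoa") is_pair <- FALSE
    # same-formula couples: consumed and produced metabolite with identical
    # non-missing formula annotation do not change and are filtered
    f <- model$metabolites$formula[consumed[k]]
    if (!is.na(f) && any(!is.na(model$metabolites$formula[om$produced]) &
                         model$metabolites$formula[om$produced] == f &
                         sp[om$produced] != s))
      is_pair <- TRUE
    keep[k] <- !is_pair
  }
  consumed[keep]
}

feasible_orientations <- function(dir) {
  switch(dir,
         forward = "forward",
         backward = "backward",
         both = c("forward", "backward"),
         character(0))
}

# reactions producing metabolite index mi under their feasible directions
producers_of <- function(model, mi, dirs, exclude = character(0)) {
  ids <- reaction_ids(model)
  out <- character(0)
  for (j in seq_along(ids)) {
    if (ids[j] %in% exclude) next
    co <- model$S[mi, j]
    if (co == 0) next
    d <- dirs[ids[j]]
    if ((co > 0 && d %in% c("forward", "both")) ||
        (co < 0 && d %in% c("backward", "both")))
      out <- c(out, ids[j])
  }
  out
}

# for a transporter, the compartment(s) the transported species comes from
# when producing metabolite index mi
transporter_origin <- function(model, j, mi, orientation) {
  om <- orient_mets(model, j, orientation)
  sp <- model$metabolites$species
  tr_sp <- sp[mi]
  origin <- om$consumed[sp[om$consumed] == tr_sp]
  model$metabolites$compartment[origin]
}

#' Classify pathway entry points
#'
#' For every gene-associated, non-transporter reaction able to carry flux,
#' traces (per feasible flux direction) where its non-cofactor consumed
#' metabolites come from. A producer from a different subsystem that is not
#' a transporter makes the reaction an entry point after a pathway change; a
#' transporter producer is traced to the origin compartment, where producers
#' of the transported species in the reaction's own subsystem indicate a
#' compartment change and producers from other subsystems a pathway change.
#' Reactions whose metabolites are all cofactors are not considered.
#'
#' @param model a flux-consistent \code{metabolic_model} with subsystem
#'   annotation.
#' @param cofactors a [cofactor_config()], or NULL to disable filtering.
#' @param policy an [epsilon_policy()].
#' @param directions optional precomputed [flux_directions()].
#' @return data.frame with columns \code{reaction}, \code{class} (one of
#'   "transporter", "entry_pathway_change", "entry_compartment_change",
#'   "internal"), \code{direction}, \code{considered} (FALSE for
#'   cofactor-only or blocked reactions).
#' @export
find_entry_points <- function(model, cofactors = cofactor_config(),
                              policy = epsilon_policy(),
                              directions = NULL) {
  if (is.null(cofactors))
    cofactors <- cofactor_config(pairs = list(), inorganic = character(0),
                                 co2 = character(0),
                                 acetyl_coa_rule = FALSE)
  dirs <- if (is.null(directions)) flux_directions(model, policy) else directions
  trans <- classify_transporters(model)
  ga <- gene_associated_reactions(model)
  ids <- reaction_ids(model)
  subsys <- stats::setNames(model$reactions$subsystem, ids)
  no_subsys <- ga[subsys[ga] == ""]
  if (length(no_subsys))
    warning(sprintf("skipping reaction(s) without subsystem annotation: %s",
                    paste(no_subsys, collapse = ", ")))
  rows <- lapply(ga, function(r) {
    j <- rxn_index(model, r)
    d <- dirs[r]
    if (r %in% trans)
      return(data.frame(reaction = r, class = "transporter", direction = d,
                        considered = TRUE, stringsAsFactors = FALSE))
    if (d == "blocked" || subsys[r] == "")
      return(data.frame(reaction = r, class = "internal", direction = d,
                        considered = FALSE, stringsAsFactors = FALSE))
    classes <- character(0)
    any_considered <- FALSE
    for (o in feasible_orientations(d)) {
      mets <- filter_cofactors(model, j, o, cofactors)
      if (!length(mets)) next
      any_considered <- TRUE
      for (mi in mets) {
        prods <- producers_of(model, mi, dirs, exclude = r)
        for (p in prods) {
          if (p %in% trans) {
            oc <- unique(unlist(lapply(feasible_orientations(dirs[p]),
                                       function(po) {
              om <- orient_mets(model, rxn_index(model, p), po)
              if (!(mi %in% om$produced)) return(character(0))
              transporter_origin(model, rxn_index(model, p), mi, po)
            })))
            if (!length(oc)) next
            sp_tr <- model$metabolites$species[mi]
            origin_idx <- which(model$metabolites$species == sp_tr &
                                model$metabolites$compartment %in% oc)
            op <- unique(unlist(lapply(origin_idx, producers_of,
                                       model = model, dirs = dirs,
                                       exclude = c(r, p))))
            op_sub <- subsys[op]
            if (any(op_sub != subsys[r]))
              classes <- c(classes, "entry_pathway_change")
            if (any(op_sub == subsys[r]))
              classes <- c(classes, "entry_compartment_change")
            if (!length(op))  # transported from the boundary
              classes <- c(classes, "entry_pathway_change")
          } else if (subsys[p] != subsys[r]) {
            classes <- c(classes, "entry_pathway_change")
          }
        }
      }
    }
    cls <- if ("entry_pathway_change" %in% classes) "entry_pathway_change"
           else if ("entry_compartment_change" %in% classes) "entry_compartment_change"
           else "internal"
    data.frame(reaction = r, class = cls, direction = d,
               considered = any_considered, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Positional enrichment of high-regulatory-load reactions
#'
#' Builds the hypergeometric counts (N population, K successes in the
#' population, n draws, k observed successes) for one of three tests:
#' \describe{
#'   \item{transporters}{population = gene-associated reactions; successes =
#'     transporters; draws = HRL reactions.}
#'   \item{entry_points_excluding_transporters}{population excludes
#'     transporters; successes = entry points; draws = HRL reactions in the
#'     population.}
#'   \item{combined}{successes = transporters or entry points; draws = HRL
#'     reactions.}
#' }
#'
#' @param annotation data.frame from [find_entry_points()].
#' @param hrl_reactions character vector of reactions controlled by
#'   high-regulatory-load genes (subset of the annotated reactions).
#' @param mode one of "transporters",
#'   "entry_points_excluding_transporters", "combined".
#' @return list with N, K, n, k and the upper-tail probability \code{p}.
#' @export
positional_enrichment <- function(annotation, hrl_reactions,
                                  mode = c("transporters",
                                           "entry_points_excluding_transporters",
                                           "combined")) {
  mode <- match.arg(mode)
  entry_classes <- c("entry_pathway_change", "entry_compartment_change")
  is_trans <- annotation$class == "transporter"
  is_entry <- annotation$class %in% entry_classes
  hrl <- annotation$reaction %in% hrl_reactions
  if (mode == "transporters") {
    pop <- rep(TRUE, nrow(annotation))
    succ <- is_trans
  } else if (mode == "entry_points_excluding_transporters") {
    pop <- !is_trans
    succ <- is_entry & !is_trans
  } else {
    pop <- rep(TRUE, nrow(annotation))
    succ <- is_trans | is_entry
  }
  N <- sum(pop)
  K <- sum(succ & pop)
  n <- sum(hrl & pop)
  k <- sum(hrl & succ & pop)
  list(N = N, K = K, n = n, k = k,
       p = hypergeom_enrichment(N, K, n, k))
}

#' Export a metabolite-reaction edge list for network visualization
#'
#' Writes one row per (reaction, metabolite) incidence with the role of the
#' metabolite, loadable in Cytoscape-style tools.
#'
#' @param model a \code{metabolic_model}.
#' @param path output TSV path, or NULL to return the data.frame.
#' @return the edge-list data.frame, invisibly when written.
#' @export
export_edge_list <- function(model, path = NULL) {
  rows <- list()
  for (j in seq_len(n_reactions(model))) {
    col <- model$S[, j]
    nz <- which(col != 0)
    rows[[j]] <- data.frame(reaction = reaction_ids(model)[j],
                            metabolite = model$metabolites$id[nz],
                            role = ifelse(col[nz] < 0, "substrate", "product"),
                            coefficient = abs(col[nz]),
                            subsystem = model$reactions$subsystem[j],
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  if (is.null(path)) return(edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}
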