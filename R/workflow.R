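# Orchestration of the context-extraction workflow: reaction scoring to core
# sets, optional medium constraining, optional biomass forcing with a
# two-pass extraction, and leave-one-out cross-validation of confidence.

#' Partition scored reactions into core sets
#'
#' Expression-supported reactions (+1) that are not transporters become core;
#' expression-supported transporters become non-penalized (their genes are
#' often promiscuous, so forcing them would drag whole subsystems in);
#' reactions scored -1 become inactive. Reactions without a score (no GPR)
#' stay penalized non-core.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_scores named vector from [map_scores()].
#' @param transporters character vector of transporter reaction ids (see
#'   [classify_transporters()]).
#' @return a [core_sets()] object.
#' @export
build_core_sets <- function(model, reaction_scores,
                            transporters = classify_transporters(model)) {
  ids <- reaction_ids(model)
  sc <- reaction_scores[ids]
  plus <- ids[!is.na(sc) & sc == 1]
  minus <- ids[!is.na(sc) & sc == -1]
  core_sets(core = setdiff(plus, transporters),
            inactive = minus,
            non_penalized = intersect(plus, transporters))
}

#' Growth-medium specification
#'
#' @param metabolites character vector of extracellular metabolite species
#'   present in the medium (compartment-stripped identifiers).
#' @param compartment extracellular compartment label (default "e").
#' @return object of class \code{medium_spec}.
#' @export
medium_spec <- function(metabolites, compartment = "e") {
  structure(list(metabolites = unique(metabolites),
                 compartment = compartment), class = "medium_spec")
}

#' Constrain a model to a growth medium
#'
#' Closes the uptake direction of every exchange reaction whose metabolite is
#' absent from the medium, adds missing exchange reactions for medium
#' metabolites when requested, then re-runs [fastcc()] and restricts the
#' model to the consistent part.
#'
#' @param model a \code{metabolic_model}.
#' @param medium a [medium_spec()].
#' @param policy an [epsilon_policy()].
#' @param add_missing add exchange reactions for medium metabolites that lack
#'   one (default TRUE).
#' @param uptake_bound bound magnitude for added exchanges (default 1000).
#' @return medium-constrained, flux-consistent \code{metabolic_model}.
#' @export
apply_medium <- function(model, medium, policy = epsilon_policy(),
                         add_missing = TRUE, uptake_bound = 1000) {
  stopifnot(inherits(medium, "medium_spec"))
  extra <- model$metabolites$compartment == medium$compartment
  unknown <- setdiff(medium$metabolites,
                     model$metabolites$species[extra])
  if (length(unknown))
    warning(sprintf("medium metabolite(s) not in model: %s",
                    paste(unknown, collapse = ", ")))
  ex <- exchange_reactions(model)
  for (r in ex) {
    j <- rxn_index(model, r)
    midx <- which(model$S[, j] != 0)
    if (!extra[midx]) next
    sp <- model$metabolites$species[midx]
    if (sp %in% medium$metabolites) next
    # close the uptake direction (flux bringing the metabolite in)
    if (model$S[midx, j] < 0) {
      model$reactions$lb[j] <- max(model$reactions$lb[j], 0)
    } else {
      model$reactions$ub[j] <- min(model$reactions$ub[j], 0)
    }
  }
  if (add_missing) {
    have_ex <- vapply(ex, function(r) {
      j <- rxn_index(model, r)
      model$metabolites$species[which(model$S[, j] != 0)]
    }, character(1))
    need <- setdiff(intersect(medium$metabolites,
                              model$metabolites$species[extra]), have_ex)
    for (sp in need) {
      midx <- which(extra & model$metabolites$species == sp)[1]
      rid <- paste0("EX_", model$metabolites$id[midx], "_added")
      model$reactions <- rbind(
        model$reactions,
        data.frame(id = rid, lb = -uptake_bound, ub = uptake_bound,
                   gpr = "", subsystem = "Exchange",
                   stringsAsFactors = FALSE))
      col <- matrix(0, nrow(model$S), 1, dimnames = list(NULL, rid))
      col[midx, 1] <- -1
      model$S <- cbind(model$S, col)
      model$gpr_rules <- c(model$gpr_rules, list(NULL))
    }
  }
  validate_model(model)
  keep <- fastcc(model, policy)
  restrict_model(model, keep)
}

#' Reconstruct a context-specific model
#'
#' Without a biomass reaction, a single modified-FASTCORE run extracts the
#' consistent subnetwork around the core. With a biomass reaction, a first
#' pass forces biomass flux while leaving core reactions (and core
#' transporters) non-penalized, so that the biomass support re-uses as much
#' expression-supported machinery as possible; the pass-1 output joins the
#' core, transporters are moved back out of the core into the non-penalized
#' set, and a second pass forces all core reactions to carry flux.
#'
#' @param model a flux-consistent (medium-constrained) parent model.
#' @param sets a [core_sets()] object computed on this model.
#' @param biomass optional biomass reaction id.
#' @param policy an [epsilon_policy()].
#' @param transporters transporter set used to keep transport reactions out
#'   of the forced core in pass 2.
#' @return object of class \code{context_model}: fields \code{parent_id},
#'   \code{retained}, \code{confidence} (NA until [crossvalidate()]),
#'   \code{sets}, \code{biomass}, \code{provenance}.
#' @export
reconstruct <- function(model, sets, biomass = NULL,
                        policy = epsilon_policy(),
                        transporters = classify_transporters(model)) {
  stopifnot(inherits(sets, "core_sets"))
  work <- model
  if (length(sets$inactive)) {
    work <- zero_reactions(work, sets$inactive)
    keep <- fastcc(work, policy)
    lost <- setdiff(sets$core, keep)
    if (length(lost))
      stop(sprintf("unrecoverable core reaction(s): %s",
                   paste(lost, collapse = ", ")), call. = FALSE)
    work <- restrict_model(work, keep)
  }
  avail <- reaction_ids(work)
  np <- intersect(sets$non_penalized, avail)
  core <- sets$core
  if (!length(core) && is.null(biomass) && !length(sets$forced)) {
    warning("empty core and no forced reactions: returning an empty model")
    retained <- character(0)
  } else if (is.null(biomass)) {
    retained <- modified_fastcore(
      work, core_sets(core = core, non_penalized = np,
                      forced = intersect(sets$forced, avail)), policy)
  } else {
    if (!biomass %in% avail)
      stop(sprintf("forced reaction cannot carry flux: %s", biomass),
           call. = FALSE)
    pass1 <- modified_fastcore(
      work, core_sets(non_penalized = union(core, np), forced = biomass),
      policy)
    core2 <- setdiff(union(pass1, core), transporters)
    np2 <- union(np, intersect(union(pass1, core), transporters))
    retained <- modified_fastcore(
      work, core_sets(core = core2, non_penalized = np2), policy)
  }
  structure(list(parent_id = model$id,
                 parent_reactions = reaction_ids(model),
                 retained = retained,
                 confidence = stats::setNames(
                   rep(NA_character_, length(retained)), retained),
                 exclusion_support = NULL,
                 sets = sets, biomass = biomass,
                 provenance = list(eps = policy$eps,
                                   n_core = length(sets$core),
                                   n_inactive = length(sets$inactive),
                                   n_non_penalized = length(sets$non_penalized),
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context_model of '%s': %d retained reactions (core %d)>\n",
              x$parent_id, length(x$retained), length(x$sets$core)))
  invisible(x)
}

#' Leave-one-out cross-validation of reaction confidence
#'
#' Repeats the reconstruction once per core reaction with that reaction left
#' out of the core. Retained reactions present in every run are supported by
#' at least two core reactions (confidence "high"); core reactions absent
#' from their own left-out run rest on their own expression evidence only
#' ("moderate"); remaining non-core reactions depend on a single core
#' reaction ("low"). Optionally the same process runs over the inactive set:
#' an excluded reaction that reappears when its own inactive call is lifted
#' was excluded on "single-evidence", otherwise "multi-evidence".
#'
#' @param model parent model as passed to [reconstruct()].
#' @param sets a [core_sets()] object.
#' @param biomass optional biomass reaction id.
#' @param policy an [epsilon_policy()].
#' @param exclusions also label excluded (inactive) reactions (default
#'   FALSE).
#' @param max_folds cap on leave-one-out folds; cores larger than this are
#'   deterministically subsampled with \code{seed}.
#' @param seed seed for fold subsampling.
#' @return a \code{context_model} with \code{confidence} filled in (and
#'   \code{exclusion_support} when \code{exclusions = TRUE}).
#' @export
crossvalidate <- function(model, sets, biomass = NULL,
                          policy = epsilon_policy(), exclusions = FALSE,
                          max_folds = Inf, seed = 1L) {
  base <- reconstruct(model, sets, biomass, policy)
  folds <- sets$core
  if (length(folds) > max_folds) {
    set.seed(seed)
    folds <- sort(sample(folds, max_folds))
  }
  runs <- lapply(folds, function(r) {
    s2 <- core_sets(core = setdiff(sets$core, r),
                    inactive = sets$inactive,
                    non_penalized = sets$non_penalized,
                    forced = sets$forced)
    tryCatch(reconstruct(model, s2, biomass, policy)$retained,
             error = function(e) character(0),
             warning = function(w) character(0))
  })
  conf <- stats::setNames(rep("low", length(base$retained)), base$retained)
  if (length(runs)) {
    in_all <- base$retained[vapply(base$retained, function(r)
      all(vapply(runs, function(run) r %in% run, logical(1))), logical(1))]
    conf[in_all] <- "high"
    for (i in seq_along(folds)) {
      r <- folds[i]
      if (r %in% base$retained && !(r %in% runs[[i]]))
        conf[r] <- "moderate"
    }
  } else {
    conf[] <- "high"
  }
  base$confidence <- conf
  if (exclusions && length(sets$inactive)) {
    supp <- stats::setNames(rep(NA_character_, length(sets$inactive)),
                            sets$inactive)
    for (r in sets$inactive) {
      s2 <- core_sets(core = sets$core,
                      inactive = setdiff(sets$inactive, r),
                      non_penalized = sets$non_penalized,
                      forced = sets$forced)
      back <- tryCatch(reconstruct(model, s2, biomass, policy)$retained,
                       error = function(e) character(0),
                       warning = function(w) character(0))
      supp[r] <- if (r %in% back) "single-evidence" else "multi-evidence"
    }
    base$exclusion_support <- supp
  }
  base
}

#' Run the whole discretization-to-model workflow
#'
#' Convenience wrapper: consensus gene scores, GPR mapping, core-set
#' construction, optional medium step, reconstruction and optional
#' cross-validation.
#'
#' @param model parent \code{metabolic_model} (made consistent internally).
#' @param score_matrix genes x samples trinary score matrix.
#' @param active_fraction consensus fraction (default 0.9).
#' @param medium optional [medium_spec()].
#' @param biomass optional biomass reaction id.
#' @param policy an [epsilon_policy()].
#' @param crossval run [crossvalidate()] (default FALSE).
#' @return a \code{context_model}.
#' @export
run_workflow <- function(model, score_matrix, active_fraction = 0.9,
                         medium = NULL, biomass = NULL,
                         policy = epsilon_policy(), crossval = FALSE) {
  keep <- fastcc(model, policy)
  cons <- restrict_model(model, keep)
  if (!is.null(medium)) cons <- apply_medium(cons, medium, policy)
  gs <- consensus_scores(score_matrix, active_fraction)
  rs <- map_scores(cons, gs)
  sets <- build_core_sets(cons, rs)
  if (crossval) crossvalidate(cons, sets, biomass, policy)
  else reconstruct(cons, sets, biomass, policy)
}
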