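# Context extraction: FASTCORE-style close-to-minimal consistent subnetworks
# around a core of expression-supported reactions, plus the modified variant
# with zero-cost (non-penalized) and forced (must-carry-flux) reaction sets.
#
# Two LPs alternate: LP-7 pushes as many unsupported core reactions as
# possible above the flux threshold; LP-9 then finds a flux vector keeping
# those core fluxes high while minimizing the weighted L1 norm over the
# penalized reactions (weight 1 penalized, 0 non-penalized/core).

#' Core / inactive / non-penalized / forced reaction sets
#'
#' @param core reactions with positive expression evidence that must be in
#'   the extracted model.
#' @param inactive reactions with negative evidence; the workflow zeroes
#'   their bounds before extraction.
#' @param non_penalized reactions whose inclusion is free of cost but not
#'   forced (expression-supported transporters).
#' @param forced reactions that must carry flux (e.g. biomass) without being
#'   ordinary core members.
#' @return object of class \code{core_sets}.
#' @export
core_sets <- function(core = character(0), inactive = character(0),
                      non_penalized = character(0), forced = character(0)) {
  if (length(intersect(core, inactive)))
    stop("core and inactive sets overlap", call. = FALSE)
  structure(list(core = unique(core), inactive = unique(inactive),
                 non_penalized = unique(setdiff(non_penalized, core)),
                 forced = unique(forced)),
            class = "core_sets")
}

# LP-9 (weighted): minimize sum_j w_j |v_j| over penalized reactions subject
# to v_k >= eps * scale for the supported core K, S v = 0 and the model
# bounds scaled by the same factor (the solution is returned unscaled), so
# the anti-degeneracy scaling never collides with finite capacities.
lp9 <- function(model, K, penalized, policy, scale = 1e5) {
  n <- n_reactions(model)
  np <- length(penalized)
  kdx <- rxn_index(model, K)
  pdx <- rxn_index(model, penalized)
  level <- rep(policy$eps * scale, length(kdx))
  nv <- n + np
  Aeq <- cbind(model$S, matrix(0, nrow(model$S), np))
  # v_p - z_p <= 0 and -v_p - z_p <= 0
  Ale <- matrix(0, 2 * np + length(K), nv)
  ble <- numeric(2 * np + length(K))
  if (np) {
    Ale[cbind(seq_len(np), pdx)] <- 1
    Ale[cbind(seq_len(np), n + seq_len(np))] <- -1
    Ale[cbind(np + seq_len(np), pdx)] <- -1
    Ale[cbind(np + seq_len(np), n + seq_len(np))] <- -1
  }
  # -v_k <= -level
  Ale[cbind(2 * np + seq_along(K), kdx)] <- -1
  ble[2 * np + seq_along(K)] <- -level
  obj <- c(numeric(n), rep(1, np))
  r <- lp_solve(obj, Aeq, rep(0, nrow(model$S)), Ale, ble,
                lb = c(model$reactions$lb * scale, rep(0, np)),
                ub = c(model$reactions$ub * scale, rep(Inf, np)))
  if (r$status != "optimal") return(NULL)
  stats::setNames(r$x[seq_len(n)] / scale, reaction_ids(model))
}

find_sparse_mode <- function(model, J, penalized, singleton, policy) {
  if (!length(J)) return(character(0))
  v <- lp7(model, if (singleton) J[1] else J, policy)
  K <- intersect(J, flux_support(v, policy))
  if (!length(K)) return(character(0))
  v2 <- lp9(model, K, penalized, policy)
  if (is.null(v2)) return(character(0))
  flux_support(v2, policy)
}

fastcore_weighted <- function(model, core, non_penalized, policy) {
  all_ids <- reaction_ids(model)
  unknown <- setdiff(core, all_ids)
  if (length(unknown))
    stop(sprintf("core reaction(s) not in model: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!length(core)) return(character(0))
  irrev <- all_ids[model$reactions$lb >= 0]
  penal <- setdiff(all_ids, union(core, non_penalized))

  work <- model
  J <- intersect(core, irrev)
  A <- find_sparse_mode(work, J, penal, FALSE, policy)
  miss <- setdiff(J, A)
  if (length(miss))
    stop(sprintf("unrecoverable core reaction(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  J <- setdiff(core, A)
  flipped <- FALSE
  singleton <- FALSE
  while (length(J)) {
    penal_now <- setdiff(penal, A)
    supp <- find_sparse_mode(work, J, penal_now, singleton, policy)
    A <- union(A, supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      JiRev <- setdiff(if (singleton) J[1] else J, irrev)
      if (flipped || !length(JiRev)) {
        if (singleton)
          stop(sprintf("unrecoverable core reaction(s): %s", J[1]),
               call. = FALSE)
        flipped <- FALSE
        singleton <- TRUE
      } else {
        work <- flip_reactions(work, JiRev)
        flipped <- TRUE
      }
    }
  }
  all_ids[all_ids %in% A]
}

#' FASTCORE context extraction
#'
#' Returns a close-to-minimal flux-consistent superset of \code{core}: every
#' returned reaction can carry flux of magnitude at least \code{policy$eps}
#' within the returned subnetwork. On fixtures small enough for exhaustive
#' search the added non-core set is exactly minimal.
#'
#' @param model a flux-consistent \code{metabolic_model}.
#' @param core character vector of core reaction ids (must be consistent in
#'   \code{model}).
#' @param policy an [epsilon_policy()].
#' @return character vector of retained reaction ids (superset of core).
#' @export
fastcore_extract <- function(model, core, policy = epsilon_policy()) {
  fastcore_weighted(model, core, character(0), policy)
}

#' Modified FASTCORE with non-penalized and forced reaction sets
#'
#' Like [fastcore_extract()], but reactions in \code{sets$non_penalized}
#' cost nothing to include (they are preferred over penalized non-core
#' reactions in the sparsity step) and reactions in \code{sets$forced} must
#' carry flux even though they are not expression-supported core members.
#' Reactions in \code{sets$inactive} are silenced (bounds zeroed) before
#' extraction.
#'
#' @param model a flux-consistent \code{metabolic_model}.
#' @param sets a [core_sets()] object.
#' @param policy an [epsilon_policy()].
#' @return character vector of retained reaction ids.
#' @export
modified_fastcore <- function(model, sets, policy = epsilon_policy()) {
  stopifnot(inherits(sets, "core_sets"))
  if (length(sets$inactive)) model <- zero_reactions(model, sets$inactive)
  core_all <- union(sets$core, sets$forced)
  if (!length(core_all)) return(character(0))
  if (length(sets$forced)) {
    rng <- fva(model, sets$forced)
    dead <- rng$reaction[pmax(rng$vmax, -rng$vmin) < policy$eps]
    if (length(dead))
      stop(sprintf("forced reaction cannot carry flux: %s",
                   paste(dead, collapse = ", ")), call. = FALSE)
  }
  fastcore_weighted(model, core_all, setdiff(sets$non_penalized, core_all),
                    policy)
}
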