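# The metabolic model container: a constraint-based genome-scale model with
# stoichiometry S (metabolites x reactions), flux bounds, GPR rules,
# subsystem annotation per reaction and compartment annotation per metabolite.

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns \code{id}, \code{species}
#'   (compartment-stripped chemical identity), \code{compartment}, and
#'   optionally \code{formula}.
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{gpr} (GPR string, "" for none), \code{subsystem} ("" allowed).
#' @param S numeric stoichiometric matrix, metabolites x reactions, with
#'   dimnames matching the id columns.
#' @param objective optional reaction id of the biomass/objective reaction.
#' @param id model identifier.
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, S, objective = NULL,
                            id = "model") {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  S <- as.matrix(S)
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      S = S,
                      objective = objective,
                      gpr_rules = lapply(reactions$gpr, parse_gpr)),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks matrix dimensions, duplicate identifiers and \code{lb <= ub}
#' per reaction; a violation raises an error naming the offending reaction.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (ncol(model$S) != nrow(model$reactions))
    stop("S column count does not match reaction count", call. = FALSE)
  if (nrow(model$S) != nrow(model$metabolites))
    stop("S row count does not match metabolite count", call. = FALSE)
  if (anyDuplicated(model$reactions$id))
    stop("duplicate reaction ids", call. = FALSE)
  if (anyDuplicated(model$metabolites$id))
    stop("duplicate metabolite ids", call. = FALSE)
  bad <- which(model$reactions$lb > model$reactions$ub)
  if (length(bad))
    stop(sprintf("lb > ub for reaction '%s'", model$reactions$id[bad[1]]),
         call. = FALSE)
  if (!is.null(model$objective) && !model$objective %in% model$reactions$id)
    stop(sprintf("objective reaction '%s' not in model", model$objective),
         call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites x %d reactions, %d compartments>\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              length(unique(x$metabolites$compartment))))
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model a \code{metabolic_model}.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Reaction identifiers of a model
#' @param model a \code{metabolic_model}.
#' @return character vector.
#' @export
reaction_ids <- function(model) model$reactions$id

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx))
    stop(sprintf("unknown reaction id(s): %s",
                 paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}

#' Restrict a model to a subset of reactions
#'
#' Drops all other reactions and any metabolite no longer referenced.
#'
#' @param model a \code{metabolic_model}.
#' @param keep character vector of reaction ids to retain.
#' @return restricted \code{metabolic_model}.
#' @export
restrict_model <- function(model, keep) {
  idx <- rxn_index(model, unique(keep))
  idx <- sort(idx)
  S <- model$S[, idx, drop = FALSE]
  used <- rowSums(S != 0) > 0
  obj <- model$objective
  if (!is.null(obj) && !obj %in% model$reactions$id[idx]) obj <- NULL
  metabolic_model(model$metabolites[used, , drop = FALSE],
                  model$reactions[idx, , drop = FALSE],
                  S[used, , drop = FALSE],
                  objective = obj, id = model$id)
}

#' Set flux bounds of selected reactions
#'
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids.
#' @param lb,ub new bounds (recycled); NULL leaves a bound unchanged.
#' @return modified model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- rxn_index(model, ids)
  if (!is.null(lb)) model$reactions$lb[idx] <- lb
  if (!is.null(ub)) model$reactions$ub[idx] <- ub
  validate_model(model)
  model
}

#' Zero out (silence) selected reactions
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids whose bounds become [0, 0].
#' @return modified model.
#' @export
zero_reactions <- function(model, ids) set_bounds(model, ids, lb = 0, ub = 0)

#' Identify exchange reactions
#'
#' An exchange (or demand/sink) reaction touches exactly one metabolite, so
#' it moves mass across the system boundary.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[colSums(model$S != 0) == 1]
}

#' Reactions with a non-empty GPR rule
#' @param model a \code{metabolic_model}.
#' @return character vector of reaction ids.
#' @export
gene_associated_reactions <- function(model) {
  model$reactions$id[!vapply(model$gpr_rules, is.null, logical(1))]
}

#' All genes referenced by a model's GPR rules
#' @param model a \code{metabolic_model}.
#' @return character vector of unique gene identifiers.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$gpr_rules, gpr_genes)))
}

#' Epsilon policy: what counts as "carrying flux"
#'
#' @param eps minimal significant flux magnitude; the FASTCORE-lineage
#'   default of 1e-4 is used.
#' @param feas_tol solver feasibility tolerance; must be at least 100x
#'   smaller than \code{eps}.
#' @return object of class \code{epsilon_policy}.
#' @export
epsilon_policy <- function(eps = 1e-4, feas_tol = 1e-9) {
  stopifnot(eps > 0, eps >= 100 * feas_tol)
  structure(list(eps = eps, feas_tol = feas_tol), class = "epsilon_policy")
}

# internal model-builder used by fixtures and tests: reactions given as
# named stoichiometry vectors over metabolite ids.
build_model <- function(mets, rxns, objective = NULL, id = "model") {
  # mets: data.frame(id, species, compartment[, formula])
  # rxns: named list; each element list(mets = c(id = coef), lb, ub,
  #        gpr = "", subsystem = "")
  rid <- names(rxns)
  S <- matrix(0, nrow(mets), length(rxns), dimnames = list(mets$id, rid))
  lb <- ub <- numeric(length(rxns))
  gpr <- sub <- character(length(rxns))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    S[names(r$mets), j] <- r$mets
    lb[j] <- r$lb
    ub[j] <- r$ub
    gpr[j] <- if (is.null(r$gpr)) "" else r$gpr
    sub[j] <- if (is.null(r$subsystem)) "" else r$subsystem
  }
  metabolic_model(mets,
                  data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                             subsystem = sub, stringsAsFactors = FALSE),
                  S, objective = objective, id = id)
}
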