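# LP backbone over a metabolic model: flux balance (FBA), flux variability
# (FVA) and flux-consistency checking via FASTCC-style LP sweeps.
#
# All LPs share the steady-state constraint S v = 0 with the model's bounds.

model_lp <- function(model, obj, maximize = FALSE, extra_lb = NULL,
                     extra_ub = NULL) {
  lb <- if (is.null(extra_lb)) model$reactions$lb else extra_lb
  ub <- if (is.null(extra_ub)) model$reactions$ub else extra_ub
  lp_solve(obj, model$S, rep(0, nrow(model$S)), lb = lb, ub = ub,
           maximize = maximize)
}

#' Maximize the flux through one reaction (flux balance analysis)
#'
#' Solves \eqn{\max v_{obj}} subject to \eqn{S v = 0} and the model bounds.
#' The optimum is unique even when the optimal flux vector is not.
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id to optimize; defaults to
#'   \code{model$objective}.
#' @param maximize direction (default TRUE).
#' @return list with \code{objective} (optimal flux value) and \code{fluxes}
#'   (named optimal flux vector).
#' @export
maximize_flux <- function(model, objective = model$objective,
                          maximize = TRUE) {
  if (is.null(objective)) stop("no objective reaction given", call. = FALSE)
  j <- rxn_index(model, objective)
  obj <- numeric(n_reactions(model))
  obj[j] <- 1
  r <- model_lp(model, obj, maximize = maximize)
  if (r$status == "infeasible")
    stop("model is infeasible under its bounds", call. = FALSE)
  if (r$status == "unbounded")
    stop(sprintf("objective '%s' is unbounded", objective), call. = FALSE)
  list(objective = r$objective,
       fluxes = stats::setNames(r$x, reaction_ids(model)))
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux under
#' \eqn{S v = 0} and the bounds, yielding the feasible flux range.
#'
#' @param model a \code{metabolic_model}.
#' @param reactions reaction ids (default: all).
#' @return data.frame with columns \code{reaction}, \code{vmin}, \code{vmax}.
#' @export
fva <- function(model, reactions = reaction_ids(model)) {
  idx <- rxn_index(model, reactions)
  n <- n_reactions(model)
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n)
    obj[idx[k]] <- 1
    lo <- model_lp(model, obj, maximize = FALSE)
    hi <- model_lp(model, obj, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop("model is infeasible under its bounds", call. = FALSE)
    vmin[k] <- if (lo$status == "unbounded") -Inf else lo$objective
    vmax[k] <- if (hi$status == "unbounded") Inf else hi$objective
  }
  data.frame(reaction = reactions, vmin = vmin, vmax = vmax,
             stringsAsFactors = FALSE)
}

#' Blocked reactions by the naive per-reaction FVA oracle
#'
#' The brute-force 2n-LP definition of flux consistency: a reaction is
#' blocked iff its FVA range lies strictly inside \code{(-eps, eps)}. Shipped
#' as the independent oracle against which [fastcc()] is tested.
#'
#' @param model a \code{metabolic_model}.
#' @param policy an [epsilon_policy()].
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions_fva <- function(model, policy = epsilon_policy()) {
  r <- fva(model)
  r$reaction[r$vmax < policy$eps & r$vmin > -policy$eps]
}

# LP-7: maximize the number of reactions in J that reach flux >= eps.
#   max sum(z_J)  s.t.  S v = 0, z_j <= v_j, 0 <= z <= eps, lb <= v <= ub
lp7 <- function(model, J, policy) {
  n <- n_reactions(model)
  nj <- length(J)
  jdx <- rxn_index(model, J)
  nv <- n + nj
  Aeq <- cbind(model$S, matrix(0, nrow(model$S), nj))
  Ale <- matrix(0, nj, nv)
  Ale[cbind(seq_len(nj), n + seq_len(nj))] <- 1   # z_j
  Ale[cbind(seq_len(nj), jdx)] <- -1              # - v_j <= 0
  obj <- c(numeric(n), rep(1, nj))
  r <- lp_solve(obj, Aeq, rep(0, nrow(model$S)), Ale, rep(0, nj),
                lb = c(model$reactions$lb, rep(0, nj)),
                ub = c(model$reactions$ub, rep(policy$eps, nj)),
                maximize = TRUE)
  if (r$status != "optimal")
    stop("LP-7 failed: model infeasible under its bounds", call. = FALSE)
  stats::setNames(r$x[seq_len(n)], reaction_ids(model))
}

flux_support <- function(v, policy) names(v)[abs(v) >= policy$eps * 0.99]

flip_reactions <- function(model, ids) {
  idx <- rxn_index(model, ids)
  lb <- model$reactions$lb[idx]
  ub <- model$reactions$ub[idx]
  model$reactions$lb[idx] <- -ub
  model$reactions$ub[idx] <- -lb
  model$S[, idx] <- -model$S[, idx]
  model
}

#' Flux-consistent reaction set (FASTCC)
#'
#' Identifies the reactions able to carry a flux of magnitude at least
#' \code{policy$eps} in some steady-state flux distribution, using the
#' LP-7 sweep with sign flipping for reversible reactions. The complement is
#' the blocked set removed by consistency pruning.
#'
#' @param model a \code{metabolic_model}.
#' @param policy an [epsilon_policy()].
#' @return character vector of consistent (unblocked) reaction ids, in model
#'   order.
#' @export
fastcc <- function(model, policy = epsilon_policy()) {
  all_ids <- reaction_ids(model)
  irrev <- all_ids[model$reactions$lb >= 0]
  A <- character(0)

  J <- irrev
  if (length(J)) {
    v <- lp7(model, J, policy)
    A <- flux_support(v, policy)
  }
  blocked_irrev <- setdiff(J, A)
  J <- setdiff(setdiff(all_ids, A), blocked_irrev)

  flipped <- FALSE
  singleton <- FALSE
  work <- model
  while (length(J)) {
    Ji <- if (singleton) J[1] else J
    v <- lp7(work, Ji, policy)
    A <- union(A, flux_support(v, policy))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      JiRev <- setdiff(Ji, irrev)
      if (flipped || !length(JiRev)) {
        flipped <- FALSE
        if (singleton) J <- setdiff(J, Ji) else singleton <- TRUE
      } else {
        work <- flip_reactions(work, JiRev)
        flipped <- TRUE
      }
    }
  }
  all_ids[all_ids %in% A]
}
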