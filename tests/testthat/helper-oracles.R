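# Independent oracles. These deliberately avoid the algorithms under test:
# consistency is checked reaction-by-reaction with the naive 2n-LP FVA
# definition, and minimal supports are found by exhaustive subset search.

# every reaction of the restricted model can carry |v| >= eps
oracle_all_consistent <- function(model, ids, policy = epsilon_policy()) {
  if (!length(ids)) return(TRUE)
  sub <- restrict_model(model, ids)
  length(blocked_reactions_fva(sub, policy)) == 0
}

subsets_of <- function(x, k) {
  if (k == 0) return(list(character(0)))
  if (k > length(x)) return(list())
  utils::combn(x, k, simplify = FALSE)
}

# exhaustive minimal-weighted-support search: find the minimum number of
# penalized reactions whose addition (possibly together with any free
# non-penalized reactions) makes core fully consistent. Returns the cost and
# one witness set.
oracle_min_support <- function(model, core, non_penalized = character(0),
                               policy = epsilon_policy()) {
  all_ids <- reaction_ids(model)
  cand <- setdiff(all_ids, core)
  np <- intersect(cand, non_penalized)
  pen <- setdiff(cand, np)
  np_subs <- unlist(lapply(0:length(np), subsets_of, x = np),
                    recursive = FALSE)
  for (cost in 0:length(pen)) {
    for (ps in subsets_of(pen, cost)) {
      for (ns in np_subs) {
        ids <- c(core, ps, ns)
        if (oracle_all_consistent(model, ids, policy))
          return(list(cost = cost, set = ids))
      }
    }
  }
  NULL
}

# hypergeometric upper tail by direct enumeration
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# graph-walk entry-point oracle: direct re-statement of the tracing rules on
# a small model, independent of the package's vectorized implementation
oracle_entry_class <- function(model, rid, dirs, trans, cof = cofactor_config()) {
  subsys <- stats::setNames(model$reactions$subsystem, reaction_ids(model))
  j <- match(rid, reaction_ids(model))
  if (rid %in% trans) return("transporter")
  d <- dirs[rid]
  if (d == "blocked") return("internal")
  ors <- if (d == "both") c("forward", "backward") else d
  found <- character(0)
  sp <- tolower(model$metabolites$species)
  for (o in ors) {
    col <- model$S[, j] * (if (o == "forward") 1 else -1)
    consumed <- which(col < 0)
    produced <- which(col > 0)
    keep <- c()
    for (mi in consumed) {
      s <- sp[mi]
      if (s %in% tolower(c(cof$inorganic, cof$co2))) next
      paired <- FALSE
      for (p in cof$pairs)
        if ((s == tolower(p[1]) && tolower(p[2]) %in% sp[produced]) ||
            (s == tolower(p[2]) && tolower(p[1]) %in% sp[produced]))
          paired <- TRUE
      if (!paired) keep <- c(keep, mi)
    }
    for (mi in keep) {
      for (pj in seq_along(reaction_ids(model))) {
        pid <- reaction_ids(model)[pj]
        if (pid == rid) next
        co <- model$S[mi, pj]
        pd <- dirs[pid]
        makes <- (co > 0 && pd %in% c("forward", "both")) ||
                 (co < 0 && pd %in% c("backward", "both"))
        if (!makes) next
        if (!(pid %in% trans)) {
          if (subsys[pid] != subsys[rid]) found <- c(found, "path")
        } else {
          # origin compartment of the transported species
          sp_m <- model$metabolites$species[mi]
          ocomp <- model$metabolites$compartment[
            model$S[, pj] * sign(co) < 0 &
              model$metabolites$species == sp_m]
          oi <- which(model$metabolites$species == sp_m &
                      model$metabolites$compartment %in% ocomp)
          origin_prod <- character(0)
          for (qj in seq_along(reaction_ids(model))) {
            qid <- reaction_ids(model)[qj]
            if (qid %in% c(rid, pid)) next
            for (m2 in oi) {
              cq <- model$S[m2, qj]
              qd <- dirs[qid]
              if ((cq > 0 && qd %in% c("forward", "both")) ||
                  (cq < 0 && qd %in% c("backward", "both")))
                origin_prod <- c(origin_prod, qid)
            }
          }
          if (!length(origin_prod)) found <- c(found, "path")
          if (any(subsys[origin_prod] != subsys[rid])) found <- c(found, "path")
          if (any(subsys[origin_prod] == subsys[rid])) found <- c(found, "comp")
        }
      }
    }
  }
  if ("path" %in% found) "entry_pathway_change"
  else if ("comp" %in% found) "entry_compartment_change"
  else "internal"
}
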