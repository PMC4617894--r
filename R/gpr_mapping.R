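# Mapping gene-level trinary scores to reaction level through GPR rules.

#' Map gene scores to reaction scores via GPR rules
#'
#' Applies [evaluate_gpr()] per reaction: AND takes the minimum child score,
#' OR the maximum. Reactions without a GPR rule get \code{NA} — they carry no
#' expression evidence and enter neither the core nor the inactive set.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_scores named numeric vector of trinary gene scores.
#' @param default score substituted for genes absent from \code{gene_scores}
#'   (default 0).
#' @return named numeric vector per reaction, values in {-1, 0, 1} or NA.
#' @export
map_scores <- function(model, gene_scores, default = 0) {
  out <- vapply(model$gpr_rules, function(rule) {
    if (is.null(rule)) return(NA_real_)
    evaluate_gpr(rule, gene_scores, default = default)
  }, numeric(1))
  stats::setNames(out, reaction_ids(model))
}

#' Propagate differential-expression labels to reactions
#'
#' Re-uses the min/max GPR semantics with up = +1, down = -1, unchanged = 0:
#' a reaction is called up-regulated when its rule evaluates to +1 and
#' down-regulated at -1.
#'
#' @param model a \code{metabolic_model}.
#' @param up,down character vectors of up-/down-regulated gene ids.
#' @return list with character vectors \code{up} and \code{down} of reaction
#'   ids.
#' @export
propagate_de_labels <- function(model, up, down) {
  labels <- c(stats::setNames(rep(1, length(up)), up),
              stats::setNames(rep(-1, length(down)), down))
  sc <- map_scores(model, labels)
  list(up = names(sc)[!is.na(sc) & sc == 1],
       down = names(sc)[!is.na(sc) & sc == -1])
}
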