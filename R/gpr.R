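# Gene-protein-reaction (GPR) Boolean rules.
#
# A rule is stored as a nested list tree: leaves are gene identifiers
# (character scalars wrapped as list(op = "gene", gene = id)), internal nodes
# combine >= 2 children with "and" / "or". AND models protein complexes
# (every subunit required), OR models isozymes (any one suffices).

#' Parse a GPR string into a Boolean rule tree
#'
#' Accepts case-insensitive \code{AND}/\code{OR} connectives, parentheses and
#' opaque gene tokens (any run of characters other than whitespace or
#' parentheses). When parentheses are absent, \code{AND} binds tighter than
#' \code{OR}, so \code{"A or B and C"} parses as \code{OR(A, AND(B, C))}.
#'
#' @param text GPR string; empty or all-whitespace strings yield \code{NULL}
#'   (reaction has no gene association).
#' @return a \code{gpr_rule} tree, or \code{NULL} for an empty rule.
#' @examples
#' parse_gpr("((A and B) or C)")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("GPR parse error near token %d ('%s'): trailing input",
                 st$pos, st$toks[st$pos]), call. = FALSE)
  node
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  if (length(kids) == 1L) kids[[1L]] else gpr_node("or", kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  if (length(kids) == 1L) kids[[1L]] else gpr_node("and", kids)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok))
    stop(sprintf("GPR parse error at position %d: missing operand", st$pos),
         call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop(sprintf("GPR parse error at token %d: unbalanced parentheses",
                   st$pos), call. = FALSE)
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop(sprintf("GPR parse error at token %d ('%s'): empty operand",
                 st$pos, tok), call. = FALSE)
  st$pos <- st$pos + 1L
  structure(list(op = "gene", gene = tok), class = "gpr_rule")
}

gpr_node <- function(op, children) {
  structure(list(op = op, children = children), class = "gpr_rule")
}

#' Render a GPR rule tree back to a canonical string
#'
#' Inverse of [parse_gpr()] up to whitespace and case: every internal node is
#' fully parenthesized, connectives are lowercase. \code{parse_gpr} is
#' idempotent through this renderer.
#'
#' @param rule a \code{gpr_rule} tree or \code{NULL}.
#' @return character scalar (empty string for \code{NULL}).
#' @export
gpr_to_string <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$op == "gene") return(rule$gene)
  inner <- vapply(rule$children, gpr_to_string, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", rule$op, " ")), ")")
}

#' Genes referenced by a GPR rule
#' @param rule a \code{gpr_rule} tree or \code{NULL}.
#' @return character vector of unique gene identifiers.
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

#' Evaluate a GPR rule on trinary gene scores
#'
#' AND maps to the minimum of its children's scores (a complex is only as
#' available as its least-expressed subunit); OR maps to the maximum (one
#' expressed isozyme suffices). Leaves return the gene's score.
#'
#' @param rule a \code{gpr_rule} tree (not \code{NULL}).
#' @param gene_scores named numeric vector of trinary scores in {-1, 0, 1}.
#' @param default score used for genes absent from \code{gene_scores}
#'   (default 0, "undetermined", so missing annotation never deletes a
#'   reaction).
#' @return trinary score in {-1, 0, 1}.
#' @export
evaluate_gpr <- function(rule, gene_scores, default = 0) {
  stopifnot(!is.null(rule))
  if (rule$op == "gene") {
    s <- gene_scores[rule$gene]
    return(if (is.na(s) || is.null(s)) default else unname(s))
  }
  vals <- vapply(rule$children, evaluate_gpr, numeric(1),
                 gene_scores = gene_scores, default = default)
  if (rule$op == "and") min(vals) else max(vals)
}

#' Evaluate a GPR rule as a Boolean under gene knockouts
#'
#' @param rule a \code{gpr_rule} tree (not \code{NULL}).
#' @param knocked character vector of deleted gene identifiers; all other
#'   genes are treated as present.
#' @return TRUE if the reaction retains enzymatic support, FALSE otherwise.
#' @export
evaluate_gpr_boolean <- function(rule, knocked) {
  if (rule$op == "gene") return(!(rule$gene %in% knocked))
  vals <- vapply(rule$children, evaluate_gpr_boolean, logical(1),
                 knocked = knocked)
  if (rule$op == "and") all(vals) else any(vals)
}
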