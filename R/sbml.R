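# SBML import/export. Writes SBML Level 3 Version 1 with the fbc v2 package
# (flux bounds as parameters, GPRs as gene-product associations); reads both
# that dialect and legacy note-encoded annotations (GENE_ASSOCIATION /
# SUBSYSTEM lines), which is how older genome-scale reconstructions are
# distributed.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a metabolic model to SBML
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_CORE_NS,
                            "xmlns:fbc" = SBML_FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_sanitize(model$id),
                             "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment))
    xml2::xml_add_child(loc, "compartment", id = sbml_sanitize(cp),
                        constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(los, "species",
                              id = paste0("M_", sbml_sanitize(mt$id)),
                              name = mt$id,
                              compartment = sbml_sanitize(mt$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (!is.na(mt$formula) && nzchar(mt$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("lb_", sbml_sanitize(r$id)),
                        value = format(r$lb, digits = 17), constant = "true")
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("ub_", sbml_sanitize(r$id)),
                        value = format(r$ub, digits = 17), constant = "true")
  }

  genes <- model_genes(model)
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_sanitize(g)),
                          "fbc:label" = g)
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    rx <- xml2::xml_add_child(lor, "reaction",
                              id = paste0("R_", sbml_sanitize(r$id)),
                              name = r$id,
                              reversible = tolower(r$lb < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", sbml_sanitize(r$id)),
                              "fbc:upperFluxBound" = paste0("ub_", sbml_sanitize(r$id)))
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    col <- model$S[, j]
    rs <- which(col < 0)
    ps <- which(col > 0)
    if (length(rs)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in rs)
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", sbml_sanitize(model$metabolites$id[i])),
                            stoichiometry = format(-col[i], digits = 17),
                            constant = "true")
    }
    if (length(ps)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in ps)
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", sbml_sanitize(model$metabolites$id[i])),
                            stoichiometry = format(col[i], digits = 17),
                            constant = "true")
    }
    rule <- model$gpr_rules[[j]]
    if (!is.null(rule)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      write_gpr_node(gpa, rule)
    }
  }

  if (!is.null(model$objective)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_sanitize(model$objective)),
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

write_gpr_node <- function(parent, rule) {
  if (rule$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_sanitize(rule$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", rule$op))
    for (ch in rule$children) write_gpr_node(node, ch)
  }
}

attr_any_ns <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

local_children <- function(node, name) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", name))
}

read_gpr_node <- function(node, labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- attr_any_ns(node, "geneProduct")
    lab <- labels[gid]
    return(structure(list(op = "gene",
                          gene = if (is.na(lab)) sub("^G_", "", gid) else unname(lab)),
                     class = "gpr_rule"))
  }
  kids <- xml2::xml_children(node)
  sub <- lapply(kids, read_gpr_node, labels = labels)
  if (nm %in% c("and", "or")) return(gpr_node(nm, sub))
  if (length(sub) == 1) return(sub[[1]])
  stop(sprintf("unsupported GPR element '%s' in SBML", nm), call. = FALSE)
}

#' Read a metabolic model from SBML
#'
#' Accepts SBML Level 2/3; flux bounds are taken from fbc bound parameters
#' when present, otherwise from the \code{reversible} attribute (defaults
#' -1000/1000 reversible, 0/1000 irreversible). GPR rules are read from fbc
#' gene-product associations or from \code{GENE_ASSOCIATION:} note lines;
#' subsystems from \code{SUBSYSTEM:} note lines.
#'
#' @param path SBML file path.
#' @return a validated \code{metabolic_model}.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("cannot read SBML file '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  mdl <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (is.na(xml2::xml_name(mdl, ns = character())) || length(mdl) == 0)
    stop("no <model> element found", call. = FALSE)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='species']")
  comp <- vapply(sp_nodes, function(n) xml2::xml_attr(n, "compartment"),
                 character(1))
  sid <- vapply(sp_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
  sname <- vapply(sp_nodes, function(n) xml2::xml_attr(n, "name"),
                  character(1))
  mid <- ifelse(is.na(sname) | !nzchar(sname), sub("^M_", "", sid), sname)
  formula <- vapply(sp_nodes, attr_any_ns, character(1),
                    name = "chemicalFormula")
  # species identity: id minus a trailing _<compartment> suffix
  species <- mid
  suffix <- paste0("_", comp)
  has_suffix <- substring(mid, nchar(mid) - nchar(suffix) + 1) == suffix
  species[has_suffix] <- substring(mid[has_suffix], 1,
                                   nchar(mid[has_suffix]) - nchar(suffix[has_suffix]))
  mets <- data.frame(id = mid, species = species, compartment = comp,
                     formula = formula, stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(xml2::xml_attr(n, "value")),
           numeric(1)),
    vapply(par_nodes, function(n) xml2::xml_attr(n, "id"), character(1)))

  gp_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='geneProduct']")
  labels <- stats::setNames(
    vapply(gp_nodes, attr_any_ns, character(1), name = "label"),
    vapply(gp_nodes, attr_any_ns, character(1), name = "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='reaction']")
  nr <- length(rx_nodes)
  rid <- lb <- ub <- gpr <- subsys <- vector("character", nr)
  lb <- ub <- numeric(nr)
  sto <- list()
  sid_to_mid <- stats::setNames(mid, sid)
  for (j in seq_len(nr)) {
    n <- rx_nodes[[j]]
    nm <- xml2::xml_attr(n, "name")
    rid[j] <- if (!is.na(nm) && nzchar(nm)) nm else
      sub("^R_", "", xml2::xml_attr(n, "id"))
    lbp <- attr_any_ns(n, "lowerFluxBound")
    ubp <- attr_any_ns(n, "upperFluxBound")
    rev <- identical(xml2::xml_attr(n, "reversible"), "true")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[lbp]
             else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[ubp]
             else 1000

    coefs <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in local_children(local_children(n, side), "speciesReference")) {
        spid <- xml2::xml_attr(sr, "species")
        st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
        if (is.na(st)) st <- 1
        key <- sid_to_mid[spid]
        if (is.na(key))
          stop(sprintf("reaction '%s' references unknown species '%s'",
                       rid[j], spid), call. = FALSE)
        coefs[key] <- (if (key %in% names(coefs)) coefs[key] else 0) + sgn * st
      }
    }
    sto[[j]] <- coefs

    gpa <- xml2::xml_find_first(n, ".//*[local-name()='geneProductAssociation']")
    notes_txt <- paste(xml2::xml_text(
      xml2::xml_find_all(n, ".//*[local-name()='notes']//*")), collapse = "\n")
    if (length(gpa) && !inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      rule <- if (length(kids)) read_gpr_node(kids[[1]], labels) else NULL
      gpr[j] <- gpr_to_string(rule)
    } else if (grepl("GENE_ASSOCIATION:", notes_txt)) {
      line <- regmatches(notes_txt,
                         regexpr("GENE_ASSOCIATION:[^\n]*", notes_txt))
      gpr[j] <- trimws(sub("GENE_ASSOCIATION:", "", line))
    } else gpr[j] <- ""
    if (grepl("SUBSYSTEM:", notes_txt)) {
      line <- regmatches(notes_txt, regexpr("SUBSYSTEM:[^\n]*", notes_txt))
      subsys[j] <- trimws(sub("SUBSYSTEM:", "", line))
    } else subsys[j] <- ""
  }

  S <- matrix(0, nrow(mets), nr, dimnames = list(mets$id, rid))
  for (j in seq_len(nr))
    if (length(sto[[j]])) S[names(sto[[j]]), j] <- sto[[j]]

  objective <- NULL
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (length(fo) && !inherits(fo, "xml_missing")) {
    ro <- attr_any_ns(fo, "reaction")
    hit <- which(vapply(rx_nodes, function(n)
      identical(xml2::xml_attr(n, "id"), ro), logical(1)))
    if (length(hit)) objective <- rid[hit[1]]
  }

  metabolic_model(mets, data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                                   subsystem = subsys,
                                   stringsAsFactors = FALSE),
                  S, objective = objective, id = model_id)
}

#' Export a context model as SBML restricted to its retained reactions
#'
#' @param context a \code{context_model}.
#' @param parent the parent \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_context_sbml <- function(context, parent, path) {
  write_sbml(restrict_model(parent, context$retained), path)
}
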