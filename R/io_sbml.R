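# SBML Level 3 subset with FBC-style flux bounds and gene associations.
#
# The writer emits the conventional COBRA encoding: species carry
# fbc:charge and fbc:chemicalFormula, reactions reference shared bound
# parameters via fbc:lowerFluxBound/fbc:upperFluxBound, GPR rules are
# fbc:geneProductAssociation trees over fbc:geneProduct entries, and the
# objective is an fbc:listOfObjectives entry. The reader accepts exactly
# this subset and rejects constructs outside it (events, rules).

.SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model as an SBML Level 3 (FBC subset) document
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sbml_subset <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_CORE_NS, "xmlns:fbc" = .SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(
      sps, "species", id = paste0("M_", m$id), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = as.character(m$charge)
    )
    if (nzchar(m$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    }
  }

  # shared flux-bound parameters
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  par_id <- function(v) {
    s <- gsub("-", "m", gsub("\\.", "p", format(v, digits = 15)))
    paste0("B_", s)
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(pars, "parameter", id = par_id(v),
                        value = format(v, digits = 15), constant = "true")
  }

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    node <- xml2::xml_add_child(
      rxs, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = par_id(r$lb),
      "fbc:upperFluxBound" = par_id(r$ub)
    )
    meta <- character(0)
    if (nzchar(r$subsystem)) {
      meta <- c(meta, paste0("SUBSYSTEM: ", r$subsystem))
    }
    if (!is.na(r$drg)) {
      meta <- c(meta, paste0("DELTA_R_G_PRIME: ",
                             format(r$drg, digits = 15)))
    }
    if (length(meta) > 0L) {
      notes <- xml2::xml_add_child(node, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      for (line in meta) xml2::xml_add_child(body, "p", line)
    }
    s <- model$stoichiometry[[r$id]]
    reac <- s[s < 0]
    prod <- s[s > 0]
    if (length(reac) > 0L) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = format(-reac[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (length(prod) > 0L) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = format(prod[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (nzchar(r$gpr)) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      .gpr_to_fbc(assoc, parse_gpr(r$gpr)$tree)
    }
  }

  if (!is.na(model$objective)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective),
                        "fbc:coefficient" = "1")
  }

  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(gps, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

.gpr_to_fbc <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", tree))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent,
                              if (tree$op == "and") "fbc:and" else "fbc:or")
  for (arg in tree$args) .gpr_to_fbc(node, arg)
  invisible(NULL)
}

#' Read a model from an SBML Level 3 (FBC subset) document
#'
#' Rejects SBML constructs outside the flux-balance subset (events, rate
#' or assignment rules, initial assignments, constraints) with an error
#' naming the construct.
#'
#' @param path path to the SBML file.
#' @param quiet suppress the entity-count message.
#' @return a `metabolic_model`.
#' @export
read_sbml_subset <- function(path, quiet = TRUE) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_CORE_NS, fbc = .SBML_FBC_NS)
  for (construct in c("listOfEvents", "listOfRules",
                      "listOfInitialAssignments", "listOfConstraints")) {
    if (length(xml2::xml_find_all(doc, paste0("//s:", construct),
                                  ns)) > 0L) {
      stop(sprintf("SBML construct outside supported subset: %s",
                   construct), call. = FALSE)
    }
  }
  strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

  pars <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id")
  )

  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula", default = ""),
    charge = as.integer(xml2::xml_attr(sp_nodes, "charge", default = "0")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE
  )
  mets$formula[is.na(mets$formula)] <- ""
  mets$name[is.na(mets$name)] <- mets$id

  gp_nodes <- xml2::xml_find_all(
    doc, "//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- strip_prefix(xml2::xml_attr(gp_nodes, "id"), "G_")

  rx_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    nm <- xml2::xml_attr(node, "name")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) par_vals[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref)) par_vals[[ub_ref]] else 1000
    st <- numeric(0)
    for (sr in xml2::xml_find_all(node,
                                  "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      m <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node,
                                  "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      m <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(assoc, "xml_missing")) "" else {
      kids <- xml2::xml_children(assoc)
      if (length(kids) == 0L) "" else
        deparse_gpr(parse_gpr(.fbc_to_gpr(kids[[1]], ns)))
    }
    subsystem <- ""
    drg <- NA_real_
    for (p in xml2::xml_find_all(
      node, "./s:notes//*[local-name() = 'p']", ns)) {
      txt <- xml2::xml_text(p)
      if (startsWith(txt, "SUBSYSTEM: ")) {
        subsystem <- sub("^SUBSYSTEM: ", "", txt)
      } else if (startsWith(txt, "DELTA_R_G_PRIME: ")) {
        drg <- as.numeric(sub("^DELTA_R_G_PRIME: ", "", txt))
      }
    }
    reactions[[i]] <- reaction(id = rid, stoichiometry = st,
                               name = if (is.na(nm)) rid else nm,
                               lb = lb, ub = ub, gpr = gpr,
                               subsystem = subsystem, drg = drg)
  }

  obj_node <- xml2::xml_find_first(
    doc, "//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- if (inherits(obj_node, "xml_missing")) NA_character_ else {
    strip_prefix(xml2::xml_attr(obj_node, "reaction"), "R_")
  }

  model <- metabolic_model(mets, reactions,
                           genes = if (length(genes) > 0L) genes else NULL,
                           objective = objective)
  if (!quiet) {
    message(sprintf("loaded SBML model: %d genes, %d metabolites, %d reactions",
                    length(model$genes), nrow(model$metabolites),
                    nrow(model$reactions)))
  }
  model
}

.fbc_to_gpr <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(sub("^G_", "",
               xml2::xml_attr(node, "geneProduct")))
  }
  parts <- vapply(xml2::xml_children(node), .fbc_to_gpr, character(1),
                  ns = ns)
  joined <- paste(parts, collapse = if (nm == "and") " and " else " or ")
  paste0("(", joined, ")")
}
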