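#' Construct a metabolite
#'
#' @param id metabolite id carrying a compartment suffix (`_c` or `_e`),
#'   e.g. `"g6p_c"`.
#' @param name free-text name.
#' @param formula chemical formula string (may be `""` for pseudo-species
#'   such as biomass).
#' @param charge integer elementary charge.
#' @param compartment `"c"` (cytosol) or `"e"` (extracellular). Defaults to
#'   the id suffix.
#' @return one-row data.frame in the model metabolite layout.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = NULL) {
  if (is.null(compartment)) compartment <- sub("^.*_([ce])$", "\\1", id)
  if (!compartment %in% c("c", "e")) {
    stop(sprintf("metabolite '%s': compartment must be 'c' or 'e'", id),
         call. = FALSE)
  }
  if (!endsWith(id, paste0("_", compartment))) {
    stop(sprintf("metabolite '%s': id suffix does not match compartment '%s'",
                 id, compartment), call. = FALSE)
  }
  data.frame(id = id, name = name, formula = formula,
             charge = as.integer(charge), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed), in mmol per unit flux.
#' @param name free-text name.
#' @param lb,ub flux bounds in mmol/gDCW/h (1/h for the biomass reaction).
#' @param gpr GPR rule string (`""` = spontaneous/orphan).
#' @param subsystem free-text pathway label.
#' @param drg optional transformed Gibbs energy of reaction in kJ/mol
#'   (`NA` if unknown).
#' @return a list of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, name = id, lb = -1000, ub = 1000,
                     gpr = "", subsystem = "", drg = NA_real_) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)),
            all(nzchar(names(stoichiometry))))
  if (length(stoichiometry) == 0L) {
    stop(sprintf("reaction '%s': empty stoichiometry", id), call. = FALSE)
  }
  if (lb > ub) {
    stop(sprintf("reaction '%s': lower bound %g exceeds upper bound %g",
                 id, lb, ub), call. = FALSE)
  }
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lb = lb, ub = ub, gpr = gpr, subsystem = subsystem,
                 drg = drg),
            class = "reaction")
}

#' Assemble a metabolic model
#'
#' A metabolic model bundles metabolites, reactions (with stoichiometry,
#' bounds and GPR rules), the gene list, and the objective reaction.
#' Exchange pseudo-reactions are detected structurally: a reaction touching
#' exactly one metabolite, which must live in the extracellular
#' compartment.
#'
#' @param metabolites data.frame with columns id, name, formula, charge,
#'   compartment (rows as produced by [metabolite()]).
#' @param reactions list of [reaction()] objects.
#' @param genes character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @param objective id of the objective reaction (conventionally the
#'   biomass reaction); `NA` allowed for models used only structurally.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective = NA_character_) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  rids <- vapply(reactions, `[[`, character(1), "id")
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rids
  rx <- data.frame(
    id = rids,
    name = vapply(reactions, `[[`, character(1), "name"),
    lb = vapply(reactions, `[[`, numeric(1), "lb"),
    ub = vapply(reactions, `[[`, numeric(1), "ub"),
    gpr = vapply(reactions, `[[`, character(1), "gpr"),
    subsystem = vapply(reactions, `[[`, character(1), "subsystem"),
    drg = vapply(reactions, `[[`, numeric(1), "drg"),
    stringsAsFactors = FALSE
  )
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(rx$gpr, gpr_genes), use.names = FALSE)))
  }
  model <- structure(list(metabolites = metabolites, reactions = rx,
                          stoichiometry = stoich, genes = genes,
                          objective = objective),
                     class = "metabolic_model")
  model$reactions$is_exchange <- vapply(model$stoichiometry, function(s) {
    length(s) == 1L
  }, logical(1))
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, resolvability of stoichiometry keys and GPR
#' leaves, bound ordering, the single-extracellular-metabolite form of
#' exchange reactions, and the objective id.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a message on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rx <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(rx$id)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")),
         call. = FALSE)
  }
  bad <- !(mets$compartment %in% c("c", "e"))
  if (any(bad)) {
    stop(sprintf("metabolite(s) outside compartments {c,e}: %s",
                 paste(mets$id[bad], collapse = ", ")), call. = FALSE)
  }
  for (rid in rx$id) {
    s <- model$stoichiometry[[rid]]
    missing_mets <- setdiff(names(s), mets$id)
    if (length(missing_mets) > 0L) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   rid, paste(missing_mets, collapse = ", ")), call. = FALSE)
    }
    if (any(abs(s) >= 1e6)) {
      stop(sprintf("reaction '%s': coefficient magnitude >= 1e6", rid),
           call. = FALSE)
    }
  }
  if (any(rx$lb > rx$ub)) {
    stop(sprintf("lb > ub for reaction(s): %s",
                 paste(rx$id[rx$lb > rx$ub], collapse = ", ")), call. = FALSE)
  }
  ex <- rx$id[rx$is_exchange]
  for (rid in ex) {
    met <- names(model$stoichiometry[[rid]])
    comp <- mets$compartment[match(met, mets$id)]
    if (!identical(comp, "e")) {
      stop(sprintf("exchange reaction '%s' touches non-extracellular metabolite '%s'",
                   rid, met), call. = FALSE)
    }
  }
  gpr_leaves <- unique(unlist(lapply(rx$gpr, gpr_genes), use.names = FALSE))
  missing_genes <- setdiff(gpr_leaves, model$genes)
  if (length(missing_genes) > 0L) {
    stop(sprintf("GPR gene(s) absent from gene list: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  if (!is.na(model$objective) && !(model$objective %in% rx$id)) {
    stop(sprintf("objective reaction '%s' not in model", model$objective),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d genes, %d metabolites, %d reactions\n",
              length(x$genes), nrow(x$metabolites), nrow(x$reactions)))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Build the stoichiometric matrix S
#'
#' Rows are metabolites (both compartments; exchange pseudo-reactions are
#' written single-metabolite, `a_e <-> 0`, so every retained row closes its
#' balance), columns follow the model's reaction order. Entry (i, j) is the
#' stoichiometric coefficient of metabolite i in reaction j.
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix with dimnames (metabolite ids x reaction
#'   ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    s <- model$stoichiometry[[rids[j]]]
    S[names(s), j] <- s
  }
  S
}

#' Disable reactions lost under a set of gene deletions
#'
#' Every reaction whose GPR evaluates to inactive under the deletions has
#' its bounds closed to (0, 0); all other reactions are untouched. Deleting
#' a gene id absent from the model is a warning, not an error, so scenario
#' scripts can be shared across models.
#'
#' @param model a `metabolic_model`.
#' @param deleted character vector of deleted gene ids.
#' @return list with `model` (the derived model) and `disabled` (character
#'   vector of closed reaction ids).
#' @export
apply_gene_deletions <- function(model, deleted) {
  stopifnot(inherits(model, "metabolic_model"))
  deleted <- unique(as.character(deleted))
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown) > 0L) {
    warning(sprintf("deleted gene(s) not in model (ignored): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  disabled <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gpr[i]
    if (!nzchar(rule)) next  # spontaneous/orphan: never gene-disabled
    if (!evaluate_gpr(rule, deleted)) {
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- 0
      disabled <- c(disabled, model$reactions$id[i])
    }
  }
  list(model = model, disabled = disabled)
}

#' Close reactions directly by id
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions whose bounds are set to (0, 0).
#' @return the derived model.
#' @export
knockout_reactions <- function(model, reaction_ids) {
  missing_rx <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing_rx) > 0L) {
    stop(sprintf("unknown reaction id(s): %s",
                 paste(missing_rx, collapse = ", ")), call. = FALSE)
  }
  idx <- model$reactions$id %in% reaction_ids
  model$reactions$lb[idx] <- 0
  model$reactions$ub[idx] <- 0
  model
}

#' Add reactions (and any new metabolites) to a model
#'
#' Used to graft heterologous pathways, e.g. the E. coli glycerol
#' utilization triple or the xylose isomerase/xylulokinase pair, onto a
#' host model. All model invariants are re-validated after the union.
#'
#' @param model a `metabolic_model`.
#' @param reactions list of [reaction()] objects to add.
#' @param metabolites optional data.frame of new metabolites (rows as from
#'   [metabolite()]) required by the added reactions.
#' @param genes optional character vector of new gene ids; GPR leaves of
#'   the added reactions are added automatically.
#' @return the augmented model.
#' @export
augment_model <- function(model, reactions, metabolites = NULL,
                          genes = NULL) {
  stopifnot(inherits(model, "metabolic_model"), is.list(reactions))
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  new_ids <- vapply(reactions, `[[`, character(1), "id")
  dup <- intersect(new_ids, model$reactions$id)
  if (length(dup) > 0L) {
    stop(sprintf("reaction id(s) already present: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  mets <- model$metabolites
  if (!is.null(metabolites)) {
    metabolites <- metabolites[!(metabolites$id %in% mets$id), , drop = FALSE]
    mets <- rbind(mets, metabolites)
  }
  new_genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)),
                             use.names = FALSE))
  all_genes <- union(union(model$genes, new_genes), genes)
  old_rx <- lapply(model$reactions$id, function(rid) {
    i <- match(rid, model$reactions$id)
    reaction(id = rid, stoichiometry = model$stoichiometry[[rid]],
             name = model$reactions$name[i], lb = model$reactions$lb[i],
             ub = model$reactions$ub[i], gpr = model$reactions$gpr[i],
             subsystem = model$reactions$subsystem[i],
             drg = model$reactions$drg[i])
  })
  out <- metabolic_model(mets, c(old_rx, reactions), genes = all_genes,
                         objective = model$objective)
  out
}

#' Set flux bounds on one reaction
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; `NA` leaves the existing value.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NA_real_, ub = NA_real_) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) {
    stop(sprintf("unknown reaction id '%s'", reaction_id), call. = FALSE)
  }
  if (!is.na(lb)) model$reactions$lb[i] <- lb
  if (!is.na(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i]) {
    stop(sprintf("reaction '%s': lb %g > ub %g", reaction_id,
                 model$reactions$lb[i], model$reactions$ub[i]), call. = FALSE)
  }
  model
}

#' Exchange reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}
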