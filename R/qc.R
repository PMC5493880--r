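#' Elemental and charge balance report
#'
#' For every reaction computes the per-element residual (products minus
#' reactants, i.e. the stoichiometry-weighted sum of formula counts) and
#' the charge residual. Exchange, demand/sink and biomass reactions
#' intentionally create or destroy mass and are marked `exempt`; everything
#' else must balance exactly.
#'
#' Generic residue elements (R, X) are tolerated as long as they cancel;
#' a metabolite with an empty formula in a non-exempt reaction is an error.
#'
#' @param model a `metabolic_model`.
#' @param biomass_id id of the biomass reaction to exempt; default
#'   `model$objective`.
#' @return data.frame of class `balance_report` with columns `reaction_id`,
#'   `status` (`balanced`/`imbalanced`/`exempt`), `charge_residual`, and
#'   `residuals` (list column of named element residual vectors).
#' @export
check_mass_charge_balance <- function(model, biomass_id = model$objective) {
  mets <- model$metabolites
  comp_cache <- lapply(stats::setNames(mets$formula, mets$id), parse_formula)
  charges <- stats::setNames(mets$charge, mets$id)
  exempt_ids <- union(exchange_reactions(model),
                      if (is.na(biomass_id)) character(0) else biomass_id)
  n <- nrow(model$reactions)
  status <- character(n)
  charge_res <- numeric(n)
  res_list <- vector("list", n)
  for (i in seq_len(n)) {
    rid <- model$reactions$id[i]
    s <- model$stoichiometry[[rid]]
    if (rid %in% exempt_ids) {
      status[i] <- "exempt"
      charge_res[i] <- NA_real_
      res_list[[i]] <- stats::setNames(numeric(0), character(0))
      next
    }
    no_formula <- names(s)[!nzchar(mets$formula[match(names(s), mets$id)])]
    if (length(no_formula) > 0L) {
      stop(sprintf("reaction '%s': metabolite(s) without formula: %s",
                   rid, paste(no_formula, collapse = ", ")), call. = FALSE)
    }
    resid <- numeric(0)
    for (m in names(s)) {
      comp <- comp_cache[[m]]
      for (el in names(comp)) {
        resid[el] <- (if (el %in% names(resid)) resid[el] else 0) +
          s[[m]] * comp[[el]]
      }
    }
    resid <- resid[abs(resid) > 1e-9]
    cr <- sum(s * charges[names(s)])
    status[i] <- if (length(resid) == 0L && abs(cr) < 1e-9) {
      "balanced"
    } else "imbalanced"
    charge_res[i] <- cr
    res_list[[i]] <- resid
  }
  out <- data.frame(reaction_id = model$reactions$id, status = status,
                    charge_residual = charge_res, stringsAsFactors = FALSE)
  out$residuals <- res_list
  class(out) <- c("balance_report", "data.frame")
  out
}

#' Net mass of the biomass reaction
#'
#' Computes the net mass drained by the biomass pseudo-reaction:
#' `(sum of reactant-side coeff x MW - sum of product-side coeff x MW)
#' / 1000`, with coefficients in mmol/gDCW and molecular weights from the
#' metabolite formulas. A produced pseudo-species without a formula (a
#' "biomass" metabolite) is excluded. By the standard convention the result
#' should be 1 g per gram dry cell weight; growth-associated ATP hydrolysis
#' cancels in the net sum.
#'
#' @param model a `metabolic_model`.
#' @param biomass_reaction_id biomass reaction id; default
#'   `model$objective`.
#' @return mass in g/gDCW (a number).
#' @export
check_biomass_weight <- function(model,
                                 biomass_reaction_id = model$objective) {
  if (is.na(biomass_reaction_id) ||
      !(biomass_reaction_id %in% model$reactions$id)) {
    stop("biomass reaction not found in model", call. = FALSE)
  }
  s <- model$stoichiometry[[biomass_reaction_id]]
  mets <- model$metabolites
  total <- 0
  for (m in names(s)) {
    i <- match(m, mets$id)
    f <- mets$formula[i]
    if (!nzchar(f)) {
      if (s[[m]] > 0) next  # produced biomass pseudo-species: excluded
      stop(sprintf("biomass precursor '%s' has no formula", m),
           call. = FALSE)
    }
    comp <- parse_formula(f)
    if (any(names(comp) %in% c("R", "X"))) {
      stop(sprintf("metabolite '%s': generic residue element in biomass computation",
                   m), call. = FALSE)
    }
    total <- total - s[[m]] * molecular_weight(comp)
  }
  total / 1000
}

#' Assign reaction directionality from Gibbs energy
#'
#' Applies the usual thermodynamic rule: a reaction with transformed Gibbs
#' energy at or below `-t_irr` kJ/mol is irreversible forward
#' (bounds `(0, default_max)`), at or above `+t_irr` irreversible backward
#' (`(-default_max, 0)`), and reversible otherwise
#' (`(-default_max, default_max)`). Reactions without a Gibbs energy value
#' are left unchanged.
#'
#' @param model a `metabolic_model`.
#' @param t_irr irreversibility cutoff in kJ/mol (default 30).
#' @param default_max the "unbounded" sentinel flux (default 1000
#'   mmol/gDCW/h).
#' @param reaction_ids subset to process; default all non-exchange
#'   reactions with a Gibbs energy annotation.
#' @return the model with updated bounds; attribute `skipped` lists
#'   reactions without Gibbs energy values.
#' @export
assign_directionality <- function(model, t_irr = 30, default_max = 1000,
                                  reaction_ids = NULL) {
  stopifnot(t_irr >= 0)
  reaction_ids <- reaction_ids %||%
    model$reactions$id[!model$reactions$is_exchange]
  skipped <- character(0)
  for (rid in reaction_ids) {
    i <- match(rid, model$reactions$id)
    if (is.na(i)) stop(sprintf("unknown reaction '%s'", rid), call. = FALSE)
    drg <- model$reactions$drg[i]
    if (is.na(drg)) {
      skipped <- c(skipped, rid)
      next
    }
    if (drg <= -t_irr) {
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- default_max
    } else if (drg >= t_irr) {
      model$reactions$lb[i] <- -default_max
      model$reactions$ub[i] <- 0
    } else {
      model$reactions$lb[i] <- -default_max
      model$reactions$ub[i] <- default_max
    }
  }
  attr(model, "skipped") <- skipped
  model
}

#' Write a QC report as TSV
#'
#' @param report a `balance_report`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_balance_report <- function(report, path) {
  flat <- data.frame(
    reaction_id = report$reaction_id,
    status = report$status,
    charge_residual = report$charge_residual,
    element_residuals = vapply(report$residuals, function(r) {
      if (length(r) == 0L) "" else
        paste(sprintf("%s:%g", names(r), r), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
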