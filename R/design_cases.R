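# Named strain-design case studies: overproduction targets analyzed with
# the MUST procedure under 13C-derived wild-type bounds.

.design_cases <- list(
  lysine = list(target_met = "lys__L", additions = character(0)),
  valine = list(target_met = "val__L", additions = character(0)),
  serine = list(target_met = "ser__L", additions = character(0)),
  pdo = list(target_met = "12ppd", additions = "pdo_ecoli"),
  isobutanol = list(target_met = "ibutoh",
                    additions = "isobutanol_kivd_adhA"),
  proline = list(target_met = "pro__L", additions = character(0)),
  proline_dputA = list(target_met = "pro__L", additions = character(0),
                       delete_genes = "putA")
)

# exchange reaction whose single metabolite has the given base name
.find_exchange_for <- function(model, target_met) {
  ex <- exchange_reactions(model)
  for (rid in ex) {
    met <- names(model$stoichiometry[[rid]])
    if (sub("_[ce]$", "", met) == target_met) return(rid)
  }
  NA_character_
}

#' Run a named overproduction design case
#'
#' Applies the case's heterologous pathway additions (1,2-propanediol and
#' isobutanol) or gene deletions (the PutA-free proline case), fixes the
#' substrate uptake, and runs the MUST analysis against the wild-type
#' 13C-style bounds with the standard floors: product at 98 percent of its
#' theoretical maximum, biomass at 1 percent of its own.
#'
#' @param model a `metabolic_model`.
#' @param case one of `"lysine"`, `"valine"`, `"serine"`, `"pdo"`,
#'   `"isobutanol"`, `"proline"`, `"proline_dputA"`.
#' @param c13_constraints wild-type experimental flux bounds; if `NULL`, a
#'   13C-style table is generated around [minicore_wt_fluxes()] (suitable
#'   for the bundled mini-core model only).
#' @param carbon_source substrate exchange id (default the glucose
#'   exchange, `"EX_glc__D_e"`).
#' @param uptake_rate substrate uptake fixed in both spaces (default the
#'   magnitude of the model's current lower bound on the substrate
#'   exchange).
#' @param yield_fraction,biomass_fraction overproducer floors (defaults
#'   0.98, 0.01).
#' @param width_fraction interval half-width for generated 13C tables
#'   (default 0.05).
#' @param seed seed for generated 13C tables (default 20170630).
#' @return object of class `design_result`: list with `case`, `target_id`,
#'   `must` (a `must_sets`), `wt_reference` (the flux state the generated
#'   bounds wrap, or `NULL` when bounds were supplied), and `provenance`.
#' @export
run_design_case <- function(model, case, c13_constraints = NULL,
                            carbon_source = "EX_glc__D_e",
                            uptake_rate = NULL, yield_fraction = 0.98,
                            biomass_fraction = 0.01,
                            width_fraction = 0.05, seed = 20170630) {
  if (!case %in% names(.design_cases)) {
    stop(sprintf("unknown design case '%s'; known cases: %s", case,
                 paste(names(.design_cases), collapse = ", ")),
         call. = FALSE)
  }
  spec <- .design_cases[[case]]
  for (a in spec$additions) model <- add_pathway(model, a)
  if (!is.null(spec$delete_genes)) {
    model <- apply_gene_deletions(model, spec$delete_genes)$model
  }
  target_id <- .find_exchange_for(model, spec$target_met)
  if (is.na(target_id)) {
    stop(sprintf("no exchange reaction for target metabolite '%s' in model",
                 spec$target_met), call. = FALSE)
  }
  if (!(carbon_source %in% model$reactions$id)) {
    stop(sprintf("unknown carbon source exchange '%s'", carbon_source),
         call. = FALSE)
  }
  if (is.null(uptake_rate)) {
    uptake_rate <- abs(model$reactions$lb[match(carbon_source,
                                                model$reactions$id)])
    if (uptake_rate <= 0) {
      stop("uptake_rate not given and substrate exchange is closed",
           call. = FALSE)
    }
  }
  base_cs <- constraint_set(carbon_source, -uptake_rate, -uptake_rate)

  wt_reference <- NULL
  if (is.null(c13_constraints)) {
    wt_model <- apply_constraints(model, base_cs)
    wt_reference <- if ("PPCK" %in% model$reactions$id) {
      minicore_wt_fluxes(wt_model)
    } else {
      minimize_total_flux_at_optimum(wt_model)
    }
    c13_constraints <- make_c13_constraints(
      model, wt_reference, width_fraction = width_fraction, seed = seed)
  }

  must <- run_must_analysis(model, target_id,
                            c13_constraints = c13_constraints,
                            base_constraints = base_cs,
                            yield_fraction = yield_fraction,
                            biomass_fraction = biomass_fraction)
  res <- list(case = case, target_id = target_id, must = must,
              wt_reference = wt_reference,
              provenance = .provenance(model, list(
                case = case, carbon_source = carbon_source,
                uptake_rate = uptake_rate,
                yield_fraction = yield_fraction,
                biomass_fraction = biomass_fraction,
                width_fraction = width_fraction, seed = seed)))
  class(res) <- "design_result"
  res
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> case %s, target %s\n", x$case, x$target_id))
  print(x$must)
  invisible(x)
}

#' Genes recommended for a MUST class of a design result
#'
#' @param result a `design_result`.
#' @param class `"must_up"`, `"must_down"` (includes zero-forced) or
#'   `"must_zero"`.
#' @return character vector of gene ids (GPR leaves of the classified
#'   reactions).
#' @export
design_genes <- function(result, class = c("must_up", "must_down",
                                           "must_zero")) {
  class <- match.arg(class)
  ids <- must_reactions(result$must, class)
  genes <- result$must$genes[match(ids, result$must$reaction_id)]
  unique(unlist(strsplit(genes[nzchar(genes)], ",", fixed = TRUE),
                use.names = FALSE))
}
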