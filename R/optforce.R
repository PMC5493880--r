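# MUST stage of the OptForce strain-design procedure.
#
# Flux spans (FVA with no objective cut) are computed for the wild-type
# space, delimited by 13C-derived experimental flux bounds, and for the
# overproducer space, delimited by a production floor (a fraction of the
# theoretical maximum) plus a biomass floor. Reactions whose two spans do
# not overlap MUST be up-regulated (MustU), down-regulated (MustL) or, if
# additionally forced to zero, knocked out (MustX) to reach the target.

#' Constraints describing a forced-overproduction state
#'
#' Floors the target flux at `yield_fraction` of its theoretical maximum
#' and the biomass flux at `biomass_fraction` of its own theoretical
#' maximum, both computed under `base_constraints` (which should pin the
#' substrate uptake). A `yield_fraction` of 0 imposes no target floor.
#'
#' @param model a `metabolic_model`.
#' @param target_reaction_id the product transport/exchange flux to force.
#' @param yield_fraction floor on the target as a fraction of its maximum,
#'   in (0, 1]; default 0.98.
#' @param biomass_fraction floor on biomass as a fraction of its maximum,
#'   in \[0, 1\]; default 0.01.
#' @param base_constraints optional `constraint_set` (e.g. fixed substrate
#'   uptake) under which the maxima are computed and to which the floors
#'   are appended.
#' @return a `constraint_set`; attributes `target_floor` and
#'   `biomass_floor` carry the floor values.
#' @export
build_overproduction_constraints <- function(model, target_reaction_id,
                                             yield_fraction = 0.98,
                                             biomass_fraction = 0.01,
                                             base_constraints = NULL) {
  stopifnot(yield_fraction >= 0, yield_fraction <= 1,
            biomass_fraction >= 0, biomass_fraction <= 1)
  out <- base_constraints %||% constraint_set()
  target_floor <- NA_real_
  biomass_floor <- NA_real_
  if (yield_fraction > 0) {
    tmax <- theoretical_maximum(model, target_reaction_id,
                                constraints = base_constraints)
    target_floor <- yield_fraction * tmax
    i <- match(target_reaction_id, model$reactions$id)
    out <- merge_constraints(out, constraint_set(
      target_reaction_id, target_floor, model$reactions$ub[i],
      mode = "tighten"))
  }
  if (biomass_fraction > 0 && !is.na(model$objective)) {
    bmax <- theoretical_maximum(model, model$objective,
                                constraints = base_constraints)
    biomass_floor <- biomass_fraction * bmax
    i <- match(model$objective, model$reactions$id)
    out <- merge_constraints(out, constraint_set(
      model$objective, biomass_floor, model$reactions$ub[i],
      mode = "tighten"))
  }
  probe <- solve_fba(model, constraints = out,
                     objective = if (yield_fraction > 0)
                       target_reaction_id else model$objective)
  if (probe$status != "optimal") {
    stop(sprintf(
      "overproduction constraints infeasible (target floor %.6g, biomass floor %.6g)",
      target_floor, biomass_floor), call. = FALSE)
  }
  attr(out, "target_floor") <- target_floor
  attr(out, "biomass_floor") <- biomass_floor
  out
}

#' Flux spans under a constraint set
#'
#' FVA at objective fraction 0: the constraint set itself (13C bounds or
#' production floors) delimits the space, with no optimality cut.
#'
#' @param model a `metabolic_model`.
#' @param constraints a `constraint_set`.
#' @param reaction_ids reactions to span; default all.
#' @return a `flux_range` data.frame.
#' @export
compute_flux_spans <- function(model, constraints = NULL,
                               reaction_ids = NULL) {
  feas <- tryCatch(
    solve_fba(model, constraints = constraints, sense = "min",
              objective = model$reactions$id[1]),
    error = function(e) list(status = "infeasible")
  )
  if (feas$status == "infeasible") {
    viol <- .find_infeasible_bound(model, constraints)
    stop(sprintf("constraint set infeasible%s",
                 if (is.na(viol)) "" else
                   sprintf(" (relaxing '%s' restores feasibility)", viol)),
         call. = FALSE)
  }
  solve_fva(model, constraints = constraints, objective_fraction = 0,
            reaction_ids = reaction_ids)
}

# best-effort irreducible-infeasibility probe: relax one constrained
# reaction at a time and report the first whose relaxation restores
# feasibility
.find_infeasible_bound <- function(model, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0L) return(NA_character_)
  for (k in seq_len(nrow(constraints))) {
    cs <- constraints[-k, , drop = FALSE]
    class(cs) <- c("constraint_set", "data.frame")
    probe <- tryCatch(
      solve_fba(model, constraints = cs, sense = "min",
                objective = model$reactions$id[1]),
      error = function(e) list(status = "infeasible")
    )
    if (probe$status == "optimal") return(constraints$reaction_id[k])
  }
  NA_character_
}

#' Classify MUST sets from wild-type and overproducer flux spans
#'
#' A reaction is MustU if its overproducer span lies strictly above the
#' wild-type span (`ov_min > wt_max + epsilon`), MustL if strictly below
#' (`ov_max < wt_min - epsilon`), and MustX — a knockout call, reported as
#' a sub-class of MustL — if the overproducer span is additionally pinned
#' to zero. Overlapping spans are unclassified. The gap is the distance
#' between the two intervals; gaps below 1e-3 are annotated as weak.
#'
#' @param wt,ov `flux_range` data.frames over the same reaction ids.
#' @param epsilon absolute overlap tolerance (default 1e-6).
#' @return object of class `must_sets`: data.frame with columns
#'   `reaction_id`, `wt_min`, `wt_max`, `ov_min`, `ov_max`, `class`
#'   (`must_up`/`must_down`/`must_zero`/`unclassified`), `gap`, `weak`.
#' @export
classify_must_sets <- function(wt, ov, epsilon = 1e-6) {
  if (!setequal(wt$reaction_id, ov$reaction_id)) {
    stop("wild-type and overproducer spans cover different reactions",
         call. = FALSE)
  }
  ov <- ov[match(wt$reaction_id, ov$reaction_id), , drop = FALSE]
  cls <- rep("unclassified", nrow(wt))
  gap <- rep(0, nrow(wt))
  up <- ov$min > wt$max + epsilon
  down <- ov$max < wt$min - epsilon
  zero <- down & abs(ov$min) <= epsilon & abs(ov$max) <= epsilon
  cls[up] <- "must_up"
  cls[down] <- "must_down"
  cls[zero] <- "must_zero"
  gap[up] <- ov$min[up] - wt$max[up]
  gap[down] <- wt$min[down] - ov$max[down]
  out <- data.frame(reaction_id = wt$reaction_id,
                    wt_min = wt$min, wt_max = wt$max,
                    ov_min = ov$min, ov_max = ov$max,
                    class = cls, gap = gap,
                    weak = cls != "unclassified" & gap < 1e-3,
                    stringsAsFactors = FALSE)
  class(out) <- c("must_sets", "data.frame")
  out
}

#' Reactions in a MUST class
#'
#' @param must a `must_sets` object.
#' @param class one of `"must_up"`, `"must_down"`, `"must_zero"`.
#'   `"must_down"` includes the zero-forced sub-class.
#' @return character vector of reaction ids.
#' @export
must_reactions <- function(must, class = c("must_up", "must_down",
                                           "must_zero")) {
  class <- match.arg(class)
  if (class == "must_down") {
    must$reaction_id[must$class %in% c("must_down", "must_zero")]
  } else {
    must$reaction_id[must$class == class]
  }
}

#' @export
print.must_sets <- function(x, ...) {
  n <- table(factor(x$class, levels = c("must_up", "must_down",
                                        "must_zero", "unclassified")))
  cat(sprintf("<must_sets> MustU %d | MustL %d | MustX %d | unclassified %d\n",
              n[["must_up"]], n[["must_down"]], n[["must_zero"]],
              n[["unclassified"]]))
  invisible(x)
}

#' Run the full MUST analysis
#'
#' Composes [build_overproduction_constraints()] (overproducer space),
#' [compute_flux_spans()] for the wild-type space (delimited by the
#' 13C-derived bounds only) and the overproducer space, and
#' [classify_must_sets()]. The report maps reaction-level calls to gene
#' names through the GPR rules.
#'
#' @param model a `metabolic_model` (with any heterologous additions
#'   already applied).
#' @param target_id target transport/exchange reaction id.
#' @param c13_constraints `constraint_set` of wild-type experimental flux
#'   bounds.
#' @param base_constraints optional `constraint_set` shared by both
#'   spaces (e.g. fixed substrate uptake).
#' @param yield_fraction,biomass_fraction floors for the overproducer
#'   space (defaults 0.98 and 0.01).
#' @param epsilon overlap tolerance (default 1e-6).
#' @param reaction_ids reactions to classify; default all.
#' @return a `must_sets` data.frame with an added `genes` column;
#'   attributes `target_floor` and `biomass_floor` carry the floors used.
#' @export
run_must_analysis <- function(model, target_id, c13_constraints,
                              base_constraints = NULL,
                              yield_fraction = 0.98,
                              biomass_fraction = 0.01, epsilon = 1e-6,
                              reaction_ids = NULL) {
  wt_cs <- merge_constraints(base_constraints, c13_constraints)
  ov_cs <- build_overproduction_constraints(
    model, target_id, yield_fraction = yield_fraction,
    biomass_fraction = biomass_fraction,
    base_constraints = base_constraints
  )
  wt <- compute_flux_spans(model, wt_cs, reaction_ids = reaction_ids)
  ov <- compute_flux_spans(model, ov_cs, reaction_ids = reaction_ids)
  must <- classify_must_sets(wt, ov, epsilon = epsilon)
  must$genes <- vapply(must$reaction_id, function(rid) {
    paste(gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)]),
          collapse = ",")
  }, character(1))
  attr(must, "target_floor") <- attr(ov_cs, "target_floor")
  attr(must, "biomass_floor") <- attr(ov_cs, "biomass_floor")
  attr(must, "target_id") <- target_id
  must
}

#' Write a MUST report
#'
#' TSV of the per-reaction spans and classes plus a human-readable summary
#' block listing the reactions per class with their gene names.
#'
#' @param must a `must_sets` object.
#' @param path output TSV path; the summary goes to `<path>.txt`.
#' @return the TSV path, invisibly.
#' @export
write_must_report <- function(must, path) {
  utils::write.table(as.data.frame(must), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- c(sprintf("MUST analysis for target %s",
                     attr(must, "target_id") %||% "(unknown)"))
  for (cl in c("must_up", "must_down", "must_zero")) {
    ids <- must$reaction_id[must$class == cl]
    gn <- must$genes[must$class == cl]
    label <- c(must_up = "MustU (upregulate)",
               must_down = "MustL (downregulate)",
               must_zero = "MustX (knock out)")[[cl]]
    lines <- c(lines, paste0(label, ":"),
               if (length(ids) == 0L) "  (none)" else
                 sprintf("  %s [%s]", ids, gn))
  }
  writeLines(lines, paste0(path, ".txt"))
  invisible(path)
}
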