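#' Build a flux-bound constraint set
#'
#' A constraint set is a table of per-reaction flux bound overrides, the
#' carrier for 13C-derived experimental flux intervals and for scenario
#' uptake settings. `mode = "override"` replaces the model bounds;
#' `mode = "tighten"` intersects with them.
#'
#' @param reaction_id character vector of reaction ids.
#' @param lb,ub numeric bound vectors (mmol/gDCW/h).
#' @param mode `"override"` (default) or `"tighten"`, recycled.
#' @return object of class `constraint_set` (a data.frame).
#' @export
constraint_set <- function(reaction_id = character(0), lb = numeric(0),
                           ub = numeric(0), mode = "override") {
  stopifnot(length(reaction_id) == length(lb), length(lb) == length(ub))
  if (any(lb > ub)) {
    bad <- reaction_id[lb > ub]
    stop(sprintf("constraint lb > ub for: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  mode <- rep_len(mode, length(reaction_id))
  stopifnot(all(mode %in% c("override", "tighten")))
  if (anyDuplicated(reaction_id)) {
    stop("duplicate reaction ids in constraint set", call. = FALSE)
  }
  structure(data.frame(reaction_id = as.character(reaction_id),
                       lb = as.numeric(lb), ub = as.numeric(ub),
                       mode = mode, stringsAsFactors = FALSE),
            class = c("constraint_set", "data.frame"))
}

#' Merge two constraint sets
#'
#' Entries of `b` win on shared reaction ids.
#' @param a,b `constraint_set` objects (either may be `NULL`).
#' @return merged `constraint_set`.
#' @export
merge_constraints <- function(a, b) {
  if (is.null(a)) return(if (is.null(b)) constraint_set() else b)
  if (is.null(b)) return(a)
  keep <- !(a$reaction_id %in% b$reaction_id)
  out <- rbind(as.data.frame(a)[keep, , drop = FALSE], as.data.frame(b))
  constraint_set(out$reaction_id, out$lb, out$ub, out$mode)
}

#' Apply a constraint set to a model's bounds
#'
#' @param model a `metabolic_model`.
#' @param constraints a `constraint_set` or `NULL`.
#' @return the model with bounds merged.
#' @export
apply_constraints <- function(model, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0L) return(model)
  unknown <- setdiff(constraints$reaction_id, model$reactions$id)
  if (length(unknown) > 0L) {
    stop(sprintf("constraint set references unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  idx <- match(constraints$reaction_id, model$reactions$id)
  for (k in seq_len(nrow(constraints))) {
    i <- idx[k]
    if (constraints$mode[k] == "override") {
      model$reactions$lb[i] <- constraints$lb[k]
      model$reactions$ub[i] <- constraints$ub[k]
    } else {
      model$reactions$lb[i] <- max(model$reactions$lb[i], constraints$lb[k])
      model$reactions$ub[i] <- min(model$reactions$ub[i], constraints$ub[k])
    }
    if (model$reactions$lb[i] > model$reactions$ub[i]) {
      stop(sprintf("constraint on '%s' yields empty interval [%g, %g]",
                   constraints$reaction_id[k], model$reactions$lb[i],
                   model$reactions$ub[i]), call. = FALSE)
    }
  }
  model
}
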