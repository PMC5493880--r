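#' Flux balance analysis
#'
#' Maximizes the objective flux subject to the steady state `S v = 0` and
#' the model bounds merged with an optional constraint set. Exchange
#' reactions for freely transported small molecules (CO2, H2O, NH3/NH4,
#' phosphate, sulfite/sulfate, protons and water by default) can be opened
#' to (-default_max, default_max) via `free_exchanges`.
#'
#' @param model a `metabolic_model`.
#' @param constraints optional `constraint_set` of bound overrides.
#' @param objective objective reaction id; default `model$objective`.
#' @param free_exchanges character vector of extracellular metabolite base
#'   names whose exchange reactions are opened fully; `NULL` (default)
#'   leaves exchange bounds as stored in the model.
#' @param sense `"max"` (default) or `"min"`.
#' @param tol feasibility tolerance for the LP (default 1e-9).
#' @return object of class `flux_distribution`: list with `fluxes` (named
#'   vector), `objective_value`, `objective`, and `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`).
#' @export
solve_fba <- function(model, constraints = NULL, objective = NULL,
                      free_exchanges = NULL, sense = "max", tol = 1e-9) {
  model <- .prepare_model(model, constraints, free_exchanges)
  objective <- objective %||% model$objective
  j <- match(objective, model$reactions$id)
  if (is.na(j)) {
    stop(sprintf("objective reaction '%s' not in model", objective),
         call. = FALSE)
  }
  S <- build_stoichiometric_matrix(model)
  n <- ncol(S)
  obj <- numeric(n)
  obj[j] <- 1
  sol <- lp_solve(obj, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, sense = sense, tol = tol)
  fluxes <- stats::setNames(sol$x, model$reactions$id)
  structure(list(fluxes = fluxes, objective_value = sol$objective,
                 objective = objective, status = sol$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s, objective %s = %s\n",
              x$status, x$objective,
              format(x$objective_value, digits = 6)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.free_exchange_defaults <- c("co2", "h2o", "nh4", "nh3", "pi", "po4",
                             "so3", "so4", "h")

.prepare_model <- function(model, constraints, free_exchanges) {
  if (!is.null(free_exchanges)) {
    ex <- exchange_reactions(model)
    for (rid in ex) {
      met <- names(model$stoichiometry[[rid]])
      base <- sub("_[ce]$", "", met)
      base <- sub("__[A-Z]$", "", base)  # strip stereo tags like __D, __L
      if (tolower(base) %in% tolower(free_exchanges)) {
        i <- match(rid, model$reactions$id)
        model$reactions$lb[i] <- -1000
        model$reactions$ub[i] <- 1000
      }
    }
  }
  apply_constraints(model, constraints)
}

#' Resolve alternate optima by total-flux minimization
#'
#' FBA optima are usually degenerate; single flux values are only
#' well-defined under a selection rule. This fixes the objective at its
#' optimum (within relative tolerance 1e-6) and minimizes the sum of
#' absolute fluxes via the standard forward/reverse flux split, which
#' removes futile cycles and picks a parsimonious representative.
#'
#' @inheritParams solve_fba
#' @return a `flux_distribution` with the same objective value and minimal
#'   total flux; carries the total in `total_flux`.
#' @export
minimize_total_flux_at_optimum <- function(model, constraints = NULL,
                                           objective = NULL,
                                           free_exchanges = NULL,
                                           tol = 1e-9) {
  model <- .prepare_model(model, constraints, free_exchanges)
  objective <- objective %||% model$objective
  base <- solve_fba(model, objective = objective, tol = tol)
  if (base$status != "optimal") return(base)
  opt <- base$objective_value
  j <- match(objective, model$reactions$id)
  model$reactions$lb[j] <- max(model$reactions$lb[j],
                               opt - abs(opt) * 1e-6 - 1e-9)

  S <- build_stoichiometric_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # split v = p - q with p, q >= 0; bounds arranged so p - q spans [lb, ub]
  p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
  q_lb <- pmax(-ub, 0); q_ub <- pmax(-lb, 0)
  A <- cbind(S, -S)
  obj <- rep(1, 2L * n)
  sol <- lp_solve(obj, A, rep(0, nrow(S)), c(p_lb, q_lb), c(p_ub, q_ub),
                  sense = "min", tol = tol)
  if (sol$status != "optimal") {
    stop(sprintf("flux minimization LP returned status '%s'", sol$status),
         call. = FALSE)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  fluxes <- stats::setNames(v, model$reactions$id)
  structure(list(fluxes = fluxes, objective_value = fluxes[[objective]],
                 objective = objective, status = "optimal",
                 total_flux = sum(abs(v))),
            class = "flux_distribution")
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' the model bounds, the constraint set, and (for `objective_fraction > 0`)
#' a floor on the objective at `objective_fraction` times its optimum.
#' `objective_fraction = 0` gives pure feasibility spans with no objective
#' cut, the setting used for MUST-set flux spans.
#'
#' @inheritParams solve_fba
#' @param objective_fraction number in \[0, 1\].
#' @param reaction_ids reactions to scan; default all.
#' @return object of class `flux_range`: data.frame with columns
#'   `reaction_id`, `min`, `max`.
#' @export
solve_fva <- function(model, constraints = NULL, objective_fraction = 1.0,
                      reaction_ids = NULL, objective = NULL,
                      free_exchanges = NULL, tol = 1e-9) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  model <- .prepare_model(model, constraints, free_exchanges)
  reaction_ids <- reaction_ids %||% model$reactions$id
  missing_rx <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing_rx) > 0L) {
    stop(sprintf("unknown reaction id(s): %s",
                 paste(missing_rx, collapse = ", ")), call. = FALSE)
  }
  if (objective_fraction > 0) {
    objective <- objective %||% model$objective
    base <- solve_fba(model, objective = objective, tol = tol)
    if (base$status != "optimal") {
      stop(sprintf("base FBA returned status '%s'; cannot run FVA",
                   base$status), call. = FALSE)
    }
    opt <- base$objective_value
    j <- match(objective, model$reactions$id)
    floor_val <- objective_fraction * opt
    # keep the cut numerically attainable
    floor_val <- floor_val - abs(floor_val) * 1e-9
    model$reactions$lb[j] <- max(model$reactions$lb[j], floor_val)
  }
  S <- build_stoichiometric_matrix(model)
  n <- ncol(S)
  zeros <- rep(0, nrow(S))
  res <- matrix(NA_real_, nrow = length(reaction_ids), ncol = 2L)
  for (k in seq_along(reaction_ids)) {
    j <- match(reaction_ids[k], model$reactions$id)
    obj <- numeric(n); obj[j] <- 1
    lo <- lp_solve(obj, S, zeros, model$reactions$lb, model$reactions$ub,
                   sense = "min", tol = tol)
    hi <- lp_solve(obj, S, zeros, model$reactions$lb, model$reactions$ub,
                   sense = "max", tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop(sprintf("FVA LP for '%s' returned status '%s'",
                   reaction_ids[k],
                   if (lo$status != "optimal") lo$status else hi$status),
           call. = FALSE)
    }
    res[k, ] <- c(lo$objective, hi$objective)
  }
  structure(data.frame(reaction_id = reaction_ids, min = res[, 1],
                       max = res[, 2], stringsAsFactors = FALSE),
            class = c("flux_range", "data.frame"))
}

#' Simulate gene or reaction deletions
#'
#' Applies gene deletions through the GPR rules (or closes reactions
#' directly), then reruns FBA with total-flux minimization so the reported
#' fluxes are unique up to true degeneracy.
#'
#' @inheritParams solve_fba
#' @param genes character vector of gene ids to delete.
#' @param reactions character vector of reaction ids to close directly.
#' @return a `flux_distribution`; attribute `disabled` lists the reactions
#'   closed by the GPR evaluation.
#' @export
simulate_deletion <- function(model, genes = character(0),
                              reactions = character(0), constraints = NULL,
                              objective = NULL, free_exchanges = NULL,
                              tol = 1e-9) {
  disabled <- character(0)
  if (length(genes) > 0L) {
    del <- apply_gene_deletions(model, genes)
    model <- del$model
    disabled <- del$disabled
  }
  if (length(reactions) > 0L) {
    model <- knockout_reactions(model, reactions)
    disabled <- union(disabled, reactions)
  }
  out <- minimize_total_flux_at_optimum(model, constraints = constraints,
                                        objective = objective,
                                        free_exchanges = free_exchanges,
                                        tol = tol)
  attr(out, "disabled") <- disabled
  out
}

#' Robustness scan over a pinned reaction flux
#'
#' Re-solves the model with one reaction's flux fixed at multiples of its
#' flux in the base optimal distribution, reporting each reporter
#' reaction's flux relative to that base (ratio of test flux to native
#' flux). Infeasible multipliers are recorded and the scan continues.
#'
#' @inheritParams solve_fba
#' @param pinned_reaction_id the reaction whose flux is scanned.
#' @param multipliers numeric vector of scale factors, e.g.
#'   `seq(1, 5, by = 0.5)`.
#' @param reporter_ids reactions whose fluxes are reported.
#' @param reference optional `flux_distribution` supplying the native
#'   fluxes that define multiplier 1 and the reporter denominators;
#'   default is the base optimum under the scan objective itself.
#' @return data.frame with columns `multiplier`, `status`,
#'   `objective_value`, then per reporter its relative flux (test over
#'   native; `NA` where the native flux is zero) and absolute flux
#'   (`<id>_flux`).
#' @export
robustness_scan <- function(model, pinned_reaction_id, multipliers,
                            reporter_ids, constraints = NULL,
                            objective = NULL, free_exchanges = NULL,
                            reference = NULL, tol = 1e-9) {
  model <- .prepare_model(model, constraints, free_exchanges)
  objective <- objective %||% model$objective
  base <- reference %||%
    minimize_total_flux_at_optimum(model, objective = objective, tol = tol)
  if (base$status != "optimal") {
    stop(sprintf("base solution status '%s'", base$status), call. = FALSE)
  }
  ref <- base$fluxes[[pinned_reaction_id]]
  if (!is.finite(ref) || abs(ref) < 1e-9) {
    stop(sprintf("reference flux of '%s' is zero; cannot scan multiples",
                 pinned_reaction_id), call. = FALSE)
  }
  rep_base <- base$fluxes[reporter_ids]
  out <- vector("list", length(multipliers))
  for (k in seq_along(multipliers)) {
    pin <- multipliers[k] * ref
    mk <- tryCatch(
      set_bounds(model, pinned_reaction_id, lb = pin, ub = pin),
      error = function(e) NULL
    )
    sol <- if (is.null(mk)) {
      list(status = "infeasible")
    } else {
      tryCatch(minimize_total_flux_at_optimum(mk, objective = objective,
                                              tol = tol),
               error = function(e) list(status = "infeasible"))
    }
    row <- data.frame(multiplier = multipliers[k], status = sol$status,
                      objective_value = if (sol$status == "optimal")
                        sol$objective_value else NA_real_,
                      stringsAsFactors = FALSE)
    for (r in reporter_ids) {
      row[[r]] <- if (sol$status == "optimal") {
        if (abs(rep_base[[r]]) < 1e-9) NA_real_
        else sol$fluxes[[r]] / rep_base[[r]]
      } else NA_real_
      row[[paste0(r, "_flux")]] <- if (sol$status == "optimal")
        sol$fluxes[[r]] else NA_real_
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' Cofactor production breakdown
#'
#' For a solved flux distribution, splits the turnover of one metabolite
#' into producing reactions: reaction r produces at rate
#' `coeff(r, metabolite) * v_r` when that product is positive. At steady
#' state total production equals total consumption.
#'
#' @param model a `metabolic_model`.
#' @param distribution a `flux_distribution` with status `"optimal"`.
#' @param metabolite_id the metabolite (e.g. `"nadph_c"`).
#' @return list with `production` (named vector of positive producer
#'   rates), `consumption` (named vector of consumer rates, positive
#'   numbers), and `total` (total production rate).
#' @export
cofactor_production <- function(model, distribution, metabolite_id) {
  stopifnot(inherits(distribution, "flux_distribution"))
  if (distribution$status != "optimal") {
    stop("distribution is not optimal", call. = FALSE)
  }
  if (!(metabolite_id %in% model$metabolites$id)) {
    stop(sprintf("unknown metabolite '%s'", metabolite_id), call. = FALSE)
  }
  rates <- vapply(model$reactions$id, function(rid) {
    s <- model$stoichiometry[[rid]]
    coeff <- if (metabolite_id %in% names(s)) s[[metabolite_id]] else 0
    coeff * distribution$fluxes[[rid]]
  }, numeric(1))
  prod <- rates[rates > 1e-9]
  cons <- -rates[rates < -1e-9]
  list(production = prod, consumption = cons, total = sum(prod))
}

#' Theoretical maximum of a target flux
#'
#' FBA with the target as sole objective under the given constraints;
#' the anchor for overproduction floors (e.g. 98 percent of the
#' theoretical maximum).
#'
#' @inheritParams solve_fba
#' @param target_reaction_id the flux to maximize.
#' @return the optimum (a number).
#' @export
theoretical_maximum <- function(model, target_reaction_id,
                                constraints = NULL, free_exchanges = NULL,
                                tol = 1e-9) {
  sol <- solve_fba(model, constraints = constraints,
                   objective = target_reaction_id,
                   free_exchanges = free_exchanges, tol = tol)
  if (sol$status != "optimal") {
    stop(sprintf("theoretical maximum of '%s': LP status '%s'",
                 target_reaction_id, sol$status), call. = FALSE)
  }
  sol$objective_value
}
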