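#' Read a scenario configuration
#'
#' Scenario configs are YAML (or JSON, which YAML subsumes) documents with
#' keys: `carbon_source` (exchange reaction id), `uptake_rate`
#' (mmol/gDCW/h, > 0), optional `oxygen_rate` (number or `"free"`,
#' default free), optional `deletions` (list with `genes` and/or
#' `reactions`, or a flat gene list), optional `additions` (pathway names
#' from [known_pathways()]), optional `objective` (reaction id), optional
#' `uptake_mode` (`"fix"`, the default, sets the uptake as an equality;
#' `"bound"` only caps it), and optional `name`.
#'
#' @param config path to a YAML file, or a YAML string, or an already
#'   parsed list.
#' @return object of class `scenario_config`.
#' @export
read_scenario <- function(config) {
  cfg <- if (is.list(config)) {
    config
  } else if (length(config) == 1L && file.exists(config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(paste(config, collapse = "\n"))
  }
  scenario_config(
    carbon_source = cfg$carbon_source,
    uptake_rate = cfg$uptake_rate,
    oxygen_rate = cfg$oxygen_rate %||% "free",
    deletions = cfg$deletions,
    additions = cfg$additions,
    objective = cfg$objective,
    uptake_mode = cfg$uptake_mode %||% "fix",
    name = cfg$name %||% "scenario"
  )
}

#' Construct a scenario configuration
#'
#' @param carbon_source exchange reaction id of the carbon source (may be
#'   `NULL` for pure-addition scenarios).
#' @param uptake_rate carbon uptake rate, mmol/gDCW/h (> 0).
#' @param oxygen_rate `"free"` or a positive uptake rate.
#' @param deletions list with elements `genes` and/or `reactions`, or a
#'   character vector of gene ids.
#' @param additions character vector of pathway names.
#' @param objective objective reaction id (`NULL` = model default).
#' @param uptake_mode `"fix"` or `"bound"`.
#' @param name scenario label.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(carbon_source = NULL, uptake_rate = NULL,
                            oxygen_rate = "free", deletions = NULL,
                            additions = NULL, objective = NULL,
                            uptake_mode = c("fix", "bound"),
                            name = "scenario") {
  uptake_mode <- match.arg(uptake_mode)
  if (!is.null(uptake_rate)) {
    if (!is.numeric(uptake_rate) || uptake_rate <= 0) {
      stop("uptake_rate must be a positive number", call. = FALSE)
    }
  }
  if (!identical(oxygen_rate, "free")) {
    if (!is.numeric(oxygen_rate) || oxygen_rate <= 0) {
      stop("oxygen_rate must be \"free\" or a positive number",
           call. = FALSE)
    }
  }
  if (is.character(deletions)) deletions <- list(genes = deletions)
  deletions <- list(genes = as.character(deletions$genes %||% character(0)),
                    reactions = as.character(deletions$reactions %||%
                                               character(0)))
  additions <- as.character(additions %||% character(0))
  for (a in additions) pathway_additions(a)  # validates the name
  structure(list(carbon_source = carbon_source, uptake_rate = uptake_rate,
                 oxygen_rate = oxygen_rate, deletions = deletions,
                 additions = additions, objective = objective,
                 uptake_mode = uptake_mode, name = name),
            class = "scenario_config")
}

#' Enzymatic reactions a scenario's pathway additions expand to
#' @param config a `scenario_config`.
#' @return character vector of core (enzymatic) reaction ids added.
#' @export
scenario_expansions <- function(config) {
  unlist(lapply(config$additions, function(a) pathway_additions(a)$core),
         use.names = FALSE)
}

# apply a scenario's additions, deletions and medium to a model;
# returns list(model, substrate_exchange)
.scenario_model <- function(model, config) {
  for (a in config$additions) model <- add_pathway(model, a)
  if (length(config$deletions$genes) > 0L) {
    model <- apply_gene_deletions(model, config$deletions$genes)$model
  }
  if (length(config$deletions$reactions) > 0L) {
    model <- knockout_reactions(model, config$deletions$reactions)
  }
  ex <- exchange_reactions(model)
  if (!is.null(config$carbon_source) &&
      !(config$carbon_source %in% ex)) {
    stop(sprintf("unknown carbon-source exchange '%s'; candidates: %s",
                 config$carbon_source, paste(ex, collapse = ", ")),
         call. = FALSE)
  }
  # minimal medium: close uptake through all exchanges, then reopen the
  # freely transported small molecules, oxygen, and the carbon source
  free_set <- .free_exchange_defaults
  o2_ex <- ex[vapply(ex, function(rid) {
    grepl("^o2_", names(model$stoichiometry[[rid]]))
  }, logical(1))]
  for (rid in ex) {
    met <- names(model$stoichiometry[[rid]])
    base <- sub("__[A-Z]$", "", sub("_[ce]$", "", met))
    i <- match(rid, model$reactions$id)
    if (tolower(base) %in% free_set) {
      model$reactions$lb[i] <- -1000
      model$reactions$ub[i] <- 1000
    } else if (!(rid %in% o2_ex)) {
      model$reactions$lb[i] <- max(model$reactions$lb[i], 0)
    }
  }
  if (!is.null(config$carbon_source)) {
    u <- config$uptake_rate
    if (is.null(u)) stop("carbon_source set but uptake_rate missing",
                         call. = FALSE)
    model <- set_bounds(model, config$carbon_source, lb = -u,
                        ub = if (config$uptake_mode == "fix") -u else 0)
  }
  if (identical(config$oxygen_rate, "free")) {
    for (rid in o2_ex) model <- set_bounds(model, rid, lb = -1000, ub = 1000)
  } else {
    r <- config$oxygen_rate
    for (rid in o2_ex) {
      model <- set_bounds(model, rid, lb = -r,
                          ub = if (config$uptake_mode == "fix") -r else 0)
    }
  }
  list(model = model)
}

#' Run a growth scenario
#'
#' Applies a scenario's pathway additions, deletions and medium settings
#' (the carbon source uptake fixed as an equality by default, oxygen free
#' unless pinned), maximizes the objective (biomass by default), resolves
#' alternate optima by total-flux minimization, and reports the growth
#' rate and fluxes normalized to 100 units of carbon-source uptake.
#'
#' @param model a `metabolic_model`.
#' @param config a `scenario_config` (or anything [read_scenario()]
#'   accepts).
#' @param check_uniqueness also run FVA at objective fraction `1 - 1e-6`
#'   and flag fluxes whose range exceeds `1e-5` as degenerate (slower).
#' @return object of class `scenario_result`: list with `name`,
#'   `growth_rate`, `status`, `distribution`, `fluxes` (data.frame with
#'   normalized fluxes and, if requested, a `degenerate` flag), and
#'   `provenance`.
#' @export
run_growth_scenario <- function(model, config, check_uniqueness = FALSE) {
  if (!inherits(config, "scenario_config")) config <- read_scenario(config)
  prep <- .scenario_model(model, config)
  m <- prep$model
  objective <- config$objective %||% m$objective
  sol <- tryCatch(
    minimize_total_flux_at_optimum(m, objective = objective),
    error = function(e) solve_fba(m, objective = objective)
  )
  if (sol$status != "optimal") {
    res <- list(name = config$name, growth_rate = 0, status = sol$status,
                distribution = sol, fluxes = NULL,
                provenance = .provenance(model, config))
    class(res) <- "scenario_result"
    return(res)
  }
  fluxes <- data.frame(reaction_id = names(sol$fluxes),
                       flux = as.numeric(sol$fluxes),
                       stringsAsFactors = FALSE)
  if (!is.null(config$carbon_source)) {
    ref <- abs(sol$fluxes[[config$carbon_source]])
    fluxes$normalized <- if (ref > 1e-9) 100 * fluxes$flux / ref else
      NA_real_
  }
  if (check_uniqueness) {
    mfix <- m
    j <- match(objective, mfix$reactions$id)
    opt <- sol$fluxes[[objective]]
    mfix$reactions$lb[j] <- max(mfix$reactions$lb[j],
                                opt - abs(opt) * 1e-6 - 1e-9)
    fva <- solve_fva(mfix, objective_fraction = 0)
    width <- fva$max - fva$min
    fluxes$degenerate <- width[match(fluxes$reaction_id,
                                     fva$reaction_id)] > 1e-5
  }
  res <- list(name = config$name,
              growth_rate = sol$fluxes[[objective]],
              status = "optimal", distribution = sol, fluxes = fluxes,
              provenance = .provenance(model, config))
  class(res) <- "scenario_result"
  res
}

.provenance <- function(model, config, extra = list()) {
  c(list(model_digest = model_digest(model),
         config = unclass(config),
         package_version = as.character(utils::packageVersion("mustflux")),
         lp_tolerances = c(feasibility = 1e-9, optimality = 1e-7),
         seed = 20170630),
    extra)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: status %s, growth rate %s 1/h\n",
              x$name, x$status, format(x$growth_rate, digits = 6)))
  invisible(x)
}

#' Normalize a scenario's fluxes to a reference reaction and write reports
#'
#' Scales every flux to 100 units of the reference flux magnitude (the
#' convention for central-carbon flux maps normalized to glucose uptake =
#' 100) and optionally writes a TSV report.
#'
#' @param result a `scenario_result` with status `"optimal"`.
#' @param reference_reaction_id reaction whose flux magnitude becomes 100.
#' @param path optional output TSV path.
#' @return data.frame with columns `reaction_id`, `flux`, `normalized`
#'   (and `degenerate` if present in the result).
#' @export
normalize_and_report <- function(result, reference_reaction_id,
                                 path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (result$status != "optimal") {
    stop("scenario result is not optimal", call. = FALSE)
  }
  v <- result$distribution$fluxes
  ref <- abs(v[[reference_reaction_id]])
  if (!is.finite(ref) || ref < 1e-9) {
    stop(sprintf("reference reaction '%s' carries zero flux",
                 reference_reaction_id), call. = FALSE)
  }
  out <- data.frame(reaction_id = names(v), flux = as.numeric(v),
                    normalized = 100 * as.numeric(v) / ref,
                    stringsAsFactors = FALSE)
  if (!is.null(result$fluxes) && "degenerate" %in% names(result$fluxes)) {
    out$degenerate <- result$fluxes$degenerate[
      match(out$reaction_id, result$fluxes$reaction_id)]
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
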