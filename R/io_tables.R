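# Tabular model dialect.
#
# Reaction table columns: id, name, equation, gpr, lb, ub, subsystem,
# and optionally delta_r_g_prime. Metabolite table columns: id, name,
# formula, charge, compartment. Equations follow
#   [coeff] met { + [coeff] met }  (-> | <=>)  [coeff] met { + ... }
# with coefficients defaulting to 1 and metabolite compartments written
# either as a suffix tag "met[c]" or an underscore suffix "met_c" (both
# accepted on input; "met_c" is always emitted).

.detect_delim <- function(header_line) {
  counts <- c("\t" = lengths(regmatches(header_line,
                                        gregexpr("\t", header_line))),
              "," = lengths(regmatches(header_line,
                                       gregexpr(",", header_line))),
              ";" = lengths(regmatches(header_line,
                                       gregexpr(";", header_line))))
  if (max(counts) == 0L) return("\t")
  best <- names(counts)[counts == max(counts)]
  if ("\t" %in% best) "\t" else best[1]
}

.read_delim_auto <- function(path_or_text) {
  lines <- if (length(path_or_text) == 1L && file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE)
  } else {
    unlist(strsplit(paste(path_or_text, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(NULL)
  delim <- .detect_delim(lines[1])
  utils::read.table(text = paste(lines, collapse = "\n"), sep = delim,
                    header = TRUE, stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "", check.names = TRUE)
}

#' Normalize a metabolite id to underscore-compartment form
#'
#' Accepts both `met[c]` and `met_c` spellings; returns `met_c`.
#' @param id metabolite id token.
#' @return normalized id.
#' @export
normalize_met_id <- function(id) {
  sub("\\[([ce])\\]$", "_\\1", trimws(id))
}

#' Parse a reaction equation string
#'
#' @param text equation, e.g. `"g6p[c] + nadp[c] -> 6pgc[c] + nadph[c]"`.
#' @return list with `stoichiometry` (named numeric, negative = consumed)
#'   and `reversible` (logical).
#' @export
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrow <- regmatches(text, regexpr("<=>|<->|-->|->", text))
  if (length(arrow) == 0L) {
    stop(sprintf("equation '%s': no reaction arrow (-> or <=>)", text),
         call. = FALSE)
  }
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(text, "<=>|<->|-->|->")[[1]]
  lhs <- trimws(sides[1])
  rhs <- if (length(sides) >= 2L) trimws(sides[2]) else ""
  if (!nzchar(lhs) && !nzchar(rhs)) {
    stop(sprintf("equation '%s': both sides empty", text), call. = FALSE)
  }
  parse_side <- function(side, sign) {
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (term in terms) {
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        coeff <- 1
        met <- toks[1]
      } else if (length(toks) == 2L &&
                 grepl("^[0-9.]+([eE][+-]?[0-9]+)?$", toks[1])) {
        coeff <- as.numeric(toks[1])
        met <- toks[2]
      } else {
        stop(sprintf("equation term '%s' not parseable", term),
             call. = FALSE)
      }
      met <- normalize_met_id(met)
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coeff
    }
    out
  }
  left <- parse_side(lhs, -1)
  right <- parse_side(rhs, +1)
  # a one-sided equation is the exchange/sink form "a_e <=>"; a multi-
  # metabolite reaction with a missing side is malformed
  if ((length(left) == 0L && length(right) > 1L) ||
      (length(right) == 0L && length(left) > 1L)) {
    stop(sprintf("equation '%s': one side empty but the other has several metabolites",
                 text), call. = FALSE)
  }
  st <- left
  for (m in names(right)) {
    st[m] <- (if (m %in% names(st)) st[[m]] else 0) + right[[m]]
  }
  st <- st[abs(st) > 0]
  if (length(st) == 0L) {
    stop(sprintf("equation '%s': all coefficients cancel", text),
         call. = FALSE)
  }
  list(stoichiometry = st, reversible = reversible)
}

#' Write a stoichiometry back to an equation string
#'
#' @param stoichiometry named numeric vector (negative = consumed).
#' @param reversible emit `<=>` instead of `->`.
#' @return equation string in the `met_c` spelling.
#' @export
write_equation <- function(stoichiometry, reversible = FALSE) {
  fmt_side <- function(s) {
    if (length(s) == 0L) return("")
    paste(vapply(names(s), function(m) {
      coeff <- s[[m]]
      if (abs(coeff - 1) < 1e-12) m else paste(format(coeff, digits = 12), m)
    }, character(1)), collapse = " + ")
  }
  lhs <- -stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt_side(lhs), if (reversible) "<=>" else "->", fmt_side(rhs))
}

#' Read a model from reaction and metabolite tables
#'
#' The delimiter (tab, comma or semicolon) is auto-detected from the header
#' line. Reversible equations (`<=>`) default to bounds
#' `(-default_max, default_max)` and irreversible ones to
#' `(0, default_max)`; explicit `lb`/`ub` columns override. Column names
#' can be remapped for supplementary spreadsheets whose layout differs.
#'
#' @param reaction_table path to (or character vector of lines of) the
#'   reaction table with columns id, name, equation, gpr, lb, ub,
#'   subsystem, and optionally delta_r_g_prime.
#' @param metabolite_table path/lines of the metabolite table with columns
#'   id, name, formula, charge, compartment.
#' @param objective objective reaction id; defaults to the first reaction
#'   whose id or name contains "biomass" (case-insensitive), else `NA`.
#' @param default_max bound magnitude used when lb/ub are absent (default
#'   1000 mmol/gDCW/h).
#' @param reaction_columns,metabolite_columns optional named character
#'   vectors remapping expected column names to the file's actual names,
#'   e.g. `c(equation = "Reaction formula")`.
#' @param quiet suppress the entity-count message.
#' @return a `metabolic_model`.
#' @export
read_model_tables <- function(reaction_table, metabolite_table,
                              objective = NULL, default_max = 1000,
                              reaction_columns = NULL,
                              metabolite_columns = NULL, quiet = FALSE) {
  rxt <- .read_delim_auto(reaction_table)
  mtt <- .read_delim_auto(metabolite_table)
  if (is.null(rxt) || is.null(mtt)) {
    stop("empty reaction or metabolite table", call. = FALSE)
  }
  remap <- function(df, map) {
    if (is.null(map)) return(df)
    for (want in names(map)) {
      have <- make.names(map[[want]])
      if (have %in% names(df)) names(df)[names(df) == have] <- want
    }
    df
  }
  rxt <- remap(rxt, reaction_columns)
  mtt <- remap(mtt, metabolite_columns)
  need_m <- c("id", "name", "formula", "charge", "compartment")
  miss <- setdiff(need_m, names(mtt))
  if (length(miss) > 0L) {
    stop(sprintf("metabolite table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  need_r <- c("id", "equation")
  miss <- setdiff(need_r, names(rxt))
  if (length(miss) > 0L) {
    stop(sprintf("reaction table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  mtt$id <- normalize_met_id(as.character(mtt$id))
  mtt$formula[is.na(mtt$formula)] <- ""
  mets <- data.frame(id = mtt$id, name = as.character(mtt$name),
                     formula = as.character(mtt$formula),
                     charge = as.integer(mtt$charge),
                     compartment = as.character(mtt$compartment),
                     stringsAsFactors = FALSE)

  col_or <- function(df, col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  rx_name <- as.character(col_or(rxt, "name", NA_character_))
  rx_gpr <- as.character(col_or(rxt, "gpr", ""))
  rx_gpr[is.na(rx_gpr)] <- ""
  rx_lb <- suppressWarnings(as.numeric(col_or(rxt, "lb", NA_real_)))
  rx_ub <- suppressWarnings(as.numeric(col_or(rxt, "ub", NA_real_)))
  rx_sub <- as.character(col_or(rxt, "subsystem", ""))
  rx_sub[is.na(rx_sub)] <- ""
  rx_drg <- suppressWarnings(as.numeric(col_or(rxt, "delta_r_g_prime",
                                               NA_real_)))
  reactions <- vector("list", nrow(rxt))
  for (i in seq_len(nrow(rxt))) {
    rid <- as.character(rxt$id[i])
    eq <- tryCatch(parse_equation(as.character(rxt$equation[i])),
                   error = function(e) {
                     stop(sprintf("reaction '%s': %s", rid,
                                  conditionMessage(e)), call. = FALSE)
                   })
    unknown <- setdiff(names(eq$stoichiometry), mets$id)
    if (length(unknown) > 0L) {
      stop(sprintf("reaction '%s': unknown metabolite(s) %s", rid,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    lb <- if (!is.na(rx_lb[i])) rx_lb[i] else
      if (eq$reversible) -default_max else 0
    ub <- if (!is.na(rx_ub[i])) rx_ub[i] else default_max
    reactions[[i]] <- reaction(
      id = rid, stoichiometry = eq$stoichiometry,
      name = if (is.na(rx_name[i])) rid else rx_name[i],
      lb = lb, ub = ub, gpr = rx_gpr[i], subsystem = rx_sub[i],
      drg = rx_drg[i]
    )
  }
  model <- metabolic_model(mets, reactions, objective = NA_character_)
  if (is.null(objective)) {
    hit <- grepl("biomass", model$reactions$id, ignore.case = TRUE) |
      grepl("biomass", model$reactions$name, ignore.case = TRUE)
    objective <- if (any(hit)) model$reactions$id[which(hit)[1]] else
      NA_character_
  }
  if (is.na(objective) && "objective" %in% names(rxt)) {
    flag <- suppressWarnings(as.logical(rxt$objective))
    if (any(flag, na.rm = TRUE)) {
      objective <- as.character(rxt$id[which(flag)[1]])
    }
  }
  model$objective <- objective
  validate_model(model)
  if (!quiet) {
    message(sprintf("loaded model: %d genes, %d metabolites, %d reactions",
                    length(model$genes), nrow(model$metabolites),
                    nrow(model$reactions)))
  }
  model
}

#' Write a model to reaction and metabolite tables
#'
#' @param model a `metabolic_model`.
#' @param reaction_path,metabolite_path output TSV paths.
#' @return invisibly, a list of the two paths.
#' @export
write_model_tables <- function(model, reaction_path, metabolite_path) {
  rx <- model$reactions
  eqs <- vapply(rx$id, function(rid) {
    write_equation(model$stoichiometry[[rid]],
                   reversible = rx$lb[match(rid, rx$id)] < 0)
  }, character(1))
  rxt <- data.frame(id = rx$id, name = rx$name, equation = eqs,
                    gpr = rx$gpr, lb = rx$lb, ub = rx$ub,
                    subsystem = rx$subsystem, delta_r_g_prime = rx$drg,
                    objective = !is.na(model$objective) &
                      rx$id == model$objective,
                    stringsAsFactors = FALSE)
  utils::write.table(rxt, reaction_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$metabolites, metabolite_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(reactions = reaction_path, metabolites = metabolite_path))
}

#' Read a flux-bound constraint table
#'
#' Columns: reaction id, lower, upper, and optionally mode
#' (`override`/`tighten`). This is the carrier for 13C-tracer experimental
#' flux intervals.
#'
#' @param table path to (or lines of) the delimited table.
#' @return a `constraint_set`; an empty file gives an empty set.
#' @export
read_constraint_table <- function(table) {
  df <- .read_delim_auto(table)
  if (is.null(df) || nrow(df) == 0L) return(constraint_set())
  names(df) <- tolower(names(df))
  id_col <- intersect(c("reaction_id", "reaction", "id"), names(df))[1]
  lb_col <- intersect(c("lb", "lower", "lower_bound"), names(df))[1]
  ub_col <- intersect(c("ub", "upper", "upper_bound"), names(df))[1]
  if (is.na(id_col) || is.na(lb_col) || is.na(ub_col)) {
    stop("constraint table needs reaction id, lower and upper columns",
         call. = FALSE)
  }
  mode <- if ("mode" %in% names(df)) df$mode else "override"
  constraint_set(as.character(df[[id_col]]), as.numeric(df[[lb_col]]),
                 as.numeric(df[[ub_col]]), mode = mode)
}

#' Write a constraint set to TSV
#' @param constraints a `constraint_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_constraint_table <- function(constraints, path) {
  utils::write.table(as.data.frame(constraints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
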