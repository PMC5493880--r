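#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules associate genes with the reaction they enable: `and` joins
#' subunits of a complex (all required), `or` joins isoenzymes (any
#' suffices). The grammar accepts gene identifiers, the case-insensitive
#' keywords `and`/`or`, and parentheses; `and` binds tighter than `or`.
#' The empty string denotes a spontaneous or orphan reaction with no gene
#' requirement.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return an object of class `gpr`: either `NULL` wrapped as an empty
#'   rule, or a nested list tree with nodes `list(op = "and"|"or",
#'   args = list(...))` and character leaves.
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  toks <- .gpr_tokenize(text)
  if (length(toks) == 0L) {
    return(structure(list(tree = NULL), class = "gpr"))
  }
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error: unexpected token '%s'", st$toks[st$pos]),
         call. = FALSE)
  }
  structure(list(tree = tree), class = "gpr")
}

.gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

.gpr_parse_or <- function(st) {
  args <- list(.gpr_parse_and(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_parse_and <- function(st) {
  args <- list(.gpr_parse_atom(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_parse_atom <- function(st) {
  tk <- .gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: dangling operator", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st)
    if (is.na(.gpr_peek(st)) || .gpr_peek(st) != ")") {
      stop("GPR parse error: unbalanced parentheses", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop(sprintf("GPR parse error: unexpected token '%s'", tk), call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' A leaf gene is active unless it is deleted; `and`/`or` nodes follow
#' boolean logic. The empty rule is always active: reactions with no gene
#' association (spontaneous or orphan reactions) can never be switched off
#' by a genetic intervention.
#'
#' @param gpr a `gpr` object from [parse_gpr()] (a plain string is also
#'   accepted and parsed on the fly).
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains available, `FALSE` otherwise.
#' @export
evaluate_gpr <- function(gpr, deleted = character(0)) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  stopifnot(inherits(gpr, "gpr"))
  if (is.null(gpr$tree)) return(TRUE)
  .gpr_eval(gpr$tree, deleted)
}

.gpr_eval <- function(node, deleted) {
  if (is.character(node)) return(!(node %in% deleted))
  vals <- vapply(node$args, .gpr_eval, logical(1), deleted = deleted)
  if (node$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#' @param gpr a `gpr` object or GPR string.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr$tree)) return(character(0))
  collect <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect), use.names = FALSE)
  }
  unique(collect(gpr$tree))
}

#' Render a GPR rule back to its string form
#' @param gpr a `gpr` object.
#' @return a GPR string; `""` for the empty rule.
#' @export
deparse_gpr <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  if (is.null(gpr$tree)) return("")
  render <- function(node, parent_op = NULL) {
    if (is.character(node)) return(node)
    parts <- vapply(node$args, render, character(1), parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && node$op == "or" && parent_op == "and") {
      s <- paste0("(", s, ")")
    }
    s
  }
  render(gpr$tree)
}

#' @export
print.gpr <- function(x, ...) {
  s <- deparse_gpr(x)
  cat("<gpr> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}
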