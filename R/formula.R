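#' Parse a chemical formula into an elemental composition
#'
#' Formulas follow the usual Hill-style grammar: a sequence of element
#' tokens, each an uppercase letter optionally followed by one lowercase
#' letter, optionally followed by an integer count (default 1).
#' Repeated elements are summed, so `"CH3COOH"` and `"C2H4O2"` parse to the
#' same composition.
#'
#' @param text a single formula string, e.g. `"C6H12O6"`.
#' @return named integer vector of element counts, names sorted
#'   alphabetically.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(stats::setNames(integer(0), character(0)))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- character(0)
  counts <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (!grepl("^[A-Z]$", ch)) {
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   text, ch, i), call. = FALSE)
    }
    sym <- ch
    i <- i + 1L
    if (i <= n && grepl("^[a-z]$", chars[i])) {
      sym <- paste0(sym, chars[i])
      i <- i + 1L
    }
    num <- ""
    while (i <= n && grepl("^[0-9]$", chars[i])) {
      num <- paste0(num, chars[i])
      i <- i + 1L
    }
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    elements <- c(elements, sym)
    counts <- c(counts, cnt)
  }
  out <- tapply(counts, elements, sum)
  res <- as.integer(out)
  names(res) <- names(out)
  res[order(names(res))]
}

#' Write an elemental composition back to a canonical formula string
#'
#' Elements are emitted in Hill order (C first, then H, then the rest
#' alphabetically); counts of 1 are omitted and zero-count elements are
#' dropped, so `write_formula(parse_formula(x))` is the canonical form of
#' `x`.
#'
#' @param composition named integer vector as returned by [parse_formula()].
#' @return a single formula string (empty string for an empty composition).
#' @export
write_formula <- function(composition) {
  composition <- composition[composition != 0]
  if (length(composition) == 0L) return("")
  syms <- names(composition)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(hill, function(s) {
    cnt <- composition[[s]]
    if (cnt == 1L) s else paste0(s, cnt)
  }, character(1)), collapse = "")
}

# IUPAC 2021 conventional atomic weights for the elements that occur in
# metabolic reconstructions. "R" and "X" are generic residue placeholders
# with no defined mass.
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ar = 39.95, Ca = 40.078, Mn = 54.938, Fe = 55.845, Ni = 58.693,
  Co = 58.933, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904,
  Mo = 95.95, I = 126.90, W = 183.84
)

#' Molecular weight of a composition or formula
#'
#' @param x either a formula string or a named count vector from
#'   [parse_formula()].
#' @return molecular weight in g/mol. Generic residue symbols ("R", "X")
#'   have no mass and raise an error.
#' @export
molecular_weight <- function(x) {
  comp <- if (is.character(x)) parse_formula(x) else x
  if (length(comp) == 0L) return(0)
  unknown <- setdiff(names(comp), names(.atomic_weights))
  if (length(unknown) > 0L) {
    stop(sprintf("no atomic weight for element(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sum(.atomic_weights[names(comp)] * comp)
}
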