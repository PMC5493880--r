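# Independent oracles used across the suite.

# Dense-LP oracle by exhaustive basic-solution enumeration: every vertex
# of {A v = b, lb <= v <= ub} has n - rank(A) variables at a bound; the
# optimum of a bounded feasible LP is attained at such a vertex. This is
# an implementation entirely separate from the package's simplex solver
# and is exact for the toy fixtures (<= ~12 free variables).
oracle_lp_enumerate <- function(obj, A, b, lb, ub, sense = "max",
                                tol = 1e-8) {
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  best <- NULL
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(invisible(NULL))
    if (max(abs(A %*% v - b)) > 1e-6) return(invisible(NULL))
    val <- sum(obj * v)
    if (is.null(best) ||
        (sense == "max" && val > best$value) ||
        (sense == "min" && val < best$value)) {
      best <<- list(value = val, v = v)
    }
    invisible(NULL)
  }
  if (k == 0L) {
    sol <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
    if (!is.null(sol)) consider(as.numeric(sol))
  } else {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      nb <- combos[, ci]
      bs <- setdiff(seq_len(n), nb)
      Ab <- A[, bs, drop = FALSE]
      if (qr(Ab)$rank < r) next
      # each nonbasic variable at its lower or upper bound
      for (mask in 0:(2^k - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
        vn <- ifelse(at_ub, ub[nb], lb[nb])
        rhs <- b - as.numeric(A[, nb, drop = FALSE] %*% vn)
        xb <- tryCatch(qr.solve(Ab, rhs, tol = 1e-12),
                       error = function(e) NULL)
        if (is.null(xb)) next
        v <- numeric(n)
        v[nb] <- vn
        v[bs] <- as.numeric(xb)
        consider(v)
      }
    }
  }
  if (is.null(best)) return(list(status = "infeasible", value = NA_real_))
  list(status = "optimal", value = best$value, v = best$v)
}

# Optimize one reaction's flux over S v = 0, lb <= v <= ub, optionally
# with a floor on another reaction (the FVA objective cut), via the
# enumeration oracle. A slack variable turns the floor into an equality.
oracle_optimum <- function(model, objective, sense = "max",
                           floor_reaction = NULL, floor_value = NULL) {
  S <- build_stoichiometric_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(objective, model$reactions$id)] <- 1
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(floor_reaction)) {
    row <- numeric(n)
    row[match(floor_reaction, model$reactions$id)] <- 1
    A <- rbind(A, row)
    A <- cbind(A, c(rep(0, nrow(S)), -1))  # slack: row.v - s = floor
    b <- c(b, floor_value)
    obj <- c(obj, 0)
    lb <- c(lb, 0)
    ub <- c(ub, 1e7)
  }
  res <- oracle_lp_enumerate(obj, A, b, lb, ub, sense = sense)
  if (res$status == "optimal") {
    res$v <- res$v[seq_len(n)]
  }
  res
}

# Independent GPR evaluator: textual translation of the rule into an R
# logical expression, evaluated with R's own parser.
oracle_gpr_eval <- function(gpr_string, deleted, genes) {
  if (!nzchar(gpr_string)) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", gpr_string,
                                      ignore.case = TRUE),
               ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# random GPR tree of bounded depth over the given genes
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- vapply(seq_len(k), function(i) random_gpr(genes, depth - 1),
                 character(1))
  paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}

minicore_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_minicore_model()
    m
  }
})

wt_state_cached <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- minicore_wt_fluxes(minicore_cached())
    s
  }
})

# pinned digest of the mini central-carbon fixture (versioned data)
MINICORE_DIGEST <- "d71190f5fd96551b4b1b28b91c109a55"
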