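# Dense bounded-variable two-phase simplex.
#
# Solves   optimize  c'x   subject to  A x = b,  lb <= x <= ub.
# This is the whole LP zoo needed for constraint-based modeling: FBA, FVA,
# parsimonious flux minimization and flux spans all reduce to this form
# because the objective and every side condition act on single fluxes
# (bounds) or on the steady-state system (equalities).
#
# Variable bounds stay out of the constraint matrix: a nonbasic variable
# rests at its lower bound, its upper bound, or (generalized start) at a
# fixed interior value, which lets the solve begin at the all-zero flux
# point. Phase 1 minimizes artificial variables; pricing is Dantzig with a
# Bland fallback to guarantee termination under degeneracy.

.LP_INF <- 1e30

#' Solve a bounded linear program
#'
#' @param obj objective coefficient vector (length n).
#' @param A dense equality-constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n); magnitudes `>= 1e30` are
#'   treated as infinite.
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility tolerance (default 1e-9).
#' @param opt_tol optimality (reduced-cost) tolerance (default 1e-7).
#' @return list with `x` (solution, length n), `objective`, and `status`
#'   (`"optimal"`, `"infeasible"`, or `"unbounded"`).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, opt_tol = 1e-7) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n,
            length(ub) == n, all(lb <= ub))
  m <- nrow(A)
  cost <- if (sense == "max") -obj else obj

  lo <- ifelse(lb <= -.LP_INF, -Inf, lb)
  hi <- ifelse(ub >= .LP_INF, Inf, ub)

  if (m == 0L) {
    x <- ifelse(cost > 0, lo, ifelse(cost < 0, hi, pmax(lo, pmin(0, hi))))
    if (any(!is.finite(x) & cost != 0)) {
      return(list(x = rep(NA_real_, n), objective = NA_real_,
                  status = "unbounded"))
    }
    x[!is.finite(x)] <- 0
    return(list(x = x, objective = sum(obj * x), status = "optimal"))
  }

  # start at the point nearest zero inside the box
  x0 <- pmax(lo, pmin(0, hi))
  x0[!is.finite(x0)] <- 0

  r <- as.numeric(b - A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  ntot <- n + m
  env <- new.env(parent = emptyenv())
  env$lo <- c(lo, rep(0, m))
  env$hi <- c(hi, rep(Inf, m))
  env$x <- c(x0, abs(r))
  env$basis <- (n + 1L):ntot
  env$in_basis <- c(rep(FALSE, n), rep(TRUE, m))
  # nonbasic rest position: 1 = at lower bound, 2 = at upper, 3 = interior
  env$pos <- integer(ntot)
  env$pos[env$x <= env$lo + 1e-12] <- 1L
  env$pos[env$x >= env$hi - 1e-12] <- 2L
  env$pos[env$pos == 0L] <- 3L

  run_phase <- function(phase_cost) {
    iter <- 0L
    max_iter <- 200L * (ntot + m) + 5000L
    stall <- 0L
    bland <- FALSE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("simplex iteration limit exceeded", call. = FALSE)
      }
      B <- Afull[, env$basis, drop = FALSE]
      y <- tryCatch(solve(t(B), phase_cost[env$basis]),
                    error = function(e) qr.solve(t(B),
                                                 phase_cost[env$basis],
                                                 tol = 1e-12))
      nb <- which(!env$in_basis)
      d <- phase_cost[nb] -
        as.numeric(crossprod(Afull[, nb, drop = FALSE], y))
      pos_nb <- env$pos[nb]
      inc_ok <- (pos_nb == 1L | pos_nb == 3L) & d < -opt_tol
      dec_ok <- (pos_nb == 2L | pos_nb == 3L) & d > opt_tol
      cand <- which(inc_ok | dec_ok)
      if (length(cand) == 0L) return("optimal")
      pick <- if (bland) cand[which.min(nb[cand])] else
        cand[which.max(abs(d[cand]))]
      e <- nb[pick]
      dir <- if (inc_ok[pick]) 1 else -1

      w <- tryCatch(solve(B, Afull[, e]),
                    error = function(e2) qr.solve(B, Afull[, e],
                                                  tol = 1e-12))
      delta <- -dir * w  # movement of basic variables per unit step
      t_self <- if (dir > 0) env$hi[e] - env$x[e] else env$x[e] - env$lo[e]
      t_best <- t_self
      leave_pos <- 0L
      leave_to_lb <- TRUE
      for (i in seq_len(m)) {
        bi <- env$basis[i]
        if (delta[i] > tol) {
          if (is.finite(env$hi[bi])) {
            tt <- (env$hi[bi] - env$x[bi]) / delta[i]
            if (tt < t_best - 1e-12 ||
                (bland && tt <= t_best + 1e-12 &&
                 (leave_pos == 0L || bi < env$basis[leave_pos]))) {
              t_best <- max(tt, 0); leave_pos <- i; leave_to_lb <- FALSE
            }
          }
        } else if (delta[i] < -tol) {
          if (is.finite(env$lo[bi])) {
            tt <- (env$lo[bi] - env$x[bi]) / delta[i]
            if (tt < t_best - 1e-12 ||
                (bland && tt <= t_best + 1e-12 &&
                 (leave_pos == 0L || bi < env$basis[leave_pos]))) {
              t_best <- max(tt, 0); leave_pos <- i; leave_to_lb <- TRUE
            }
          }
        }
      }
      if (!is.finite(t_best)) return("unbounded")
      if (t_best <= tol) {
        stall <- stall + 1L
        if (stall >= 30L) bland <- TRUE
      } else {
        stall <- 0L
      }
      env$x[e] <- env$x[e] + dir * t_best
      env$x[env$basis] <- env$x[env$basis] + delta * t_best
      if (leave_pos == 0L) {
        # entering variable hit its own opposite bound: bound flip
        env$pos[e] <- if (dir > 0) 2L else 1L
      } else {
        lv <- env$basis[leave_pos]
        env$x[lv] <- if (leave_to_lb) env$lo[lv] else env$hi[lv]
        env$pos[lv] <- if (leave_to_lb) 1L else 2L
        env$basis[leave_pos] <- e
        env$in_basis[e] <- TRUE
        env$in_basis[lv] <- FALSE
      }
    }
  }

  # phase 1: drive the artificial variables to zero
  if (sum(env$x[(n + 1L):ntot]) > tol) {
    st <- run_phase(c(rep(0, n), rep(1, m)))
    if (st == "unbounded") {
      stop("phase-1 LP unbounded (internal error)", call. = FALSE)
    }
    if (sum(env$x[(n + 1L):ntot]) > tol * max(1, max(abs(b)))) {
      return(list(x = rep(NA_real_, n), objective = NA_real_,
                  status = "infeasible"))
    }
  }

  # phase 2: pin artificials at zero and optimize the true cost
  env$hi[(n + 1L):ntot] <- 0
  env$x[(n + 1L):ntot] <- 0
  env$pos[(n + 1L):ntot] <- 1L
  st <- run_phase(c(cost, rep(0, m)))
  if (st == "unbounded") {
    return(list(x = rep(NA_real_, n), objective = NA_real_,
                status = "unbounded"))
  }
  xs <- env$x[seq_len(n)]
  list(x = xs, objective = sum(obj * xs), status = "optimal")
}
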