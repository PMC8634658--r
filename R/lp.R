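#' @title Linear programming: bounded-variable simplex
#'
#' @description Solves `max/min c'x  s.t.  A x = b,  lb <= x <= ub` with a
#' dense two-phase primal simplex on bounded variables. Bland's rule is used
#' throughout, so the method cannot cycle; the price paid in iteration count
#' is irrelevant at the problem sizes this package targets (tens of
#' variables). The basis system is re-factorised at every pivot via
#' [solve()], trading speed for numerical transparency.
#'
#' No installed R package provides an LP solver in this toolchain, and the
#' LP is the analytical heart of flux balance analysis, so the solver lives
#' here rather than behind an external dependency.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense or sparse constraint matrix (m x n); coerced to dense.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; `FALSE` minimises.
#' @param tol pivot/optimality tolerance.
#'
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective`, and `x` (primal solution, length n; `NA` unless optimal).
#' @keywords internal
lp_simplex <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (m == 0L) {
    # box-only problem: optimum at bounds
    x <- ifelse((obj > 0) == maximize, ub, lb)
    x[obj == 0] <- pmin(pmax(0, lb), ub)[obj == 0]
    if (any(!is.finite(x) & obj != 0)) {
      return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                  x = rep(NA_real_, n)))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }
  sense <- if (maximize) 1 else -1

  # start every structural variable exactly on its finite bound of smaller
  # magnitude (nonbasic variables must sit on a bound); free variables at 0
  x0 <- ifelse(is.finite(lb) & is.finite(ub),
               ifelse(abs(lb) <= abs(ub), lb, ub),
               ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0)))
  resid <- b - as.vector(A %*% x0)

  # artificial columns: signed identity so artificial values start >= 0
  sgn <- ifelse(resid >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  ntot <- n + m

  basis <- n + seq_len(m)
  # status of nonbasic variables: TRUE = at lower bound
  at_lb <- x0 == lb
  at_lb[!is.finite(lb)] <- FALSE
  at_lb[!is.finite(lb) & !is.finite(ub)] <- TRUE     # free var pegged at 0
  xval <- c(x0, abs(resid))

  run_phase <- function(cost, basis, at_lb, xval) {
    maxit <- 200L * (ntot + 5L)
    for (it in seq_len(maxit)) {
      B <- Aext[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(ntot), basis)
      xN <- xval[nonbasic]
      rhs <- b - if (length(nonbasic)) as.vector(Aext[, nonbasic, drop = FALSE] %*% xN) else 0
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(ok = FALSE))
      xval[basis] <- xB
      y <- solve(t(B), cost[basis])
      d <- cost[nonbasic] - as.vector(t(Aext[, nonbasic, drop = FALSE]) %*% y)
      lbn <- at_lb[nonbasic]
      freev <- !is.finite(lbe[nonbasic]) & !is.finite(ube[nonbasic])
      elig <- (!freev & ((lbn & d > tol) | (!lbn & d < -tol))) |
        (freev & abs(d) > tol)
      if (!any(elig)) {
        return(list(ok = TRUE, status = "optimal", basis = basis,
                    at_lb = at_lb, xval = xval))
      }
      pick <- which(elig)[which.min(nonbasic[elig])]      # Bland: smallest index
      q <- nonbasic[pick]
      up <- if (freev[pick]) d[pick] > 0 else at_lb[q]    # entering increases?
      w <- solve(B, Aext[, q])
      dxB <- if (up) -w else w
      # ratio test
      tmax <- Inf; leave <- 0L; leave_to_lb <- TRUE
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (dxB[i] < -tol && is.finite(lbe[bi])) {
          ti <- (xval[bi] - lbe[bi]) / (-dxB[i])
          if (ti < tmax - tol || (ti < tmax + tol && (leave == 0L || bi < basis[leave]))) {
            tmax <- ti; leave <- i; leave_to_lb <- TRUE
          }
        } else if (dxB[i] > tol && is.finite(ube[bi])) {
          ti <- (ube[bi] - xval[bi]) / dxB[i]
          if (ti < tmax - tol || (ti < tmax + tol && (leave == 0L || bi < basis[leave]))) {
            tmax <- ti; leave <- i; leave_to_lb <- FALSE
          }
        }
      }
      tself <- if (is.finite(lbe[q]) && is.finite(ube[q])) ube[q] - lbe[q] else Inf
      if (!is.finite(tmax) && !is.finite(tself)) {
        return(list(ok = TRUE, status = "unbounded", basis = basis,
                    at_lb = at_lb, xval = xval))
      }
      if (tself <= tmax + tol && tself < Inf && (leave == 0L || tself <= tmax)) {
        # bound flip: entering variable crosses to its other bound
        xval[q] <- if (up) ube[q] else lbe[q]
        at_lb[q] <- !up
        xval[basis] <- xval[basis] + tmax_clip(dxB, tself)
        next
      }
      step <- max(tmax, 0)
      xval[basis] <- xval[basis] + dxB * step
      xval[q] <- xval[q] + (if (up) step else -step)
      out <- basis[leave]
      xval[out] <- if (leave_to_lb) lbe[out] else ube[out]
      at_lb[out] <- leave_to_lb
      basis[leave] <- q
    }
    list(ok = FALSE)
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, at_lb, xval)
  if (!isTRUE(p1$ok)) stop("LP solver failed to converge (phase 1)")
  art_sum <- sum(p1$xval[(n + 1):ntot])
  if (p1$status != "optimal" || art_sum > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  # pin artificials at zero and optimise the true objective
  ube[(n + 1):ntot] <- 0
  p1$xval[(n + 1):ntot] <- 0
  c2 <- c(sense * obj, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$at_lb, p1$xval)
  if (!isTRUE(p2$ok)) stop("LP solver failed to converge (phase 2)")
  if (p2$status == "unbounded") {
    return(list(status = "unbounded",
                objective = if (maximize) Inf else -Inf, x = rep(NA_real_, n)))
  }
  x <- p2$xval[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# helper used on bound flips: basic variables move by dxB * t
tmax_clip <- function(dxB, t) dxB * t

#' Solve a linear program with equality and inequality constraints
#'
#' Thin standard-form wrapper around [lp_simplex()]: inequality rows
#' `Aub x <= bub` receive slack variables with bounds `[0, Inf)`.
#'
#' @param obj objective coefficients.
#' @param Aeq,beq equality system (may be `NULL`).
#' @param Aub,bub inequality system (may be `NULL`).
#' @param lb,ub variable bounds.
#' @param maximize logical.
#' @return list with `status`, `objective`, `x`.
#' @keywords internal
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  Aeq <- if (is.null(Aeq)) matrix(0, 0, n) else as.matrix(Aeq)
  beq <- if (is.null(beq)) numeric(0) else beq
  Aub <- if (is.null(Aub)) matrix(0, 0, n) else as.matrix(Aub)
  bub <- if (is.null(bub)) numeric(0) else bub
  k <- nrow(Aub)
  if (k > 0L) {
    A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)),
               cbind(Aub, diag(1, k)))
    res <- lp_simplex(c(obj, rep(0, k)), A, c(beq, bub),
                      c(lb, rep(0, k)), c(ub, rep(Inf, k)), maximize)
    res$x <- res$x[seq_len(n)]
    res
  } else {
    lp_simplex(obj, Aeq, beq, lb, ub, maximize)
  }
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over the LP relaxation solved by
#' [lp_solve()]. Intended for the small binary-variable systems arising in
#' the loopless flux formulation, where the number of integer variables is
#' the number of loop-capable reactions (a handful).
#'
#' @param obj,Aeq,beq,Aub,bub,lb,ub,maximize as in [lp_solve()].
#' @param int_idx indices of variables constrained to integers.
#' @param int_tol integrality tolerance.
#' @return list with `status` ("optimal" or "infeasible"), `objective`, `x`.
#' @keywords internal
milp_solve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                       lb, ub, int_idx = integer(0), maximize = TRUE,
                       int_tol = 1e-6) {
  best <- list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, length(obj)))
  incumbent <- if (maximize) -Inf else Inf
  better <- function(a, b) if (maximize) a > b + 1e-9 else a < b - 1e-9
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(obj, Aeq, beq, Aub, bub, node$lb, node$ub, maximize)
    if (rel$status != "optimal") next
    if (is.finite(incumbent) && !better(rel$objective, incumbent)) next
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (length(int_idx) == 0L || all(frac <= int_tol)) {
      if (better(rel$objective, incumbent)) {
        incumbent <- rel$objective
        best <- list(status = "optimal", objective = rel$objective, x = rel$x)
      }
      next
    }
    j <- int_idx[which.max(frac)]
    v <- rel$x[j]
    lo <- node; hi <- node
    lo$ub[j] <- floor(v); hi$lb[j] <- ceiling(v)
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }
  best
}
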