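# Bounded-variable two-phase revised simplex and a branch-and-bound MILP core.
#
# The flux polytopes handled here are small and dense (at most a few hundred
# reactions), so the basis inverse is kept explicitly and refreshed by
# product-form eta updates with periodic refactorization. Dantzig pricing with
# a permanent switch to Bland's rule after a degeneracy stall guarantees
# termination.

LP_FEAS_TOL <- 1e-7
LP_OPT_TOL <- 1e-9
LP_PIVOT_TOL <- 1e-10

#' Solve a bounded linear program in equality form
#'
#' Maximizes (or minimizes) `obj' x` subject to `A x = b` and
#' `lb <= x <= ub`. Every variable must have at least one finite bound.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed on one side.
#' @param maximize logical; maximize when `TRUE` (default).
#' @param max_iter simplex pivot limit.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, max_iter = 50000L) {
  n <- length(obj)
  A <- as.matrix(A)
  if (n == 0L) {
    return(list(status = "optimal", objective = 0, x = numeric(0)))
  }
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (any(!is.finite(lb) & !is.finite(ub))) {
    stop("free variables (both bounds infinite) are not supported")
  }
  cc <- if (maximize) obj else -obj
  m <- nrow(A)

  if (m == 0L) {
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, ifelse(is.finite(lb), lb, ub)))
    if (any(!is.finite(x) & abs(cc[!is.finite(x)]) > 0)) {
      return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    }
    val <- sum(obj * x)
    return(list(status = "optimal", objective = val, x = x))
  }

  ## initial nonbasic placement: the finite bound of smaller magnitude
  start_at_lb <- is.finite(lb) & (!is.finite(ub) | abs(lb) <= abs(ub))
  x <- ifelse(start_at_lb, lb, ub)
  vstat <- ifelse(start_at_lb, 0L, 1L)   # 0 at lb, 1 at ub, 2 basic

  r <- b - as.vector(A %*% x)
  s <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(s, nrow = m, ncol = m))
  ntot <- n + m
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  x <- c(x, abs(r))
  vstat <- c(vstat, rep(2L, m))
  basis <- seq.int(n + 1L, n + m)
  ## B = diag(s) and s is +/-1, so Binv = diag(s)
  Binv <- diag(s, nrow = m, ncol = m)

  fixed <- (UB - LB) <= 1e-14

  run_phase <- function(cost, phase, x, vstat, basis, Binv, iter_budget) {
    stall <- 0L
    bland <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      if (it %% 60L == 0L) {
        Bm <- Afull[, basis, drop = FALSE]
        Binv_try <- tryCatch(solve(Bm), error = function(e) NULL)
        if (!is.null(Binv_try)) Binv <- Binv_try
      }
      if (it > iter_budget) stop("simplex iteration limit reached")
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost - as.vector(crossprod(Afull, y))
      elig_lo <- vstat == 0L & !fixed & d > LP_OPT_TOL
      elig_hi <- vstat == 1L & !fixed & d < -LP_OPT_TOL
      if (phase == 2L) {
        elig_lo[seq.int(n + 1L, ntot)] <- FALSE
        elig_hi[seq.int(n + 1L, ntot)] <- FALSE
      }
      cand <- which(elig_lo | elig_hi)
      if (length(cand) == 0L) {
        return(list(code = "optimal", x = x, vstat = vstat, basis = basis,
                    Binv = Binv))
      }
      j <- if (bland) cand[1L] else cand[which.max(abs(d[cand]))]
      dir <- if (vstat[j] == 0L) 1 else -1
      w <- as.vector(Binv %*% Afull[, j])

      ## ratio test over basic variables plus the entering variable's own range
      delta <- dir * w
      t_best <- UB[j] - LB[j]              # own-range flip
      leave <- 0L
      for (k in seq_len(m)) {
        dk <- delta[k]
        if (abs(dk) <= LP_PIVOT_TOL) next
        bk <- basis[k]
        tk <- if (dk > 0) (x[bk] - LB[bk]) / dk else (x[bk] - UB[bk]) / dk
        if (!is.finite(tk)) next
        if (tk < t_best - 1e-12 ||
            (leave > 0L && tk < t_best + 1e-12 &&
             abs(delta[k]) > abs(delta[leave]))) {
          t_best <- tk
          leave <- k
        }
      }
      if (!is.finite(t_best)) {
        if (phase == 1L) stop("numerical failure: unbounded phase-1 subproblem")
        return(list(code = "unbounded"))
      }
      t_best <- max(t_best, 0)
      if (t_best <= 1e-12) stall <- stall + 1L else stall <- 0L
      if (stall > 2L * ntot) bland <- TRUE

      ## apply step
      if (t_best > 0) {
        x[basis] <- x[basis] - t_best * delta
        x[j] <- x[j] + dir * t_best
      }
      if (leave == 0L) {
        vstat[j] <- if (vstat[j] == 0L) 1L else 0L
        x[j] <- if (vstat[j] == 0L) LB[j] else UB[j]
        next
      }
      out <- basis[leave]
      hit_lb <- dir * w[leave] > 0
      vstat[out] <- if (hit_lb) 0L else 1L
      x[out] <- if (hit_lb) LB[out] else UB[out]
      basis[leave] <- j
      vstat[j] <- 2L
      piv <- w[leave]
      Binv[leave, ] <- Binv[leave, ] / piv
      wadj <- w
      wadj[leave] <- 0
      Binv <- Binv - outer(wadj, Binv[leave, ])
    }
  }

  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, 1L, x, vstat, basis, Binv, max_iter)
  art_sum <- sum(p1$x[seq.int(n + 1L, ntot)])
  if (art_sum > LP_FEAS_TOL) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  ## pin artificials to zero for phase 2
  LB[seq.int(n + 1L, ntot)] <- 0
  UB[seq.int(n + 1L, ntot)] <- 0
  fixed[seq.int(n + 1L, ntot)] <- TRUE

  cost2 <- c(cc, rep(0, m))
  p2 <- run_phase(cost2, 2L, p1$x, p1$vstat, p1$basis, p1$Binv, max_iter)
  if (p2$code == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  xs <- p2$x[seq_len(n)]
  ## clip solver noise back into the box
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", objective = sum(obj * xs), x = xs)
}

#' Solve a linear program with mixed constraint directions
#'
#' Convenience wrapper around [lp_solve()] that converts `<=` and `>=` rows
#' to equalities by adding slack variables.
#'
#' @param dir character vector of "=", "<=" or ">=" per row of `A`.
#' @inheritParams lp_solve
#' @keywords internal
lp_solve_mixed <- function(obj, A, dir, rhs, lb, ub, maximize = TRUE,
                           max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(dir) == m, length(rhs) == m)
  slack_rows <- which(dir != "=")
  ns <- length(slack_rows)
  if (ns > 0L) {
    Sx <- matrix(0, m, ns)
    for (i in seq_len(ns)) {
      Sx[slack_rows[i], i] <- if (dir[slack_rows[i]] == "<=") 1 else -1
    }
    A <- cbind(A, Sx)
    obj2 <- c(obj, rep(0, ns))
    lb2 <- c(lb, rep(0, ns))
    ub2 <- c(ub, rep(Inf, ns))
  } else {
    obj2 <- obj; lb2 <- lb; ub2 <- ub
  }
  res <- lp_solve(obj2, A, rhs, lb2, ub2, maximize = maximize,
                  max_iter = max_iter)
  res$x <- res$x[seq_len(n)]
  if (res$status == "optimal") res$objective <- sum(obj * res$x)
  res
}

#' Branch-and-bound mixed-integer linear programming
#'
#' Minimizes (or maximizes) `obj' x` subject to `A x (dir) rhs`,
#' `lb <= x <= ub`, with the variables in `int_idx` required to take integer
#' values. Depth-first branch and bound on the LP relaxation, branching on
#' the most fractional integer variable; the down branch is explored first,
#' which biases the search toward sparse supports when minimizing a
#' cardinality objective.
#'
#' @inheritParams lp_solve_mixed
#' @param int_idx indices of integer-constrained variables.
#' @return list with `status`, `objective`, `x`.
#' @keywords internal
milp_solve <- function(obj, A, dir, rhs, lb, ub, int_idx,
                       maximize = FALSE, int_tol = 1e-6,
                       max_nodes = 100000L) {
  best <- list(objective = if (maximize) -Inf else Inf, x = NULL)
  sgn <- if (maximize) -1 else 1      # work in minimization internally
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) stop("branch-and-bound node limit reached")
    rel <- lp_solve_mixed(obj, A, dir, rhs, node$lb, node$ub,
                          maximize = maximize)
    if (rel$status != "optimal") next
    if (!is.null(best$x) &&
        sgn * rel$objective >= sgn * best$objective - 1e-9) next
    xi <- rel$x[int_idx]
    frac <- abs(xi - round(xi))
    if (all(frac <= int_tol)) {
      if (is.null(best$x) ||
          sgn * rel$objective < sgn * best$objective - 1e-9) {
        best <- list(objective = rel$objective, x = rel$x)
      }
      next
    }
    bvar <- int_idx[which.max(frac)]
    xv <- rel$x[bvar]
    up <- node; up$lb[bvar] <- ceiling(xv - int_tol)
    dn <- node; dn$ub[bvar] <- floor(xv + int_tol)
    ## push up first so the down branch pops first (depth-first)
    stack[[length(stack) + 1L]] <- up
    stack[[length(stack) + 1L]] <- dn
  }
  if (is.null(best$x)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  x <- best$x
  x[int_idx] <- round(x[int_idx])
  list(status = "optimal", objective = best$objective, x = x)
}
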