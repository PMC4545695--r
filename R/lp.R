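#' Solve a linear program with bounded variables
#'
#' Dense two-phase primal simplex for problems of the form
#' \deqn{\min c^T x \quad \text{s.t.} \quad A x \;(=,\le,\ge)\; b,\qquad
#'   l \le x \le u,}
#' where individual bounds may be infinite. This is the solver behind all
#' flux balance (FBA) and flux variability (FVA) computations in the
#' package. It is a bounded-variable simplex: variable bounds are handled
#' natively (nonbasic variables sit at a finite bound, free variables at
#' zero), inequality rows receive slack variables, and phase 1 minimises
#' the sum of row artificials. Dantzig pricing is used with a switch to
#' Bland's rule after a degeneracy threshold, which guarantees
#' termination.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix with `n` columns (may have zero rows).
#' @param rhs right-hand sides, one per row of `A`.
#' @param sense character vector per row: `"="`, `"<="` or `">="`.
#' @param lb,ub numeric bounds, length `n`; `-Inf`/`Inf` allowed.
#' @param maximize maximise instead of minimise.
#' @param tol pivot/zero tolerance.
#' @param feas_tol feasibility tolerance on the phase-1 objective.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"maxiter"`), `objval` (on the original
#'   maximise/minimise scale; `NA` unless optimal) and `x` (a primal
#'   solution of length `n`; `NA` unless optimal).
#' @examples
#' # max x1 + x2 s.t. x1 + 2 x2 <= 4, 0 <= x <= 3
#' lp_solve(c(1, 1), rbind(c(1, 2)), 4, "<=", c(0, 0), c(3, 3),
#'          maximize = TRUE)
#' @export
lp_solve <- function(obj, A, rhs, sense, lb, ub,
                     maximize = FALSE, tol = 1e-9, feas_tol = 1e-7) {
  n <- length(obj)
  if (is.null(A)) A <- matrix(0, 0L, n)
  A <- as.matrix(A)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(sense) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  cc <- if (maximize) -obj else obj

  ## normalise rows: ">=" -> "<=" ; then add one slack per "<=" row
  flip <- sense == ">="
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    sense[flip] <- "<="
  }
  ineq <- which(sense == "<=")
  n_slack <- length(ineq)
  if (n_slack > 0L) {
    Sl <- matrix(0, m, n_slack)
    Sl[cbind(ineq, seq_len(n_slack))] <- 1
    A <- cbind(A, Sl)
    cc <- c(cc, rep(0, n_slack))
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
  }
  res <- simplex_bounded(cc, A, rhs, lb, ub, tol = tol, feas_tol = feas_tol)
  x <- if (res$status == "optimal") res$x[seq_len(n)] else rep(NA_real_, n)
  objval <- if (res$status == "optimal") {
    if (maximize) -res$objval else res$objval
  } else NA_real_
  list(status = res$status, objval = objval, x = x)
}

## Bounded-variable two-phase simplex on  min c'x, A x = b, l <= x <= u.
## Nonbasic variables rest at a finite bound (or 0 when free); the basis
## inverse is applied through fresh LU solves every iteration, trading
## speed for numerical robustness -- appropriate for the small dense LPs
## arising from core-model FVA.
simplex_bounded <- function(cc, A, b, lb, ub, tol = 1e-9, feas_tol = 1e-7) {
  m <- nrow(A)
  n <- ncol(A)

  if (m == 0L) {
    ## no rows: each variable independently at its preferred bound
    x <- ifelse(cc > tol, lb, ifelse(cc < -tol, ub, ifelse(is.finite(lb), lb, pmin(ub, 0))))
    x[!is.finite(x) & cc == 0] <- 0
    if (any(!is.finite(x))) {
      return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
    }
    return(list(status = "optimal", objval = sum(cc * x), x = x))
  }

  ## phase 1: artificials, one per row
  start_val <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  r0 <- b - as.vector(A %*% start_val)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  art <- n + seq_len(m)
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  c1 <- c(rep(0, n), rep(1, m))

  ph1 <- simplex_iterate(c1, Aext, b, lbe, ube, basis = art,
                         xn = c(start_val, rep(0, m)), tol = tol,
                         phase1 = TRUE)
  if (ph1$status == "maxiter") {
    return(list(status = "maxiter", objval = NA_real_, x = rep(NA_real_, n)))
  }
  if (ph1$objval > feas_tol) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }

  ## phase 2: artificials pinned to zero, true costs
  lbe[art] <- 0
  ube[art] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- simplex_iterate(c2, Aext, b, lbe, ube, basis = ph1$basis,
                         xn = ph1$xn, tol = tol, phase1 = FALSE)
  if (ph2$status == "maxiter") {
    return(list(status = "maxiter", objval = NA_real_, x = rep(NA_real_, n)))
  }
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
  }
  x <- ph2$x[seq_len(n)]
  list(status = "optimal", objval = sum(cc * x), x = x)
}

## Core iteration loop. `basis` gives the basic variable of each row; `xn`
## gives resting values for every variable (only meaningful when nonbasic).
## Returns basis, resting values, full primal vector and objective.
simplex_iterate <- function(cc, A, b, lb, ub, basis, xn, tol, phase1) {
  m <- nrow(A)
  N <- ncol(A)
  max_iter <- 200L * (N + m)
  bland_after <- 20L * (N + m)

  is_basic <- rep(FALSE, N)
  is_basic[basis] <- TRUE

  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    nb <- which(!is_basic)
    xn_nb <- xn[nb]
    rhs_eff <- b - as.vector(A[, nb, drop = FALSE] %*% xn_nb)
    xB <- tryCatch(solve(B, rhs_eff), error = function(e) NULL)
    if (is.null(xB)) {
      ## singular basis (should not occur); perturb via LS solve
      xB <- qr.solve(B, rhs_eff)
    }
    y <- tryCatch(solve(t(B), cc[basis]), error = function(e) qr.solve(t(B), cc[basis]))
    d <- cc[nb] - as.vector(crossprod(A[, nb, drop = FALSE], y))

    at_lo <- is.finite(lb[nb]) & abs(xn_nb - lb[nb]) <= tol
    at_up <- is.finite(ub[nb]) & abs(xn_nb - ub[nb]) <= tol
    fixed <- at_lo & at_up & (ub[nb] - lb[nb] <= tol)
    ## eligibility: improve objective by moving off the resting point
    can_inc <- (at_lo | (!at_lo & !at_up)) & d < -tol & !fixed
    can_dec <- (at_up | (!at_lo & !at_up)) & d > tol & !fixed

    elig <- which(can_inc | can_dec)
    if (length(elig) == 0L) {
      x <- xn
      x[basis] <- xB
      return(list(status = "optimal", basis = basis, xn = xn, x = x,
                  objval = sum(cc * x)))
    }
    if (iter > bland_after) {
      j_rel <- elig[which.min(nb[elig])]          # Bland: smallest index
    } else {
      j_rel <- elig[which.max(abs(d[elig]))]      # Dantzig
    }
    j <- nb[j_rel]
    dir <- if (can_inc[j_rel]) 1 else -1

    w <- tryCatch(solve(B, A[, j]), error = function(e) qr.solve(B, A[, j]))
    ## ratio test: basic variables move as xB - t*dir*w, t >= 0
    dw <- dir * w
    ratio <- rep(Inf, m)
    to_bound <- rep(NA_character_, m)
    dec <- dw > tol & is.finite(lb[basis])          # basic value decreasing
    inc <- dw < -tol & is.finite(ub[basis])         # basic value increasing
    ratio[dec] <- (xB[dec] - lb[basis[dec]]) / dw[dec]
    to_bound[dec] <- "lower"
    ratio[inc] <- (ub[basis[inc]] - xB[inc]) / (-dw[inc])
    to_bound[inc] <- "upper"
    ratio[ratio < 0] <- 0                            # degenerate
    step <- min(ratio)
    leave <- 0L
    leave_to <- NA_character_
    if (is.finite(step)) {
      ties <- which(ratio <= step + tol)
      leave <- ties[which.max(abs(w[ties]))]         # stability tie-break
      step <- ratio[leave]
      leave_to <- to_bound[leave]
    }
    ## entering variable's own opposite bound
    own <- if (dir > 0) {
      if (is.finite(ub[j])) ub[j] - xn[j] else Inf
    } else {
      if (is.finite(lb[j])) xn[j] - lb[j] else Inf
    }
    if (own < step - tol) {
      ## bound flip, basis unchanged
      xn[j] <- if (dir > 0) ub[j] else lb[j]
      next
    }
    if (!is.finite(step)) {
      if (phase1) {
        ## phase-1 objective is bounded below; numerically treat as done
        x <- xn
        x[basis] <- xB
        return(list(status = "optimal", basis = basis, xn = xn, x = x,
                    objval = sum(cc * x)))
      }
      return(list(status = "unbounded", basis = basis, xn = xn,
                  x = rep(NA_real_, N), objval = NA_real_))
    }
    ## pivot: j enters, basis[leave] exits to the bound it hit
    out <- basis[leave]
    xn[out] <- if (leave_to == "lower") lb[out] else ub[out]
    xn[j] <- xn[j] + dir * step
    basis[leave] <- j
    is_basic[out] <- FALSE
    is_basic[j] <- TRUE
  }
  list(status = "maxiter", basis = basis, xn = xn,
       x = rep(NA_real_, N), objval = NA_real_)
}
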