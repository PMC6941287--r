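# Dense two-phase simplex for box-constrained linear programs
#
#   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
#
# This is the package's LP kernel. All flux bounds in constraint-based
# models are finite (defaults are +/-100 mmol/(g dw h)), so decision
# variables must have finite bounds; only the internal phase-1 artificials
# are unbounded above. The implementation is a textbook bounded-variable
# revised simplex: nonbasic variables sit at one of their bounds, the ratio
# test allows bound flips, Dantzig pricing with a switch to Bland's rule
# after a fixed iteration count guarantees termination. Basis systems are
# re-solved densely each iteration; intended problem sizes are a few
# hundred reactions at most.

.lpSolveBounded <- function(obj, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, maxit = NULL) {
  n <- length(obj)
  A <- as.matrix(A)
  if (n == 0L) stop("empty problem")
  if (length(lb) != n || length(ub) != n) stop("bound length mismatch")
  if (any(is.infinite(lb) & is.infinite(ub))) {
    stop("free variables (infinite on both sides) are not supported")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", obj = NA_real_, x = NULL,
                support = character()))
  }
  lb <- pmin(lb, ub)  # collapse lb>ub within tolerance to a point
  if (nrow(A) && ncol(A) != n) stop("A column count mismatch")
  cc <- if (maximize) obj else -obj
  m0 <- nrow(A)

  # no equality rows: optimum is at the bound selected by the cost sign
  if (m0 == 0L) {
    x <- ifelse(cc > 0, ub, lb)
    if (any(is.infinite(x[cc != 0]))) {
      return(list(status = "unbounded", obj = NA_real_, x = NULL,
                  support = as.character(which(cc != 0 & is.infinite(x)))))
    }
    x[is.infinite(x)] <- ifelse(is.infinite(lb[is.infinite(x)]),
                                ub[is.infinite(x)], lb[is.infinite(x)])
    val <- sum(cc * x)
    return(list(status = "optimal", obj = if (maximize) val else -val, x = x,
                support = character()))
  }

  # drop linearly dependent rows (conserved moieties give rank-deficient S);
  # consistency of the dropped rows is re-checked on the final solution
  qt <- qr(t(A))
  r <- qt$rank
  keep <- sort(qt$pivot[seq_len(r)])
  Ar <- A[keep, , drop = FALSE]
  br <- b[keep]
  m <- nrow(Ar)

  scale <- max(1, abs(br), abs(Ar))
  ftol <- tol * scale

  # initial nonbasic point: each variable at its finite bound of smaller
  # magnitude (single-sided infinite bounds force the finite side)
  xstat <- ifelse(is.infinite(ub), -1L,
                  ifelse(is.infinite(lb), 1L,
                         ifelse(abs(lb) <= abs(ub), -1L, 1L)))
  x0 <- ifelse(xstat == -1L, lb, ub)
  resid <- as.vector(br - Ar %*% x0)

  # phase 1: artificials with sign matching the residual, minimise their sum
  sgn <- ifelse(resid >= 0, 1, -1)
  Aw <- cbind(Ar, diag(sgn, m))
  lw <- c(lb, rep(0, m))
  uw <- c(ub, rep(Inf, m))
  cw1 <- c(rep(0, n), rep(-1, m))
  basis <- n + seq_len(m)
  xst <- c(xstat, rep(0L, m))   # 0 = basic

  if (is.null(maxit)) maxit <- 200L * (n + m) + 2000L

  ph1 <- .simplexCore(Aw, br, cw1, lw, uw, basis, xst, tol, maxit)
  if (ph1$status == "maxit") {
    return(list(status = "numerical", obj = NA_real_, x = NULL,
                support = character()))
  }
  if (ph1$obj < -ftol) {
    return(list(status = "infeasible", obj = NA_real_, x = NULL,
                support = character()))
  }

  # phase 2: pin artificials at zero, optimise the true objective
  uw2 <- uw; uw2[n + seq_len(m)] <- 0
  lw2 <- lw
  cw2 <- c(cc, rep(0, m))
  xst2 <- ph1$xstat
  # a nonbasic artificial must sit at 0 (its lower bound)
  ia <- n + seq_len(m)
  xst2[ia][xst2[ia] == 1L] <- -1L
  ph2 <- .simplexCore(Aw, br, cw2, lw2, uw2, ph1$basis, xst2, tol, maxit)
  if (ph2$status == "maxit") {
    return(list(status = "numerical", obj = NA_real_, x = NULL,
                support = character()))
  }
  if (ph2$status == "unbounded") {
    sup <- ph2$raySupport[ph2$raySupport <= n]
    return(list(status = "unbounded", obj = NA_real_, x = NULL,
                support = as.character(sup)))
  }
  x <- ph2$x[seq_len(n)]
  # clamp round-off and check the full (possibly rank-deficient) system
  x <- pmin(pmax(x, lb), ub)
  full <- max(abs(as.vector(A %*% x) - b))
  if (full > 1e-6 * max(1, max(abs(x)))) {
    # dropped dependent rows were inconsistent with b
    return(list(status = "infeasible", obj = NA_real_, x = NULL,
                support = character()))
  }
  val <- sum(cc * x)
  list(status = "optimal", obj = if (maximize) val else -val, x = x,
       support = character())
}

# core bounded-variable simplex iterations (maximisation).
# xstat: -1 nonbasic at lower, +1 nonbasic at upper, 0 basic.
.simplexCore <- function(Aw, bw, cw, lw, uw, basis, xstat, tol, maxit) {
  m <- nrow(Aw); nw <- ncol(Aw)
  blandAfter <- 10L * (m + nw) + 200L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) {
      return(list(status = "maxit"))
    }
    nonb <- which(xstat != 0L)
    xN <- ifelse(xstat[nonb] == -1L, lw[nonb], uw[nonb])
    B <- Aw[, basis, drop = FALSE]
    rhs <- bw - if (length(nonb)) as.vector(Aw[, nonb, drop = FALSE] %*% xN) else 0
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "maxit"))
    y <- tryCatch(solve(t(B), cw[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "maxit"))
    if (length(nonb)) {
      d <- cw[nonb] - as.vector(crossprod(Aw[, nonb, drop = FALSE], y))
    } else d <- numeric(0)

    movable <- uw[nonb] - lw[nonb] > tol
    improving <- movable &
      ((xstat[nonb] == -1L & d > tol) | (xstat[nonb] == 1L & d < -tol))
    if (!any(improving)) {
      x <- numeric(nw)
      x[basis] <- xB
      if (length(nonb)) x[nonb] <- xN
      return(list(status = "optimal", obj = sum(cw * x), x = x,
                  basis = basis, xstat = xstat))
    }
    cand <- nonb[improving]
    if (it > blandAfter) {
      j <- min(cand)                       # Bland's rule: termination
    } else {
      j <- cand[which.max(abs(d[improving]))]
    }
    dirj <- if (xstat[j] == -1L) 1 else -1  # x_j moves up from lb or down from ub
    w <- tryCatch(solve(B, Aw[, j]), error = function(e) NULL)
    if (is.null(w)) return(list(status = "maxit"))
    deltaB <- -dirj * w                     # d(xB)/dt for step t >= 0

    # ratio test: per-basic step limits (towards lower if deltaB<0, upper if >0)
    ti <- rep(Inf, m)
    toBnd <- integer(m)
    dn <- deltaB < -tol
    up <- deltaB > tol
    ti[dn] <- pmax((xB[dn] - lw[basis[dn]]) / (-deltaB[dn]), 0)
    toBnd[dn] <- -1L
    ui <- uw[basis]
    upf <- up & is.finite(ui)
    ti[upf] <- pmax((ui[upf] - xB[upf]) / deltaB[upf], 0)
    toBnd[upf] <- 1L
    ti[up & !is.finite(ui)] <- Inf

    tBound <- uw[j] - lw[j]                 # bound-flip step limit
    tMin <- min(ti, tBound)
    if (!is.finite(tMin)) {
      sup <- c(j, basis[abs(deltaB) > tol])
      return(list(status = "unbounded", raySupport = sup))
    }
    if (tBound <= tMin + tol && all(ti > tBound - tol)) {
      xstat[j] <- -xstat[j]                 # bound flip, basis unchanged
    } else {
      tied <- which(ti <= tMin + tol)
      if (it > blandAfter) {
        leave <- tied[which.min(basis[tied])]   # Bland leaving rule
      } else {
        leave <- tied[which.max(abs(deltaB[tied]))]  # stability
      }
      xstat[basis[leave]] <- toBnd[leave]
      xstat[j] <- 0L
      basis[leave] <- j
    }
  }
}
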