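# Bounded-variable two-phase primal simplex.
#
# Solves   min  c'x
#          s.t. rl <= A x <= ru        (m ranged rows)
#               lb <= x  <= ub         (n boxed variables)
#
# Each ranged row is rewritten as A_i x - s_i = 0 with a slack s_i boxed in
# [rl_i, ru_i]; phase 1 drives per-row artificial variables to zero, phase 2
# minimizes the true objective. The basis inverse is maintained explicitly
# (product-form update) and refactorized periodically; Dantzig pricing with
# a Bland fallback guards against cycling. Written for the problem sizes of
# daily diet programs (tens of rows, a few hundred columns).
#
# Internal. Returns list(status = "optimal"|"infeasible", x, obj).
#
# solve_lp dispatches to the compiled core (src/simplex.cpp); solve_lp_ref
# is the pure-R reference implementation of the same algorithm, kept as an
# independent cross-check in the test suite.

solve_lp <- function(cost, A, rl, ru, lb, ub,
                     tol = 1e-9, feas_tol = 1e-7, max_iter = 10000L) {
  if (nrow(A) == 0L) {                   # box-only problem
    if (any(lb > ub + tol)) {
      return(list(status = "infeasible", x = NULL, obj = NA_real_))
    }
    x <- ifelse(cost >= 0, lb, ub)
    return(list(status = "optimal", x = x, obj = sum(cost * x)))
  }
  .solve_lp_cpp(as.numeric(cost), as.matrix(A), as.numeric(rl),
                as.numeric(ru), as.numeric(lb), as.numeric(ub),
                tol, feas_tol, as.integer(max_iter))
}

solve_lp_ref <- function(cost, A, rl, ru, lb, ub,
                         tol = 1e-9, feas_tol = 1e-7, max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cost) == n, length(rl) == m, length(ru) == m,
            length(lb) == n, length(ub) == n, all(is.finite(lb)))
  if (any(lb > ub + tol) || any(rl > ru + tol)) {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  ub <- pmax(ub, lb)

  nf <- n + 2L * m                       # structural + slack + artificial
  Afull <- cbind(A, -diag(m), diag(m))   # artificial signs patched below
  lbf <- c(lb, rl, rep(0, m))
  ubf <- c(ub, ru, rep(Inf, m))

  # initial point: structural at lower bounds, slacks clamped row activity
  v <- as.numeric(A %*% lb)
  s0 <- pmin(pmax(v, rl), ru)
  s0[!is.finite(s0)] <- 0                # rows unbounded both sides (unused)
  resid <- v - s0
  sgn <- ifelse(resid > 0, -1, 1)
  for (i in seq_len(m)) Afull[i, n + m + i] <- sgn[i]

  xval <- c(lb, s0, abs(resid))
  # status: 0 nonbasic at lb, 1 nonbasic at ub, 2 basic
  vstat <- integer(nf)
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (abs(resid[i]) > tol) {           # slack at its nearest bound, art basic
      basis[i] <- n + m + i
      vstat[n + i] <- if (v[i] > ru[i]) 1L else 0L
      # ensure slack sits exactly on a finite bound
      xval[n + i] <- if (v[i] > ru[i]) ru[i] else rl[i]
    } else {                             # slack basic, artificial pinned at 0
      basis[i] <- n + i
      ubf[n + m + i] <- 0
      xval[n + m + i] <- 0
    }
  }
  vstat[basis] <- 2L
  enterable <- c(rep(TRUE, n + m), rep(FALSE, m))  # artificials never enter

  Binv <- solve(Afull[, basis, drop = FALSE])

  run_phase <- function(cphase, xval, vstat, basis, Binv, ubf) {
    iter <- 0L
    stall <- 0L
    last_obj <- Inf
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached", call. = FALSE)
      if (iter %% 60L == 0L) {           # periodic refactorization
        Binv <- solve(Afull[, basis, drop = FALSE])
        xn <- xval
        xn[basis] <- 0
        xval[basis] <- as.numeric(Binv %*% (-Afull %*% xn))
      }
      yy <- as.numeric(crossprod(Binv, cphase[basis]))
      d <- cphase - as.numeric(crossprod(Afull, yy))
      cand_lo <- vstat == 0L & enterable & d < -tol
      cand_hi <- vstat == 1L & enterable & d > tol
      if (!any(cand_lo) && !any(cand_hi)) {
        obj <- sum(cphase * xval)
        return(list(status = "optimal", xval = xval, vstat = vstat,
                    basis = basis, Binv = Binv, obj = obj))
      }
      obj_now <- sum(cphase * xval)
      if (obj_now < last_obj - tol) { stall <- 0L; last_obj <- obj_now }
      else stall <- stall + 1L
      viol <- numeric(nf)
      viol[cand_lo] <- -d[cand_lo]
      viol[cand_hi] <- d[cand_hi]
      e <- if (stall > 80L) which(viol > 0)[1L] else which.max(viol)  # Bland fallback
      dir <- if (vstat[e] == 0L) 1 else -1
      w <- dir * as.numeric(Binv %*% Afull[, e])   # basic change per unit step is -w

      t_own <- ubf[e] - lbf[e]
      t_best <- t_own
      leave_pos <- 0L
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (w[i] > tol) {                # basic variable decreases
          ti <- (xval[bi] - lbf[bi]) / w[i]
        } else if (w[i] < -tol) {        # basic variable increases
          ti <- (ubf[bi] - xval[bi]) / (-w[i])
        } else next
        if (!is.finite(ti)) next
        if (ti < 0) ti <- 0
        if (ti < t_best - tol || (ti < t_best + tol && leave_pos > 0L &&
                                  bi < basis[leave_pos])) {
          t_best <- ti
          leave_pos <- i
        }
      }
      if (!is.finite(t_best)) stop("LP unbounded", call. = FALSE)

      xval[e] <- xval[e] + dir * t_best
      xval[basis] <- xval[basis] - t_best * w
      if (leave_pos == 0L) {             # bound flip, basis unchanged
        vstat[e] <- if (vstat[e] == 0L) 1L else 0L
        xval[e] <- if (vstat[e] == 0L) lbf[e] else ubf[e]
      } else {
        lv <- basis[leave_pos]
        hit_upper <- w[leave_pos] < 0
        vstat[lv] <- if (hit_upper) 1L else 0L
        xval[lv] <- if (hit_upper) ubf[lv] else lbf[lv]
        vstat[e] <- 2L
        basis[leave_pos] <- e
        # product-form update of the basis inverse
        eta <- as.numeric(Binv %*% Afull[, e])
        piv <- eta[leave_pos]
        if (abs(piv) < 1e-11) {
          Binv <- solve(Afull[, basis, drop = FALSE])
        } else {
          Binv[leave_pos, ] <- Binv[leave_pos, ] / piv
          for (i in seq_len(m)) {
            if (i != leave_pos && abs(eta[i]) > 1e-13) {
              Binv[i, ] <- Binv[i, ] - eta[i] * Binv[leave_pos, ]
            }
          }
        }
      }
    }
  }

  # phase 1: minimize total artificial mass
  c1 <- c(rep(0, n + m), rep(1, m))
  if (sum(xval[(n + m + 1L):nf]) > tol) {
    ph1 <- run_phase(c1, xval, vstat, basis, Binv, ubf)
    if (ph1$obj > feas_tol) {
      return(list(status = "infeasible", x = NULL, obj = NA_real_))
    }
    xval <- ph1$xval; vstat <- ph1$vstat; basis <- ph1$basis; Binv <- ph1$Binv
  }
  # pin artificials to zero for phase 2
  ubf[(n + m + 1L):nf] <- 0
  xval[(n + m + 1L):nf] <- pmin(pmax(xval[(n + m + 1L):nf], 0), 0)

  c2 <- c(cost, rep(0, 2L * m))
  ph2 <- run_phase(c2, xval, vstat, basis, Binv, ubf)
  x <- ph2$xval[seq_len(n)]
  list(status = "optimal", x = x, obj = sum(cost * x))
}
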