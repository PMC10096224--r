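# Bounded-variable primal simplex.
#
# Solves   max/min  c' x   s.t.  A x = b,  l <= x <= u   (all bounds finite)
# with the textbook two-phase method for variables with upper bounds:
# nonbasic variables rest at one of their bounds, the ratio test allows both
# basic variables and the entering variable to hit either bound, and
# entering/leaving choices follow Bland's smallest-index rule, which
# guarantees finite termination without cycling. Dense linear algebra; the
# problems solved here have at most a few hundred reactions.

boundedSimplex <- function(A, b, lb, ub, obj, maximize = TRUE,
                           tol = 1e-9) {
  n <- ncol(A)
  m <- nrow(A)
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL,
                                value = NA_real_))
  # drop linearly dependent equality rows (consistency is audited at the
  # end through the returned residual)
  if (m > 0) {
    qa <- qr(t(A))
    keep <- sort(qa$pivot[seq_len(qa$rank)])
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
    m <- nrow(A)
  }
  cc <- if (maximize) obj else -obj

  # phase 1: artificial variables soak up the residual of an all-at-bound
  # starting point
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, abs(r) + 1)           # room above the start value
  xe <- c(x, abs(r))
  basis <- n + seq_len(m)
  atUpper <- ifelse(abs(lb) <= abs(ub), FALSE, TRUE)
  atUpper <- c(atUpper, rep(FALSE, m))

  phase1 <- c(rep(0, n), rep(-1, m))
  res1 <- simplexCore(Aext, lbe, ube, phase1, xe, basis, atUpper, tol)
  if (sum(res1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  # phase 2: freeze artificials at zero and optimise the real objective
  lbe2 <- lbe
  ube2 <- c(ub, rep(0, m))
  x2 <- res1$x
  x2[n + seq_len(m)] <- 0
  res2 <- simplexCore(Aext, lbe2, ube2, c(cc, rep(0, m)), x2,
                      res1$basis, res1$atUpper, tol)
  x <- res2$x[seq_len(n)]
  list(status = "optimal", x = x,
       value = if (maximize) sum(obj * x) else sum(obj * x))
}

simplexCore <- function(A, lb, ub, cc, x, basis, atUpper, tol,
                        maxIter = NULL) {
  n <- ncol(A)
  m <- nrow(A)
  if (is.null(maxIter)) maxIter <- 500 * (n + m) + 1000
  for (iter in seq_len(maxIter)) {
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv))
      stop("singular basis in simplex; model is numerically degenerate",
           call. = FALSE)
    y <- as.vector(crossprod(Binv, cc[basis]))
    nonbasic <- setdiff(seq_len(n), basis)
    d <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE],
                                            y))
    fixed <- ub[nonbasic] - lb[nonbasic] <= 0
    improving <- (!fixed) &
      ((!atUpper[nonbasic] & d > tol) | (atUpper[nonbasic] & d < -tol))
    if (!any(improving)) break
    e <- nonbasic[improving][which.min(nonbasic[improving])]  # Bland
    dirUp <- !atUpper[e]
    t <- if (dirUp) 1 else -1
    w <- as.vector(Binv %*% A[, e])
    # candidate steps: entering variable to its other bound, or a basic
    # variable to one of its bounds
    stepEnter <- ub[e] - lb[e]
    steps <- stepEnter
    leavers <- 0L                    # 0 = entering flips bound
    leaveAtUpper <- FALSE
    for (i in seq_len(m)) {
      tw <- t * w[i]
      bi <- basis[i]
      if (tw > tol) {
        steps <- c(steps, (x[bi] - lb[bi]) / tw)
        leavers <- c(leavers, i)
        leaveAtUpper <- c(leaveAtUpper, FALSE)
      } else if (tw < -tol) {
        steps <- c(steps, (ub[bi] - x[bi]) / (-tw))
        leavers <- c(leavers, i)
        leaveAtUpper <- c(leaveAtUpper, TRUE)
      }
    }
    delta <- max(0, min(steps))
    if (!is.finite(delta))
      stop("unbounded direction in simplex despite finite bounds",
           call. = FALSE)
    hit <- which(steps <= delta + tol)
    # Bland tie-break on the leaving variable index (entering-flip counts
    # as index e)
    hitIdx <- vapply(hit, function(h)
      if (leavers[h] == 0L) e else basis[leavers[h]], numeric(1))
    chosen <- hit[which.min(hitIdx)]
    x[e] <- x[e] + t * delta
    if (m > 0) x[basis] <- x[basis] - t * delta * w
    if (leavers[chosen] == 0L) {
      atUpper[e] <- !atUpper[e]
      x[e] <- if (atUpper[e]) ub[e] else lb[e]
    } else {
      li <- leavers[chosen]
      lv <- basis[li]
      x[lv] <- if (leaveAtUpper[chosen]) ub[lv] else lb[lv]
      atUpper[lv] <- leaveAtUpper[chosen]
      basis[li] <- e
    }
    if (iter == maxIter)
      stop("simplex iteration limit reached", call. = FALSE)
  }
  list(x = x, basis = basis, atUpper = atUpper)
}
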