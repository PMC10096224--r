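# Independent oracles, implemented before (and kept apart from) the code
# paths they verify.

# Exhaustive enumeration of the basic feasible solutions of the bounded LP
#   max obj'v  s.t.  S v = 0, lb <= v <= ub.
# Every vertex of the polytope has rank(S) "basic" coordinates determined
# by the others resting at a bound; enumerating all support/bound
# combinations and keeping the feasible ones yields the exact optimum for
# small networks. Tractable up to ~8 reactions.
vertexEnumMax <- function(S, lb, ub, obj) {
  n <- ncol(S)
  r <- qr(S)$rank
  best <- -Inf
  found <- FALSE
  combos <- if (r == 0) list(integer(0)) else
    asplit(utils::combn(n, r), 2)
  for (B in combos) {
    B <- as.integer(B)
    NB <- setdiff(seq_len(n), B)
    SB <- S[, B, drop = FALSE]
    if (length(B) && qr(SB)$rank < r) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(NB)))
    for (g in seq_len(max(1, nrow(grid)))) {
      v <- numeric(n)
      if (length(NB))
        v[NB] <- ifelse(unlist(grid[g, ]), ub[NB], lb[NB])
      rhs <- -S[, NB, drop = FALSE] %*% v[NB]
      if (length(B)) {
        sol <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v[B] <- sol
      }
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
      found <- TRUE
      best <- max(best, sum(obj * v))
    }
  }
  if (!found) NA_real_ else best
}

# Random small network with 0 in every bound interval (always feasible)
# and integer stoichiometry; returns parts plus a MetabolicNetwork.
randomSmallNetwork <- function() {
  n <- sample(3:8, 1)
  m <- sample(2:min(5, n - 1), 1)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), n * m, replace = TRUE), m, n)
    if (all(colSums(S != 0) > 0)) break
  }
  lb <- ifelse(runif(n) < 0.4, -sample(1:5, n, replace = TRUE), 0)
  ub <- sample(1:10, n, replace = TRUE)
  rownames(S) <- sprintf("m%d", seq_len(m))
  colnames(S) <- sprintf("r%d", seq_len(n))
  model <- newMetabolicNetwork(
    metabolites = data.frame(id = rownames(S)),
    reactions = data.frame(id = colnames(S), lower_bound = lb,
                           upper_bound = ub),
    stoichiometry = S)
  list(S = S, lb = lb, ub = ub, model = model,
       objective = sample(colnames(S), 1))
}

# Brute-force weighted running-sum enrichment score: walk the full ranked
# list step by step. Independent of the hit-position shortcut used by the
# package.
bruteForceES <- function(statsSorted, isHit, p = 1) {
  N <- length(statsSorted)
  Nh <- sum(isHit)
  wHit <- abs(statsSorted)^p
  sumW <- sum(wHit[isHit])
  running <- 0
  up <- 0
  down <- 0
  for (i in seq_len(N)) {
    if (isHit[i]) {
      running <- running +
        (if (sumW > 0) wHit[i] / sumW else 1 / Nh)
    } else {
      running <- running - 1 / (N - Nh)
    }
    up <- max(up, running)
    down <- min(down, running)
  }
  if (up >= -down) up else down
}

# Hand implementation of the Benjamini-Hochberg step-up adjustment.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
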