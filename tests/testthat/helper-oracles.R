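# Independent oracles for the model fitters.

# Exact epsilon-SVR solution for tiny problems by KKT state enumeration.
# Each training point is in one of five states: beta = -C, free negative,
# 0, free positive, +C.  For each state assignment the free betas and the
# bias solve a linear system; the assignment is accepted when every KKT
# condition holds.  Returns the prediction function parameters (w, b).
svr_exact_tiny <- function(X, y, epsilon, C, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n <= 6)
  K <- X %*% t(X)
  states <- c("lo", "freeneg", "zero", "freepos", "hi")
  grid <- do.call(expand.grid, rep(list(states), n))
  for (g in seq_len(nrow(grid))) {
    st <- as.character(unlist(grid[g, ]))
    beta <- numeric(n)
    beta[st == "lo"] <- -C
    beta[st == "hi"] <- C
    free <- which(st %in% c("freeneg", "freepos"))
    sgn <- ifelse(st == "freepos", 1, -1)
    # unknowns: beta[free], b;  equations: KKT equalities for free points
    # plus the sum-to-zero constraint
    n_unk <- length(free) + 1L
    A <- matrix(0, n_unk, n_unk)
    rhs <- numeric(n_unk)
    fixed <- setdiff(seq_len(n), free)
    for (r in seq_along(free)) {
      i <- free[r]
      A[r, seq_along(free)] <- K[i, free]
      A[r, n_unk] <- 1
      rhs[r] <- y[i] - epsilon * sgn[i] -
        if (length(fixed)) sum(K[i, fixed] * beta[fixed]) else 0
    }
    A[n_unk, seq_along(free)] <- 1
    rhs[n_unk] <- -sum(beta[fixed])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    if (length(free)) beta[free] <- sol[seq_along(free)]
    b <- sol[n_unk]
    if (!length(free)) {
      # b undetermined by equalities; feasibility requires sum(beta) = 0
      if (abs(sum(beta)) > tol) next
      # pick b at the centre of the feasible interval
      r_no_b <- y - drop(K %*% beta)
      lo <- max(r_no_b[beta > -C + tol] - epsilon)
      hi <- min(r_no_b[beta < C - tol] + epsilon)
      if (lo > hi + tol) next
      b <- (lo + hi) / 2
    }
    # verify all KKT conditions
    r <- y - drop(K %*% beta) - b
    ok <- TRUE
    for (i in seq_len(n)) {
      ok <- ok && switch(st[i],
        lo = r[i] <= -epsilon + tol,
        hi = r[i] >= epsilon - tol,
        zero = abs(r[i]) <= epsilon + tol,
        freepos = beta[i] > -tol && beta[i] < C + tol &&
          abs(r[i] - epsilon) <= tol * max(1, abs(y[i])),
        freeneg = beta[i] < tol && beta[i] > -C - tol &&
          abs(r[i] + epsilon) <= tol * max(1, abs(y[i])))
      if (!ok) break
    }
    if (ok) {
      return(list(w = drop(t(X) %*% beta), b = b, beta = beta))
    }
  }
  stop("no consistent KKT state found")
}

# Exhaustive best-split search: every (feature, midpoint) candidate scored
# by the weighted sum of child SSEs; ties toward the lowest feature index,
# then the smallest threshold.
best_split_brute <- function(x, y, min_leaf) {
  x <- as.matrix(x)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- x[, j] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      sse <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (is.null(best) || sse < best$sse - 1e-12)
        best <- list(feature = j, threshold = thr, sse = sse)
    }
  }
  best
}
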