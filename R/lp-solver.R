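# Dense two-phase primal simplex with Bland's anti-cycling rule, sized for
# the small LPs of flux balance / flux variability analysis on compact
# models. Standard form: the fluxes are shifted to x = v - lb >= 0, upper
# bounds become slack rows x + s = ub - lb, and the steady-state rows keep
# artificial variables through phase 1. Bland's rule (lowest eligible
# index for both entering and leaving variable) guarantees termination on
# the degenerate LPs that objective-fixed variability analysis produces.

simplex_bland <- function(Tb, basis, n_real, tol = 1e-9) {
  m <- nrow(Tb) - 1L
  repeat {
    cost <- Tb[m + 1L, seq_len(n_real)]
    enter <- which(cost < -tol)
    if (!length(enter)) return(list(T = Tb, basis = basis, status = "optimal"))
    j <- enter[1L]                      # Bland: lowest index
    col <- Tb[seq_len(m), j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(T = Tb, basis = basis, status = "unbounded"))
    ratios <- Tb[pos, ncol(Tb)] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[order(basis[cand])][1L]   # Bland: lowest basic index leaves
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    for (r in seq_len(m + 1L)) {
      if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    }
    basis[i] <- j
  }
}

# maximize obj'v  s.t.  S v = 0, lb <= v <= ub (all finite)
# returns list(status, objective, fluxes)
lp_bounded <- function(S, lb, ub, obj, maximize = TRUE, tol = 1e-9) {
  n <- length(lb)
  m_eq <- nrow(S)
  b_eq <- as.vector(-S %*% lb)
  A_eq <- S
  flip <- b_eq < 0
  A_eq[flip, ] <- -A_eq[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  u <- ub - lb

  # columns: x (n) | s (n upper-bound slacks) | artificials (m_eq)
  n_real <- 2L * n
  n_tot <- n_real + m_eq
  m <- m_eq + n
  A <- matrix(0, m, n_tot)
  A[seq_len(m_eq), seq_len(n)] <- A_eq
  A[seq_len(m_eq), n_real + seq_len(m_eq)] <- diag(m_eq)
  A[m_eq + seq_len(n), seq_len(n)] <- diag(n)
  A[m_eq + seq_len(n), n + seq_len(n)] <- diag(n)
  b <- c(b_eq, u)
  basis <- c(n_real + seq_len(m_eq), n + seq_len(n))

  # phase 1: minimize sum of artificials
  Tb <- rbind(cbind(A, b), 0)
  cost1 <- c(rep(0, n_real), rep(1, m_eq), 0)
  Tb[m + 1L, ] <- cost1
  for (i in seq_len(m_eq))            # price out the artificial basis
    Tb[m + 1L, ] <- Tb[m + 1L, ] - Tb[i, ]
  res <- simplex_bland(Tb, basis, n_real = n_tot, tol = tol)
  if (res$status != "optimal" || -res$T[m + 1L, ncol(res$T)] > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  Tb <- res$T; basis <- res$basis

  # drive any artificial still basic (at zero) out of the basis
  for (i in which(basis > n_real)) {
    row <- Tb[i, seq_len(n_real)]
    j <- which(abs(row) > tol)
    if (length(j)) {
      j <- j[1L]
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(m + 1L))
        if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      basis[i] <- j
    }
    # a row with no real coefficients is redundant; its artificial stays
    # basic at zero and never re-enters (cost kept at +1 below)
  }

  # phase 2: minimize -obj'x (maximize) with artificials locked out
  cvec <- numeric(n_tot)
  cvec[seq_len(n)] <- if (maximize) -obj else obj
  cvec[n_real + seq_len(m_eq)] <- Inf   # sentinel, replaced after pricing
  Tb[m + 1L, ] <- c(cvec[seq_len(n_real)], rep(0, m_eq), 0)
  for (i in seq_len(m)) {
    bi <- basis[i]
    if (bi <= n_real && abs(Tb[m + 1L, bi]) > 0)
      Tb[m + 1L, ] <- Tb[m + 1L, ] - Tb[m + 1L, bi] * Tb[i, ]
  }
  res <- simplex_bland(Tb, basis, n_real = n_real, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  Tb <- res$T; basis <- res$basis
  x <- numeric(n_tot)
  x[basis] <- Tb[seq_len(m), ncol(Tb)]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), fluxes = v)
}
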