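# Independent LP oracle: exhaustive enumeration of the basic feasible
# points (vertices) of {v : S v = 0, lb <= v <= ub}. For n reactions and a
# stoichiometric matrix of rank r, every vertex fixes n - r variables at a
# bound and solves the equality system for the rest; enumerating all
# subsets and bound patterns covers every vertex. Only usable for the toy
# models (n <= 10), which is the point: it shares no code with the simplex.

enumerate_vertices <- function(model, tol = 1e-8) {
  S <- model$S
  lb <- pmax(model$reactions$lb, -1e5)
  ub <- pmin(model$reactions$ub, 1e5)
  n <- ncol(S)
  r <- qr(S)$rank
  n_fix <- n - r
  verts <- list()
  for (fix_idx in utils::combn(n, n_fix, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    patterns <- expand.grid(rep(list(c("lb", "ub")), n_fix),
                            stringsAsFactors = FALSE)
    for (pi in seq_len(nrow(patterns))) {
      v <- numeric(n)
      v[fix_idx] <- ifelse(unlist(patterns[pi, ]) == "lb",
                           lb[fix_idx], ub[fix_idx])
      rhs <- -S[, fix_idx, drop = FALSE] %*% v[fix_idx]
      A <- S[, free_idx, drop = FALSE]
      qa <- qr(A)
      if (qa$rank < length(free_idx)) next
      sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - rhs)) > tol) next
      v[free_idx] <- sol
      if (all(v >= lb - tol) && all(v <= ub + tol))
        verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  out <- unique(do.call(rbind, lapply(verts, round, digits = 9)))
  colnames(out) <- colnames(S)
  out
}

# oracle FBA optimum: best objective over all vertices
oracle_fba <- function(model) {
  verts <- enumerate_vertices(model)
  obj <- as.numeric(model$reactions$objective)
  max(verts %*% obj)
}

# oracle flux ranges at the (vertex-enumerated) optimum; LP optima are
# attained at vertices, and so are per-coordinate extrema over the optimal
# face, so restricting to optimal vertices is exact
oracle_fva <- function(model, tol = 1e-6) {
  verts <- enumerate_vertices(model)
  obj <- as.numeric(model$reactions$objective)
  vals <- as.vector(verts %*% obj)
  opt <- max(vals)
  on_face <- verts[vals >= opt - tol, , drop = FALSE]
  data.frame(reaction = model$reactions$id,
             min = apply(on_face, 2, min),
             max = apply(on_face, 2, max), row.names = NULL,
             stringsAsFactors = FALSE)
}
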