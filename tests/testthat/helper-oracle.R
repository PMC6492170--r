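# Independent brute-force LP oracle.
#
# A bounded LP attains its optimum at a basic feasible solution, so for
# desk-scale problems the optimum can be found by exhaustively enumerating
# every basis choice and every lower/upper assignment of the nonbasic
# variables.  This shares no code with the simplex implementation.

oracle_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  qt <- qr(t(A))
  keep <- qt$pivot[seq_len(qt$rank)]        # drop redundant (moiety) rows
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  verts <- list()
  for (Bidx in utils::combn(n, m, simplify = FALSE)) {
    AB <- A[, Bidx, drop = FALSE]
    qa <- qr(AB)
    if (qa$rank < m) next
    Nidx <- setdiff(seq_len(n), Bidx)
    k <- length(Nidx)
    pats <- if (k == 0) matrix(FALSE, 1, 0)
            else as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    base_rhs <- b
    for (p in seq_len(nrow(pats))) {
      xN <- ifelse(pats[p, ], ub[Nidx], lb[Nidx])
      rhs <- base_rhs - if (k) A[, Nidx, drop = FALSE] %*% xN else 0
      xB <- as.numeric(solve(qa, rhs))
      x <- numeric(n); x[Bidx] <- xB; if (k) x[Nidx] <- xN
      if (all(x >= lb - tol & x <= ub + tol))
        verts[[length(verts) + 1L]] <- x
    }
  }
  do.call(rbind, verts)
}

oracle_fba <- function(model) {
  V <- oracle_vertices(model$S, rep(0, nrow(model$S)),
                       model$reactions$lb, model$reactions$ub)
  oj <- match(model$objective, model$reactions$id)
  max(V[, oj])
}

# FVA by enumerating the vertices of the optimum-constrained polytope
# (objective row with an explicit surplus variable appended)
oracle_fva <- function(model, fraction = 1.0) {
  oj <- match(model$objective, model$reactions$id)
  opt <- oracle_fba(model)
  n <- nrow(model$reactions)
  objrow <- as.numeric(seq_len(n) == oj)
  A2 <- rbind(cbind(model$S, 0), c(objrow, -1))
  b2 <- c(rep(0, nrow(model$S)), fraction * opt)
  lb2 <- c(model$reactions$lb, 0)
  ub2 <- c(model$reactions$ub, max(abs(opt), 1) * 2)
  V <- oracle_vertices(A2, b2, lb2, ub2)
  data.frame(reaction = model$reactions$id,
             min = apply(V[, seq_len(n), drop = FALSE], 2, min),
             max = apply(V[, seq_len(n), drop = FALSE], 2, max))
}

# independent per-reaction optimisation for larger fixtures: the optimum
# floor is imposed as an explicit equality row (valid at fraction = 1),
# a different formulation from the package's slack-based FVA problem.
oracle_fva_per_reaction <- function(model, reactions) {
  base <- lp_solve_bounded(as.numeric(model$reactions$id == model$objective),
                           model$S, rep(0, nrow(model$S)),
                           model$reactions$lb, model$reactions$ub)
  stopifnot(base$status == "optimal")
  n <- nrow(model$reactions)
  A2 <- rbind(model$S, as.numeric(model$reactions$id == model$objective))
  b2 <- c(rep(0, nrow(model$S)), base$objective)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    e <- as.numeric(model$reactions$id == reactions[k])
    lo <- lp_solve_bounded(e, A2, b2, model$reactions$lb, model$reactions$ub,
                           maximize = FALSE)
    hi <- lp_solve_bounded(e, A2, b2, model$reactions$lb, model$reactions$ub,
                           maximize = TRUE)
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
  }
  out
}
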