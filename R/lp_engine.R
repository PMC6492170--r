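# Steady-state flux optimisation.
#
# The package carries its own dense bounded-variable two-phase simplex.  The
# models this package targets at desk scale are small (tens of reactions), so
# a dense implementation with Bland's anti-cycling rule and per-iteration
# refactorisation is both fast enough and numerically unexciting.  Basic
# solutions are recomputed from scratch at every iteration, which keeps
# round-off drift out of the final vertex.

#' Solve a bounded linear programme
#'
#' Maximise (or minimise) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, via a two-phase bounded-variable simplex with Bland's
#' rule.  Infinite bounds are clamped to +/- 1e7.  Redundant equality rows
#' (conserved moieties) are tolerated: their artificial variables simply stay
#' basic at zero.
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (dense).
#' @param b right-hand side.
#' @param lb,ub variable bounds.
#' @param maximize logical, default `TRUE`.
#' @param tol feasibility/optimality tolerance (default 1e-9).
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, `objective`, and `residual` (max equality violation).
#' @export
lp_solve_bounded <- function(obj, A, b, lb, ub, maximize = TRUE,
                             tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  BIG <- 1e7
  lb <- pmax(lb, -BIG); ub <- pmin(ub, BIG)
  if (any(lb > ub)) return(list(status = "infeasible", x = rep(NA_real_, n),
                                objective = NA_real_, residual = NA_real_))
  sgn <- if (maximize) 1 else -1
  cstruct <- sgn * obj

  # start every structural variable at its smaller-magnitude bound
  xval <- ifelse(abs(lb) <= abs(ub), lb, ub)
  stat <- ifelse(abs(lb) <= abs(ub), "L", "U")
  r <- as.numeric(b - A %*% xval)
  asign <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(asign, m))
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(1e30, m))
  xe <- c(xval, abs(r))
  state <- c(stat, rep("B", m))
  basis <- n + seq_len(m)

  run_phase <- function(cc, basis, state, xe) {
    it <- 0L; stall <- 0L; last_obj <- -Inf
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit",
                                     basis = basis, state = state, xe = xe))
      NB <- which(state != "B")
      AB <- Aext[, basis, drop = FALSE]
      qrAB <- qr(AB, tol = 1e-13)
      if (qrAB$rank < m)
        return(list(status = "singular", basis = basis, state = state, xe = xe))
      solveAB <- function(rhs) {      # one step of iterative refinement
        z <- as.numeric(solve(qrAB, rhs))
        z + as.numeric(solve(qrAB, rhs - AB %*% z))
      }
      rhs <- b - Aext[, NB, drop = FALSE] %*% xe[NB]
      xB <- solveAB(rhs)
      xe[basis] <- xB
      cur <- sum(cc * xe)
      if (cur > last_obj + 1e-12 * (1 + abs(cur))) {
        stall <- 0L; last_obj <- cur
      } else stall <- stall + 1L
      bland <- stall > 200L          # anti-cycling fallback when degenerate
      qrABt <- qr(t(AB), tol = 1e-13)
      y <- as.numeric(solve(qrABt, cc[basis]))
      y <- y + as.numeric(solve(qrABt, cc[basis] - crossprod(AB, y)))
      d <- cc[NB] - as.numeric(crossprod(Aext[, NB, drop = FALSE], y))
      elig <- (state[NB] == "L" & d > tol) | (state[NB] == "U" & d < -tol)
      if (!any(elig))
        return(list(status = "optimal", basis = basis, state = state, xe = xe))
      j <- if (bland) NB[elig][which.min(NB[elig])]
           else NB[elig][which.max(abs(d[elig]))]
      dirj <- if (state[j] == "L") 1 else -1
      w <- solveAB(Aext[, j])
      coef <- -dirj * w                           # d(xB)/dt
      tlim <- rep(Inf, m)
      up <- coef > tol; dn <- coef < -tol
      tlim[up] <- (ube[basis[up]] - xe[basis[up]]) / coef[up]
      tlim[dn] <- (xe[basis[dn]] - lbe[basis[dn]]) / (-coef[dn])
      tlim[tlim < 0] <- 0
      town <- ube[j] - lbe[j]
      tmin <- min(tlim, town)
      if (!is.finite(tmin))
        return(list(status = "unbounded", basis = basis, state = state, xe = xe))
      if (town <= min(tlim)) {
        # entering variable runs to its opposite bound: bound flip
        xe[j] <- xe[j] + dirj * town
        xe[basis] <- xe[basis] + coef * town
        state[j] <- if (state[j] == "L") "U" else "L"
      } else {
        # Harris-style leaving choice: among (near-)minimum ratios pivot on
        # the largest-magnitude element to protect the basis conditioning;
        # under prolonged degeneracy fall back to Bland's smallest index.
        hit <- which(tlim <= tmin + 1e-9 * (1 + abs(tmin)))
        if (!length(hit)) hit <- which.min(tlim)
        lv <- if (bland) hit[which.min(basis[hit])]
              else hit[which.max(abs(coef[hit]))]
        leave <- basis[lv]
        step <- tlim[lv]
        xe[j] <- xe[j] + dirj * step
        xe[basis] <- xe[basis] + coef * step
        state[leave] <- if (coef[lv] < 0) "L" else "U"
        xe[leave] <- if (coef[lv] < 0) lbe[leave] else ube[leave]
        basis[lv] <- j
        state[j] <- "B"
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, state, xe)
  if (p1$status %in% c("iteration_limit", "singular"))
    stop("simplex failed in phase 1: ", p1$status)
  art_total <- sum(p1$xe[n + seq_len(m)])
  if (art_total > 1e-6 * (1 + max(abs(b))))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, residual = art_total))
  ube[n + seq_len(m)] <- 0   # freeze artificials
  xe <- p1$xe; xe[n + seq_len(m)][p1$state[n + seq_len(m)] != "B"] <- 0

  # phase 2: true objective
  c2 <- c(cstruct, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$state, xe)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = Inf * sgn, residual = NA_real_))
  if (p2$status %in% c("iteration_limit", "singular"))
    stop("simplex failed in phase 2: ", p2$status)
  x <- p2$xe[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)
  resid <- max(abs(A %*% x - b), 0)
  list(status = "optimal", x = x, objective = sum(obj * x), residual = resid)
}

#' Flux balance analysis: maximise growth
#'
#' Maximises the objective reaction subject to `S v = 0` and the flux bounds.
#' With `selection_rule = "min_total_flux"` (the default) a second,
#' parsimonious stage minimises the total absolute flux at the fixed optimal
#' objective, which makes the returned flux vector reproducible across
#' solvers and reaction orderings whenever the parsimonious optimum is
#' unique.
#'
#' @param model a validated `metabolic_model`.
#' @param selection_rule `"min_total_flux"` or `"solver_default"`.
#' @param tol solver tolerance.
#' @return an object of class `flux_solution`: `fluxes` (named vector),
#'   `objective_value`, `status`, `selection_rule`, `residual`.
#' @export
optimize_growth <- function(model,
                            selection_rule = c("min_total_flux", "solver_default"),
                            tol = 1e-9) {
  selection_rule <- match.arg(selection_rule)
  validate_model(model)
  n <- nrow(model$reactions)
  obj <- as.numeric(model$reactions$id == model$objective)
  res <- lp_solve_bounded(obj, model$S, rep(0, nrow(model$S)),
                          model$reactions$lb, model$reactions$ub,
                          maximize = TRUE, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(fluxes = stats::setNames(rep(NA_real_, n),
                                                   model$reactions$id),
                          objective_value = NA_real_, status = res$status,
                          selection_rule = selection_rule,
                          residual = res$residual),
                     class = "flux_solution"))
  }
  fluxes <- stats::setNames(res$x, model$reactions$id)
  if (selection_rule == "min_total_flux") {
    ps <- pfba_stage(model, res$objective, tol = tol)
    if (!is.null(ps)) fluxes <- ps
  }
  structure(list(fluxes = fluxes, objective_value = res$objective,
                 status = "optimal", selection_rule = selection_rule,
                 residual = res$residual),
            class = "flux_solution")
}

# second-stage parsimonious LP: min sum |v| s.t. S v = 0, bounds, c'v = opt.
pfba_stage <- function(model, opt, tol = 1e-9) {
  S <- model$S
  lb <- model$reactions$lb; ub <- model$reactions$ub
  n <- length(lb)
  rev <- lb < 0
  # columns: originals for irreversible, (p, q) pair for reversible
  cols <- list(); cl <- c(); cu <- c(); cobj <- c(); mapidx <- list()
  for (j in seq_len(n)) {
    if (!rev[j]) {
      cols[[length(cols) + 1L]] <- S[, j]
      cl <- c(cl, lb[j]); cu <- c(cu, ub[j]); cobj <- c(cobj, 1)
      mapidx[[length(mapidx) + 1L]] <- c(j, 1)
    } else {
      cols[[length(cols) + 1L]] <- S[, j]
      cl <- c(cl, 0); cu <- c(cu, max(ub[j], 0)); cobj <- c(cobj, 1)
      mapidx[[length(mapidx) + 1L]] <- c(j, 1)
      cols[[length(cols) + 1L]] <- -S[, j]
      cl <- c(cl, 0); cu <- c(cu, max(-lb[j], 0)); cobj <- c(cobj, 1)
      mapidx[[length(mapidx) + 1L]] <- c(j, -1)
    }
  }
  A <- do.call(cbind, cols)
  # fixed-objective row
  objrow <- numeric(ncol(A))
  oj <- match(model$objective, model$reactions$id)
  for (k in seq_along(mapidx)) {
    if (mapidx[[k]][1] == oj) objrow[k] <- mapidx[[k]][2]
  }
  A2 <- rbind(A, objrow)
  b2 <- c(rep(0, nrow(S)), opt)
  res <- lp_solve_bounded(cobj, A2, b2, cl, cu, maximize = FALSE, tol = tol)
  if (res$status != "optimal") return(NULL)
  v <- numeric(n)
  for (k in seq_along(mapidx)) v[mapidx[[k]][1]] <- v[mapidx[[k]][1]] +
      mapidx[[k]][2] * res$x[k]
  stats::setNames(v, model$reactions$id)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 10),
      " rule:", x$selection_rule, "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the growth objective
#' being at least `fraction_of_optimum` times its optimum.
#'
#' @param model a validated `metabolic_model`.
#' @param fraction_of_optimum fraction in (0, 1], default 1.
#' @param reactions reaction ids to analyse (default: all).
#' @param tol solver tolerance.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, fraction_of_optimum = 1.0,
                             reactions = NULL, tol = 1e-9) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  base <- optimize_growth(model, selection_rule = "solver_default", tol = tol)
  if (base$status != "optimal")
    stop("base FBA problem is ", base$status, "; cannot run FVA")
  opt <- base$objective_value
  if (is.null(reactions)) reactions <- model$reactions$id
  n <- nrow(model$reactions)
  objrow <- as.numeric(model$reactions$id == model$objective)
  # c'v - s = fraction * opt, s >= 0  (s absorbs any surplus above the floor)
  A2 <- rbind(cbind(model$S, 0), c(objrow, -1))
  b2 <- c(rep(0, nrow(model$S)), fraction_of_optimum * opt)
  lb2 <- c(model$reactions$lb, 0)
  ub2 <- c(model$reactions$ub, 1e7)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$reactions$id)
    if (is.na(j)) stop("unknown reaction in FVA request: ", reactions[k])
    e <- numeric(n + 1); e[j] <- 1
    lo <- lp_solve_bounded(e, A2, b2, lb2, ub2, maximize = FALSE, tol = tol)
    hi <- lp_solve_bounded(e, A2, b2, lb2, ub2, maximize = TRUE, tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for ", reactions[k])
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
  }
  swap <- out$min > out$max
  if (any(swap)) {  # numerical noise on degenerate ranges
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid; out$max[swap] <- mid
  }
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  attr(out, "optimum") <- opt
  out
}

#' Guard against solver precision loss on tiny coefficients
#'
#' Cofactor stoichiometries sit many orders of magnitude below ordinary
#' metabolic coefficients.  An LP solver silently treats coefficients near
#' its feasibility tolerance as zero, so the smallest coefficient must stay
#' at least two orders of magnitude (100x) above that tolerance.  The guard
#' reports the smallest absolute stoichiometric coefficient and bound in the
#' model, fails when the 100x rule is violated, and suggests a unit rescaling
#' exponent `k` for the offending cofactor species.
#'
#' @param model a `metabolic_model`.
#' @param solver_feasibility_tol the solver tolerance to guard against.
#' @return object of class `precision_report`: `pass`, `min_coefficient`,
#'   `min_bound`, `required` (= 100 * tol), `suggested_k` (NA when passing),
#'   `message`.
#' @export
precision_guard <- function(model, solver_feasibility_tol = 1e-9) {
  coefs <- abs(model$S[model$S != 0])
  bounds <- c(abs(model$reactions$lb), abs(model$reactions$ub))
  bounds <- bounds[bounds > 0]
  minc <- if (length(coefs)) min(coefs) else NA_real_
  minb <- if (length(bounds)) min(bounds) else NA_real_
  required <- 100 * solver_feasibility_tol
  pass <- is.na(minc) || minc >= required
  k <- if (pass) NA_integer_ else as.integer(ceiling(log10(required / minc)))
  msg <- if (pass) {
    sprintf("PASS: smallest coefficient %.3g is >= 100 x tolerance (%.3g)",
            minc, required)
  } else {
    sprintf(paste0("FAIL: smallest coefficient %.3g is below 100 x solver ",
                   "tolerance (%.3g); rescale the cofactor species' unit by ",
                   "10^k with k >= %d (see rescale_cofactor_species), or ",
                   "tighten the solver tolerance"), minc, required, k)
  }
  structure(list(pass = pass, min_coefficient = minc, min_bound = minb,
                 required = required, suggested_k = k, message = msg),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>", x$message, "\n")
  invisible(x)
}

#' Rescale the amount unit of designated cofactor species
#'
#' Expresses the listed species in a 10^-k smaller amount unit, multiplying
#' every stoichiometric coefficient in their matrix rows by `10^k`.  This is
#' a pure change of units: the steady-state balance rows are scaled by a
#' constant, so every feasible flux vector (and hence the growth optimum)
#' is unchanged, while the smallest coefficient magnitude rises by `10^k`.
#'
#' @param model a `metabolic_model`.
#' @param species_ids cofactor species to rescale.
#' @param k positive integer rescaling exponent.
#' @return the rescaled model.
#' @export
rescale_cofactor_species <- function(model, species_ids, k) {
  stopifnot(k == as.integer(k), k > 0)
  miss <- setdiff(species_ids, model$species$id)
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  model$S[species_ids, ] <- model$S[species_ids, , drop = FALSE] * 10^k
  rows <- model$cofactor_table$cofactor %in% species_ids
  if (any(rows))
    model$cofactor_table$coefficient[rows] <-
      model$cofactor_table$coefficient[rows] * 10^k
  model
}
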