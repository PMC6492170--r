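# Environmental and genetic perturbations, and flux-rewiring classification.

#' In-silico reduction of function (hemizygosity mimic)
#'
#' Uses flux as a proxy for the functional capacity of the enzyme: every
#' non-exchange reaction catalysed by the gene that carried wild-type flux
#' has its bounds capped at `fraction` times the wild-type flux magnitude in
#' the wild-type direction (the opposite direction is closed).  Nutrient
#' uptake exchanges are never capped, so the nutrient limitation of the
#' system is unchanged.
#'
#' @param model a `metabolic_model`.
#' @param gene gene whose function is reduced.
#' @param fraction capacity fraction in (0, 1); 0.5 mimics heterozygosity.
#' @param wild_type_solution a `flux_solution` for the unperturbed model.
#' @param tol fluxes below this magnitude count as zero.
#' @return the capped model.
#' @export
reduce_function <- function(model, gene, fraction, wild_type_solution,
                            tol = 1e-9) {
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  v <- wild_type_solution$fluxes
  touched <- 0L
  for (j in seq_len(nrow(model$reactions))) {
    if (model$reactions$is_exchange[j]) next
    g <- model$reactions$gpr[j]
    if (!nzchar(trimws(g)) || !(gene %in% gpr_genes(g))) next
    wj <- v[[model$reactions$id[j]]]
    if (is.na(wj) || abs(wj) <= tol) next
    if (wj > 0) {
      model$reactions$lb[j] <- 0
      model$reactions$ub[j] <- fraction * wj
    } else {
      model$reactions$lb[j] <- fraction * wj
      model$reactions$ub[j] <- 0
    }
    touched <- touched + 1L
  }
  if (touched == 0L)
    warning("gene '", gene, "' carried no wild-type flux; model unchanged")
  model
}

#' Scale the exchange bounds of a species
#'
#' Multiplies the bound magnitudes of every exchange reaction of the species
#' by `factor` (sign preserved), e.g. `factor = 0.1` imposes a 10 % medium
#' availability, `factor = 0` blocks the exchange.
#'
#' @param model a `metabolic_model`.
#' @param species species id whose exchanges are scaled.
#' @param factor non-negative scale factor.
#' @return the updated model.
#' @export
scale_exchange <- function(model, species, factor) {
  if (factor < 0) stop("scale factor must be >= 0")
  ex <- exchange_reactions(model, species)
  if (!length(ex)) stop("no exchange reaction found for species: ", species)
  for (rid in ex) {
    j <- match(rid, model$reactions$id)
    model$reactions$lb[j] <- model$reactions$lb[j] * factor
    model$reactions$ub[j] <- model$reactions$ub[j] * factor
  }
  model
}

#' Classify per-reaction flux changes between two solutions
#'
#' Relative change is `|v_new - v_ref| / max(|v_ref|, tolerance)`.  Labels:
#' * `inactive_both`: both fluxes within `tolerance` of zero;
#' * `rewired`: zero/nonzero transitions, sign flips, or (when
#'   `expected_scale` is given) any change that is neither unchanged nor the
#'   expected scaling;
#' * `unchanged`: relative change at most `tolerance`;
#' * `scaled_as_expected`: flux ratio within `tolerance` of
#'   `expected_scale` (only when given);
#' * `changed_above_threshold` / `changed_below_threshold`: relative change
#'   above/below `threshold` (only without `expected_scale`).
#'
#' The labels partition the compared reactions (the id intersection of the
#' two solutions).
#'
#' @param ref,new `flux_solution`s (or named flux vectors).
#' @param threshold relative-change threshold (default 0.25).
#' @param tolerance zero/equality tolerance (default 1e-6).
#' @param expected_scale optional expected flux ratio (e.g. 0.5 under a 50 %
#'   reduction of function).
#' @return object of class `flux_change_classification`: per-reaction data
#'   frame plus label counts.
#' @export
classify_flux_changes <- function(ref, new, threshold = 0.25,
                                  tolerance = 1e-6, expected_scale = NULL) {
  vr <- if (inherits(ref, "flux_solution")) ref$fluxes else ref
  vn <- if (inherits(new, "flux_solution")) new$fluxes else new
  ids <- intersect(names(vr), names(vn))
  if (!length(ids)) stop("solutions share no reactions")
  stopifnot(threshold > 0)
  vr <- vr[ids]; vn <- vn[ids]
  rel <- abs(vn - vr) / pmax(abs(vr), tolerance)
  zr <- abs(vr) <= tolerance; zn <- abs(vn) <= tolerance
  label <- character(length(ids))
  for (k in seq_along(ids)) {
    if (zr[k] && zn[k]) { label[k] <- "inactive_both"; next }
    if (xor(zr[k], zn[k]) || (!zr[k] && !zn[k] && sign(vr[k]) != sign(vn[k]))) {
      label[k] <- "rewired"; next
    }
    if (rel[k] <= tolerance) { label[k] <- "unchanged"; next }
    if (!is.null(expected_scale)) {
      ratio <- vn[k] / vr[k]
      label[k] <- if (abs(ratio - expected_scale) <= tolerance)
        "scaled_as_expected" else "rewired"
    } else {
      label[k] <- if (rel[k] > threshold) "changed_above_threshold"
      else "changed_below_threshold"
    }
  }
  lvls <- c("inactive_both", "unchanged", "scaled_as_expected",
            "changed_below_threshold", "changed_above_threshold", "rewired")
  counts <- table(factor(label, levels = lvls))
  structure(list(table = data.frame(reaction = ids, label = label,
                                    rel_change = unname(rel),
                                    stringsAsFactors = FALSE),
                 counts = counts, threshold = threshold,
                 tolerance = tolerance, expected_scale = expected_scale),
            class = "flux_change_classification")
}

#' @export
print.flux_change_classification <- function(x, ...) {
  cat("<flux_change_classification> threshold:", x$threshold, "\n")
  print(x$counts)
  invisible(x)
}

#' Sensitivity of the change counts to the threshold
#'
#' Reclassifies the flux changes at each threshold; the count of reactions
#' changed above threshold is non-increasing in the threshold.
#'
#' @param ref,new `flux_solution`s (or named flux vectors).
#' @param thresholds ascending numeric thresholds
#'   (e.g. `seq(0.15, 0.35, by = 0.05)`).
#' @param tolerance zero/equality tolerance.
#' @return data.frame: threshold, changed_above_threshold, plus the other
#'   label counts (which do not depend on the threshold).
#' @export
threshold_sensitivity <- function(ref, new, thresholds, tolerance = 1e-6) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  rows <- lapply(thresholds, function(th) {
    cl <- classify_flux_changes(ref, new, threshold = th, tolerance = tolerance)
    c(threshold = th, as.vector(cl$counts))
  })
  cl1 <- classify_flux_changes(ref, new, threshold = thresholds[1],
                               tolerance = tolerance)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("threshold", names(cl1$counts))
  out
}

apply_scenario <- function(model, scenario, wt_solution) {
  for (p in scenario) {
    model <- switch(p$type,
      scale_exchange = scale_exchange(model, p$species, p$factor),
      delete_gene = delete_gene(model, p$gene),
      reduce_function = reduce_function(model, p$gene, p$fraction, wt_solution),
      set_bound = set_bounds(model, p$reaction,
                             lb = if (is.null(p$lb)) NA else p$lb,
                             ub = if (is.null(p$ub)) NA else p$ub),
      stop("unknown perturbation type: ", p$type))
  }
  model
}

#' Qualitative benchmark of a perturbation scenario
#'
#' Applies the configured perturbations, re-optimises, and reports for each
#' reporter reaction whether its flux magnitude went `up`, `down` or stayed
#' the `same` (relative change below `tolerance`) against the unperturbed
#' control.  Flux magnitudes are compared, so an uptake reported by a
#' negative exchange flux "goes down" when less is taken up.
#'
#' @param model a validated `metabolic_model`.
#' @param scenario_config list of perturbations; each element is a list with
#'   a `type` (`"scale_exchange"`, `"delete_gene"`, `"reduce_function"`,
#'   `"set_bound"`) and its arguments.
#' @param reporters character vector of reporter reaction ids (e.g. oxygen
#'   exchange and the growth reaction).
#' @param tolerance relative tolerance below which a change counts as
#'   `same`; default 0.01.
#' @return named character vector: reporter -> `"up"`/`"down"`/`"same"`.
#' @export
qualitative_benchmark <- function(model, scenario_config, reporters,
                                  tolerance = 0.01) {
  miss <- setdiff(reporters, model$reactions$id)
  if (length(miss)) stop("missing reporter reactions: ",
                         paste(miss, collapse = ", "))
  ctrl <- optimize_growth(model, selection_rule = "min_total_flux")
  if (ctrl$status != "optimal") stop("control model is ", ctrl$status)
  pert_model <- apply_scenario(model, scenario_config, ctrl)
  pert <- optimize_growth(pert_model, selection_rule = "min_total_flux")
  out <- stats::setNames(character(length(reporters)), reporters)
  for (r in reporters) {
    a <- abs(ctrl$fluxes[[r]])
    b <- if (pert$status == "optimal") abs(pert$fluxes[[r]]) else 0
    rel <- abs(b - a) / max(a, tolerance)
    out[r] <- if (rel < tolerance) "same" else if (b > a) "up" else "down"
  }
  out
}
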