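# Structural queries: dead-end detection and model diffing.

#' Detect dead-end species
#'
#' A dead-end species is one that can never be produced, or never consumed,
#' by any reaction able to carry flux.  Reversible reactions (lb < 0 < ub)
#' count as both producers and consumers of each participant; exchange
#' reactions count like any other reaction, so a species with a reversible
#' exchange is never a dead end.  Reactions with bounds fixed to zero are
#' ignored.
#'
#' @param model a `metabolic_model`.
#' @param include_pseudo include pseudo-metabolites in the report (default
#'   `TRUE`, matching reconstructions that count scaffold/signal species among
#'   their dead ends).
#' @return character vector of dead-end species ids.
#' @export
find_dead_ends <- function(model, include_pseudo = TRUE) {
  ns <- nrow(model$species)
  produced <- consumed <- logical(ns)
  names(produced) <- names(consumed) <- model$species$id
  for (j in seq_len(nrow(model$reactions))) {
    lb <- model$reactions$lb[j]; ub <- model$reactions$ub[j]
    fwd <- ub > 0
    bwd <- lb < 0
    if (!fwd && !bwd) next
    col <- model$S[, j]
    pos <- col > 0; neg <- col < 0
    if (fwd) { produced <- produced | pos; consumed <- consumed | neg }
    if (bwd) { produced <- produced | neg; consumed <- consumed | pos }
    if (model$reactions$is_exchange[j]) {
      # an exchange sink/source makes its species both producible and
      # consumable in the direction(s) the bounds allow; a one-species
      # reaction already behaves this way, nothing more to do.
    }
  }
  dead <- !(produced & consumed)
  ids <- model$species$id[dead]
  if (!include_pseudo) {
    pseudo <- model$species$id[model$species$category == "pseudo_metabolite"]
    ids <- setdiff(ids, pseudo)
  }
  ids
}

canonical_reaction_key <- function(model, j) {
  col <- model$S[, j]
  nz <- which(col != 0)
  if (!length(nz)) return(paste0("empty:", model$reactions$id[j]))
  ids <- rownames(model$S)[nz]
  o <- order(ids)
  paste(paste0(ids[o], ":", signif(col[nz][o], 12)), collapse = "|")
}

#' Diff two models
#'
#' Reactions are matched by id; optionally, reactions whose ids do not match
#' are paired by canonicalised stoichiometry (`match_by_stoich = TRUE`).
#' A matched reaction counts as *modified* when its stoichiometry, bounds or
#' normalised GPR differ.  Species are compared by id only.
#'
#' @param base,extended models to compare (base first).
#' @param match_by_stoich also match id-mismatched reactions by identical
#'   stoichiometry.
#' @param tol numeric tolerance for stoichiometry/bound comparison.
#' @return an object of class `model_diff` with added/removed/modified/
#'   matched reaction ids and added/removed species ids.
#' @export
diff_models <- function(base, extended, match_by_stoich = FALSE, tol = 1e-9) {
  bi <- base$reactions$id; ei <- extended$reactions$id
  matched <- intersect(bi, ei)
  added <- setdiff(ei, bi)
  removed <- setdiff(bi, ei)
  pairs <- data.frame(base = matched, extended = matched,
                      stringsAsFactors = FALSE)
  if (match_by_stoich && length(added) && length(removed)) {
    bkey <- vapply(match(removed, bi), function(j) canonical_reaction_key(base, j),
                   character(1))
    ekey <- vapply(match(added, ei), function(j) canonical_reaction_key(extended, j),
                   character(1))
    hit <- match(ekey, bkey)
    ok <- !is.na(hit) & !duplicated(hit)
    if (any(ok)) {
      pairs <- rbind(pairs, data.frame(base = removed[hit[ok]],
                                       extended = added[ok],
                                       stringsAsFactors = FALSE))
      added <- setdiff(added, added[ok])
      removed <- setdiff(removed, removed[hit[ok]])
    }
  }
  modified <- character()
  for (k in seq_len(nrow(pairs))) {
    jb <- match(pairs$base[k], bi); je <- match(pairs$extended[k], ei)
    colb <- base$S[, jb]; cole <- extended$S[, je]
    nb <- colb[colb != 0]; ne <- cole[cole != 0]
    same_stoich <- setequal(names(nb), names(ne)) &&
      (!length(nb) || max(abs(nb[names(nb)] - ne[names(nb)])) <= tol)
    same_bounds <- abs(base$reactions$lb[jb] - extended$reactions$lb[je]) <= tol &&
      abs(base$reactions$ub[jb] - extended$reactions$ub[je]) <= tol
    same_gpr <- gpr_normalise(base$reactions$gpr[jb]) ==
      gpr_normalise(extended$reactions$gpr[je])
    if (!(same_stoich && same_bounds && same_gpr))
      modified <- c(modified, pairs$extended[k])
  }
  structure(list(
    added_species = setdiff(extended$species$id, base$species$id),
    removed_species = setdiff(base$species$id, extended$species$id),
    added_reactions = added,
    removed_reactions = removed,
    modified_reactions = modified,
    matched_reactions = pairs$extended
  ), class = "model_diff")
}

#' @export
print.model_diff <- function(x, ...) {
  cat("<model_diff>\n")
  cat("  added species:     ", length(x$added_species), "\n")
  cat("  removed species:   ", length(x$removed_species), "\n")
  cat("  added reactions:   ", length(x$added_reactions), "\n")
  cat("  removed reactions: ", length(x$removed_reactions), "\n")
  cat("  modified reactions:", length(x$modified_reactions), "\n")
  cat("  matched reactions: ", length(x$matched_reactions), "\n")
  invisible(x)
}
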