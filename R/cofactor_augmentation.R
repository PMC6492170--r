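# Cofactor augmentation.
#
# A non-consumed cofactor X of an enzyme catalysing  aA + bB <=> cC + dD
# enters the reaction as a substrate and leaves as a catalytically inactive
# product:  aA + bB + xX <=> cC + dD + xX.  Written literally, the two xX
# terms cancel in the stoichiometric matrix, so the requirement cannot bind
# cofactor availability in a plain LP.  The default mode therefore splits
# the cofactor into a free pool (the species itself) and an auto-created
# spent pool:  aA + bB + x X -> cC + dD + x X_spent,  with a drain closing
# the spent pool.  Availability of X then genuinely limits flux, and the
# summed flux into the spent pools gives the cofactor turnover a concrete
# meaning.  The literal both-sides mode is retained for fidelity; it is
# recorded in the requirement table but never changes any optimum.

#' Build a cofactor requirement table
#'
#' @param reaction_id reaction ids (recycled against the other arguments).
#' @param cofactor cofactor species ids.
#' @param coefficient non-negative dimensionless stoichiometries (amount of
#'   cofactor recruited per catalytic event).
#' @param mode `"free_to_spent"` (default, binding) or
#'   `"literal_both_sides"` (net-zero, non-binding).
#' @return a data.frame usable by [augment_model()].
#' @export
cofactor_requirement <- function(reaction_id, cofactor, coefficient,
                                 mode = "free_to_spent") {
  df <- data.frame(reaction_id = reaction_id, cofactor = cofactor,
                   coefficient = as.numeric(coefficient), mode = mode,
                   stringsAsFactors = FALSE)
  if (any(df$coefficient < 0)) stop("cofactor coefficients must be >= 0")
  if (!all(df$mode %in% c("free_to_spent", "literal_both_sides")))
    stop("unknown augmentation mode")
  df
}

#' Read a cofactor requirement table from TSV
#'
#' Expected columns: `reaction_id`, `cofactor_species`, `coefficient`, and
#' optionally `mode`.
#'
#' @param path TSV file path.
#' @return requirement data.frame.
#' @export
read_cofactor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "cofactor_species", "coefficient")
  if (!all(need %in% names(df)))
    stop("cofactor table must have columns: ", paste(need, collapse = ", "))
  cofactor_requirement(df$reaction_id, df$cofactor_species, df$coefficient,
                       mode = if ("mode" %in% names(df)) df$mode else "free_to_spent")
}

#' Write a cofactor requirement table as TSV
#' @param table requirement data.frame.
#' @param path output path.
#' @export
write_cofactor_table <- function(table, path) {
  out <- data.frame(reaction_id = table$reaction_id,
                    cofactor_species = table$cofactor,
                    coefficient = table$coefficient,
                    mode = table$mode)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

spent_id <- function(cofactor) paste0(cofactor, "_spent")
drain_id <- function(spent) paste0("DM_", spent)

#' Augment one reaction with a cofactor requirement
#'
#' In `free_to_spent` mode, adds `x` units of the cofactor species as a
#' substrate and `x` units of an auto-created spent companion species as a
#' product, together with a drain reaction for the spent pool; the original
#' metabolites are untouched.  In `literal_both_sides` mode the net matrix
#' entry is zero, so only the requirement record changes.  A requirement with
#' `x = 0` is recorded but leaves the stoichiometry unchanged.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to augment.
#' @param cofactor cofactor species id (must exist).
#' @param coefficient non-negative stoichiometry `x`.
#' @param mode augmentation mode, see [cofactor_requirement()].
#' @return the updated model (requirement recorded in
#'   `model$cofactor_table`).
#' @export
augment_reaction <- function(model, reaction_id, cofactor, coefficient,
                             mode = c("free_to_spent", "literal_both_sides")) {
  mode <- match.arg(mode)
  if (coefficient < 0) stop("negative cofactor coefficient")
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction_id)
  if (!cofactor %in% model$species$id)
    stop("missing cofactor species: ", cofactor)
  dup <- model$cofactor_table$reaction_id == reaction_id &
    model$cofactor_table$cofactor == cofactor
  if (any(dup))
    stop("duplicate cofactor requirement for (", reaction_id, ", ", cofactor, ")")
  if (mode == "free_to_spent" && coefficient > 0) {
    sp <- spent_id(cofactor)
    if (!sp %in% model$species$id) {
      comp <- model$species$compartment[match(cofactor, model$species$id)]
      cat_ <- model$species$category[match(cofactor, model$species$id)]
      model <- add_species(model, sp, name = paste(cofactor, "(spent pool)"),
                           compartment = comp, category = cat_,
                           sbo = model$species$sbo[match(cofactor, model$species$id)])
    }
    model$S[cofactor, j] <- model$S[cofactor, j] - coefficient
    model$S[sp, j] <- model$S[sp, j] + coefficient
    dr <- drain_id(sp)
    if (!dr %in% model$reactions$id) {
      st <- stats::setNames(-1, sp)
      model <- add_reaction(model, dr, st, lb = 0, ub = 1000,
                            name = paste("drain of", sp), is_exchange = TRUE)
    }
  }
  model$cofactor_table <- rbind(model$cofactor_table,
                                data.frame(reaction_id = reaction_id,
                                           cofactor = cofactor,
                                           coefficient = coefficient,
                                           mode = mode,
                                           stringsAsFactors = FALSE))
  model
}

#' Apply a cofactor requirement table to a model
#'
#' Applies [augment_reaction()] row by row; duplicate (reaction, cofactor)
#' rows are rejected up front, listing the offenders.
#'
#' @param model a `metabolic_model`.
#' @param table requirement table from [cofactor_requirement()] /
#'   [read_cofactor_table()].
#' @return the augmented model.
#' @export
augment_model <- function(model, table) {
  if (nrow(table) == 0) return(model)
  key <- paste(table$reaction_id, table$cofactor)
  if (anyDuplicated(key))
    stop("duplicate cofactor requirement rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  for (k in seq_len(nrow(table))) {
    model <- augment_reaction(model, table$reaction_id[k], table$cofactor[k],
                              table$coefficient[k], table$mode[k])
  }
  model
}

#' Derive a flux bound from an uptake-affinity threshold concentration
#'
#' High- and low-affinity metal uptake systems switch at a characteristic
#' extracellular concentration (1 uM for iron, 20 uM for copper).  The
#' threshold concentration is converted into a threshold flux bound with a
#' medium-dependent conversion factor (mmol/gDW/h per uM).
#'
#' @param ion `"iron"` or `"copper"` (informational).
#' @param threshold_concentration threshold in uM; defaults: iron 1, copper 20.
#' @param conversion_factor mmol/gDW/h per uM; must be positive.
#' @return object of class `affinity_threshold` with the `derived_flux_bound`.
#' @export
affinity_threshold <- function(ion = c("iron", "copper"),
                               threshold_concentration = NULL,
                               conversion_factor) {
  ion <- match.arg(ion)
  if (is.null(threshold_concentration))
    threshold_concentration <- switch(ion, iron = 1, copper = 20)
  if (threshold_concentration <= 0 || conversion_factor <= 0)
    stop("threshold concentration and conversion factor must be positive")
  structure(list(ion = ion,
                 threshold_concentration = threshold_concentration,
                 conversion_factor = conversion_factor,
                 derived_flux_bound = threshold_concentration * conversion_factor),
            class = "affinity_threshold")
}

#' Threshold flux bound of an affinity threshold
#' @param th an `affinity_threshold`.
#' @return the derived flux bound (mmol/gDW/h).
#' @export
threshold_to_bound <- function(th) {
  stopifnot(inherits(th, "affinity_threshold"))
  th$derived_flux_bound
}

#' Build an empty/sulphonylated scaffold cycle for Fe-S cluster biogenesis
#'
#' Adds the pseudo-metabolites ES (empty scaffold) and SS (sulphonylated
#' scaffold) and, per configured cluster type, two unbounded reaction
#' templates: (i) scaffold loading, `ES + donor -> SS`; and (ii) cluster
#' maturation, `SS + n_fe * iron -> cluster + ES` (multiple maturation routes
#' per cluster each get their own (ii)-type reaction).  ES + SS is a
#' conserved moiety: the indicator vector on `{ES, SS}` is a left null
#' vector of every added column, so at steady state the loading flux always
#' equals the total maturation flux.
#'
#' @param model a `metabolic_model`.
#' @param config list with elements:
#'   * `donor`: sulphur donor species id (e.g. mitochondrial L-cysteine);
#'   * `iron`: iron species id consumed by maturation;
#'   * `compartment`: compartment for the scaffold species;
#'   * `clusters`: list of cluster configs, each a list with `species` (the
#'     cluster product id, created if absent), `iron_per_cluster` (default 2)
#'     and `routes` (character vector of GPR rules, one maturation reaction
#'     per route; default one orphan route).
#' @return the extended model, with the circuit recorded in
#'   `model$annotations$circuits`.
#' @export
build_scaffold_cycle <- function(model, config) {
  for (f in c("donor", "iron", "compartment", "clusters"))
    if (is.null(config[[f]])) stop("scaffold config missing field: ", f)
  if (!config$donor %in% model$species$id)
    stop("missing donor species: ", config$donor)
  if (!config$iron %in% model$species$id)
    stop("missing iron species: ", config$iron)
  comp <- config$compartment
  es <- paste0("ES_", comp); ss <- paste0("SS_", comp)
  if (!es %in% model$species$id)
    model <- add_species(model, es, "empty scaffold", comp, "pseudo_metabolite")
  if (!ss %in% model$species$id)
    model <- add_species(model, ss, "sulphonylated scaffold", comp,
                         "pseudo_metabolite")
  coupled <- list()
  for (cl in config$clusters) {
    sp <- cl$species
    nfe <- if (is.null(cl$iron_per_cluster)) 2 else cl$iron_per_cluster
    routes <- if (is.null(cl$routes)) "" else cl$routes
    if (!sp %in% model$species$id)
      model <- add_species(model, sp, sp, comp, "metabolite")
    load_id <- paste0(sp, "_scaffold_load")
    st <- stats::setNames(c(-1, -1, 1), c(es, config$donor, ss))
    model <- add_reaction(model, load_id, st, lb = 0, ub = 1000,
                          gpr = if (is.null(cl$load_gpr)) "" else cl$load_gpr,
                          name = paste("scaffold loading for", sp))
    coupled[[length(coupled) + 1L]] <- c(load_id, "producer")
    for (r in seq_along(routes)) {
      mat_id <- paste0(sp, "_maturation", if (length(routes) > 1) paste0("_", r) else "")
      st <- stats::setNames(c(-1, -nfe, 1, 1), c(ss, config$iron, sp, es))
      model <- add_reaction(model, mat_id, st, lb = 0, ub = 1000,
                            gpr = routes[r],
                            name = paste("cluster maturation for", sp))
      coupled[[length(coupled) + 1L]] <- c(mat_id, "consumer")
    }
  }
  circ <- list(circuit_id = paste0("scaffold_", comp),
               members = c(es, ss),
               coupled_reactions = coupled, unbounded = TRUE)
  model$annotations$circuits <- c(model$annotations$circuits, list(circ))
  model
}

#' Wire the iron-regulon signalling circuit
#'
#' Adds the pseudo-metabolites PS (iron availability signal) and AS (iron
#' depletion signal) plus a spent-signal relay SIG, and couples them so that
#' (a) every scaffold maturation reaction consumes PS in the mitochondrion
#' and emits SIG, (b) a branch reaction converts PS into AS (the depletion
#' signal produced when PS cannot be used for biogenesis), (c) AS is relayed
#' to the cell envelope where it is a required co-substrate of high-affinity
#' iron uptake, and (d) the envelope regenerates PS from the returned spent
#' signal.  All relay reactions are unbounded and mass/energy neutral, and
#' the total PS + AS + SIG pool is a conserved moiety, so the circuit never
#' accumulates and never binds when it is not exercised.
#'
#' @param model a `metabolic_model` already carrying a scaffold cycle.
#' @param config list with elements: `high_affinity_uptake` (character
#'   vector of uptake reaction ids that must require the depletion signal),
#'   `mito_compartment`, `envelope_compartment`, and optionally `relay_gpr`
#'   (GPR for the envelope-to-mitochondrion PS relay, e.g. a karyopherin
#'   gene).
#' @return the extended model.
#' @export
build_regulon_circuit <- function(model, config) {
  circs <- model$annotations$circuits
  has_scaffold <- length(circs) &&
    any(vapply(circs, function(x) startsWith(x$circuit_id, "scaffold"), logical(1)))
  if (!has_scaffold)
    stop("regulon circuit requires a scaffold cycle; run build_scaffold_cycle first")
  ups <- config$high_affinity_uptake
  if (is.null(ups) || !all(ups %in% model$reactions$id))
    stop("high-affinity uptake reactions not found in model")
  mc <- config$mito_compartment; ec <- config$envelope_compartment
  ps_m <- paste0("PS_", mc); ps_e <- paste0("PS_", ec)
  as_m <- paste0("AS_", mc); as_e <- paste0("AS_", ec)
  sig_m <- paste0("SIG_", mc); sig_e <- paste0("SIG_", ec)
  for (sp in list(c(ps_m, mc), c(ps_e, ec), c(as_m, mc), c(as_e, ec),
                  c(sig_m, mc), c(sig_e, ec)))
    model <- add_species(model, sp[1], sp[1], sp[2], "pseudo_metabolite")
  relay_gpr <- if (is.null(config$relay_gpr)) "" else config$relay_gpr
  model <- add_reaction(model, "PS_relay",
                        stats::setNames(c(-1, 1), c(ps_e, ps_m)),
                        lb = 0, ub = 1000, gpr = relay_gpr,
                        name = "availability signal relay to mitochondrion")
  model <- add_reaction(model, "AS_branch",
                        stats::setNames(c(-1, 1), c(ps_m, as_m)),
                        lb = 0, ub = 1000,
                        name = "depletion signal branch")
  model <- add_reaction(model, "AS_relay",
                        stats::setNames(c(-1, 1), c(as_m, as_e)),
                        lb = 0, ub = 1000,
                        name = "depletion signal relay to envelope")
  model <- add_reaction(model, "SIG_relay",
                        stats::setNames(c(-1, 1), c(sig_m, sig_e)),
                        lb = 0, ub = 1000,
                        name = "spent signal relay to envelope")
  model <- add_reaction(model, "SIG_regen",
                        stats::setNames(c(-1, 1), c(sig_e, ps_e)),
                        lb = 0, ub = 1000,
                        name = "availability signal regeneration at envelope")
  # maturation reactions consume PS and emit the spent signal
  mat <- grep("_maturation", model$reactions$id, value = TRUE)
  for (rid in mat) {
    j <- match(rid, model$reactions$id)
    model$S[ps_m, j] <- model$S[ps_m, j] - 1
    model$S[sig_m, j] <- model$S[sig_m, j] + 1
  }
  # high-affinity uptake requires the depletion signal at the envelope
  for (rid in ups) {
    j <- match(rid, model$reactions$id)
    model$S[as_e, j] <- model$S[as_e, j] - 1
    model$S[sig_e, j] <- model$S[sig_e, j] + 1
  }
  circ <- list(circuit_id = "iron_regulon",
               members = c(ps_m, ps_e, as_m, as_e, sig_m, sig_e),
               coupled_reactions = lapply(
                 c("PS_relay", "AS_branch", "AS_relay", "SIG_relay", "SIG_regen"),
                 function(x) c(x, "relay")),
               unbounded = TRUE)
  model$annotations$circuits <- c(model$annotations$circuits, list(circ))
  model
}

#' Couple haem biosynthesis genes to low-affinity iron uptake
#'
#' Haem deficiency signals low iron uptake: deletion of any essential haem
#' biosynthesis gene must disable the low-affinity uptake route.  The uptake
#' reaction's GPR becomes `(existing GPR) and g1 and g2 ...`.
#'
#' @param model a `metabolic_model`.
#' @param haem_gene_ids character vector of haem pathway gene ids (an empty
#'   vector leaves the rule unchanged).
#' @param uptake_reaction_id the low-affinity uptake reaction.
#' @return the updated model.
#' @export
couple_haem_to_low_affinity <- function(model, haem_gene_ids,
                                        uptake_reaction_id) {
  j <- match(uptake_reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", uptake_reaction_id)
  if (!length(haem_gene_ids)) return(model)
  old <- model$reactions$gpr[j]
  conj <- paste(haem_gene_ids, collapse = " and ")
  model$reactions$gpr[j] <- if (nzchar(trimws(old)))
    paste0("(", old, ") and ", conj) else conj
  model$genes <- sort(union(model$genes, haem_gene_ids))
  model
}
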