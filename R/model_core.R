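#' @title Stoichiometric model container
#'
#' @description
#' A `metabolic_model` is a plain list holding the usual ingredients of a
#' constraint-based reconstruction: a species table, a reaction table, a dense
#' stoichiometric matrix `S` (species x reactions, substrates negative,
#' products positive), a gene inventory derived from the gene-protein-reaction
#' (GPR) rules, a compartment list and a single maximisation objective
#' (normally the growth/biomass reaction).
#'
#' Species fall into three categories: ordinary `metabolite`s,
#' `enzyme_species` (protein species represented explicitly in the network)
#' and `pseudo_metabolite`s.  Pseudo-metabolites are bookkeeping species that
#' carry no mass, energy or redox contribution; they are tagged with the SBO
#' term `SBO:0000409` ("interaction outcome") and are used to encode scaffold
#' cycles and regulatory signal relays.
#'
#' @param id model identifier.
#' @param compartments character vector of compartment ids (a name attribute,
#'   if present, is kept as the display name).
#' @param default_growth_rate assumed specific growth rate in 1/h used when
#'   converting medium concentrations to flux bounds; defaults to 0.1.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id = "model",
                            compartments = c(e = "extracellular", c = "cytoplasm"),
                            default_growth_rate = 0.1) {
  comp_ids <- if (is.null(names(compartments))) compartments else names(compartments)
  comp_names <- unname(compartments)
  m <- structure(list(
    id = id,
    species = data.frame(id = character(), name = character(),
                         compartment = character(), category = character(),
                         sbo = character(), stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), name = character(),
                           lb = numeric(), ub = numeric(), gpr = character(),
                           is_exchange = logical(), membrane_spanning = logical(),
                           stringsAsFactors = FALSE),
    S = matrix(0, nrow = 0, ncol = 0),
    genes = character(),
    compartments = data.frame(id = comp_ids, name = comp_names,
                              stringsAsFactors = FALSE),
    objective = NA_character_,
    default_growth_rate = default_growth_rate,
    cofactor_table = empty_cofactor_table(),
    annotations = list()
  ), class = "metabolic_model")
  m
}

#' Add a species to a model
#'
#' @param model a `metabolic_model`.
#' @param id species identifier (unique within the model).
#' @param name display name.
#' @param compartment compartment id; must be declared in the model.
#' @param category one of `"metabolite"`, `"enzyme_species"`,
#'   `"pseudo_metabolite"`.
#' @param sbo SBO term; pseudo-metabolites default to `"SBO:0000409"`.
#' @return the updated model.
#' @export
add_species <- function(model, id, name = id, compartment,
                        category = c("metabolite", "enzyme_species",
                                     "pseudo_metabolite"),
                        sbo = NA_character_) {
  category <- match.arg(category)
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$species$id)
    stop("species id already present: ", id)
  if (!compartment %in% model$compartments$id)
    stop("species '", id, "' placed in undeclared compartment '", compartment, "'")
  if (category == "pseudo_metabolite" && is.na(sbo)) sbo <- "SBO:0000409"
  model$species <- rbind(model$species,
                         data.frame(id = id, name = name, compartment = compartment,
                                    category = category, sbo = sbo,
                                    stringsAsFactors = FALSE))
  model$S <- rbind(model$S, matrix(0, 1, ncol(model$S)))
  rownames(model$S) <- model$species$id
  if (ncol(model$S) > 0) colnames(model$S) <- model$reactions$id
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction identifier.
#' @param stoich named numeric vector of stoichiometric coefficients
#'   (substrates negative, products positive); every name must be a declared
#'   species id.  May be empty only for declared exchange sinks.
#' @param lb,ub flux bounds in mmol/gDW/h; `lb <= ub` is enforced.
#' @param gpr gene-protein-reaction boolean rule, e.g.
#'   `"(g1 and g2) or g3"`; `and` encodes a complex, `or` isoenzymes.
#' @param name display name.
#' @param is_exchange logical; defaults to `TRUE` when the reaction touches a
#'   single species.
#' @param membrane_spanning logical flag for reactions represented across a
#'   membrane.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoich, lb = 0, ub = 1000, gpr = "",
                         name = id, is_exchange = NULL,
                         membrane_spanning = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$reactions$id)
    stop("reaction id already present: ", id)
  if (!is.finite(lb)) lb <- -1000
  if (!is.finite(ub)) ub <- 1000
  if (lb > ub) stop("reaction '", id, "': lower bound exceeds upper bound")
  if (is.null(is_exchange)) is_exchange <- length(stoich) == 1L
  if (length(stoich) == 0L && !is_exchange)
    stop("reaction '", id, "' has empty stoichiometry and is not an exchange sink")
  unknown <- setdiff(names(stoich), model$species$id)
  if (length(unknown))
    stop("reaction '", id, "' references unknown species: ",
         paste(unknown, collapse = ", "))
  model$reactions <- rbind(model$reactions,
                           data.frame(id = id, name = name, lb = lb, ub = ub,
                                      gpr = gpr, is_exchange = is_exchange,
                                      membrane_spanning = membrane_spanning,
                                      stringsAsFactors = FALSE))
  col <- numeric(nrow(model$S))
  names(col) <- rownames(model$S)
  if (length(stoich)) col[names(stoich)] <- as.numeric(stoich)
  model$S <- cbind(model$S, col)
  colnames(model$S) <- model$reactions$id
  model$genes <- sort(union(model$genes, gpr_genes(gpr)))
  model
}

#' Set the maximisation objective of a model
#'
#' @param model a `metabolic_model`.
#' @param reaction_id id of the (growth/biomass) reaction to maximise.
#' @return the updated model.
#' @export
set_objective <- function(model, reaction_id) {
  if (!reaction_id %in% model$reactions$id)
    stop("objective reaction not in model: ", reaction_id)
  model$objective <- reaction_id
  model
}

#' Replace the flux bounds of a reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; `NA` keeps the current value.
#' @return the updated model.
#' @export
set_bounds <- function(model, reaction_id, lb = NA, ub = NA) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  if (!is.na(lb)) model$reactions$lb[i] <- lb
  if (!is.na(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i])
    stop("reaction '", reaction_id, "': lower bound exceeds upper bound")
  model
}

#' Retrieve the stoichiometry of one reaction as a named vector
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @return named numeric vector (nonzero entries only).
#' @export
reaction_stoich <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  col <- model$S[, i]
  col[col != 0]
}

#' Find the exchange reactions of a species
#'
#' An exchange reaction is one flagged `is_exchange` whose stoichiometry
#' involves the species.
#'
#' @param model a `metabolic_model`.
#' @param species_id species id.
#' @return character vector of reaction ids (possibly empty).
#' @export
exchange_reactions <- function(model, species_id) {
  if (!species_id %in% model$species$id)
    stop("unknown species: ", species_id)
  hit <- model$reactions$is_exchange & model$S[species_id, ] != 0
  model$reactions$id[hit]
}

#' Validate the structural invariants of a model
#'
#' Checks id uniqueness, compartment declarations, bound ordering, matrix
#' dimensions, pseudo-metabolite SBO tagging, the gene inventory and the
#' objective declaration.  Invisibly returns the model on success; stops with
#' an informative message on the first violation.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$species$id))
    stop("duplicate species ids")
  if (anyDuplicated(model$reactions$id))
    stop("duplicate reaction ids")
  bad <- setdiff(model$species$compartment, model$compartments$id)
  if (length(bad))
    stop("species placed in undeclared compartments: ", paste(bad, collapse = ", "))
  if (any(model$reactions$lb > model$reactions$ub))
    stop("reaction with lower bound above upper bound")
  if (nrow(model$S) != nrow(model$species) || ncol(model$S) != nrow(model$reactions))
    stop("stoichiometric matrix dimensions inconsistent with tables")
  pseudo <- model$species$category == "pseudo_metabolite"
  if (any(pseudo & (is.na(model$species$sbo) | model$species$sbo != "SBO:0000409")))
    stop("pseudo-metabolite without SBO:0000409 tag")
  declared <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  if (!setequal(declared, model$genes))
    stop("gene set out of step with GPR rules")
  if (is.na(model$objective))
    stop("no objective reaction set; use set_objective() to declare the ",
         "growth/biomass reaction before optimising")
  if (!model$objective %in% model$reactions$id)
    stop("objective reaction absent from model: ", model$objective)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  species:   ", nrow(x$species),
      " (", sum(x$species$category == "pseudo_metabolite"), " pseudo)\n", sep = "")
  cat("  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n", sep = "")
  cat("  genes:     ", length(x$genes), "\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

# shared empty cofactor requirement table
empty_cofactor_table <- function() {
  data.frame(reaction_id = character(), cofactor = character(),
             coefficient = numeric(), mode = character(),
             stringsAsFactors = FALSE)
}

#' Structural equality of two models
#'
#' Used by the SBML round-trip tests: compares species (id, compartment,
#' category, SBO), reactions (id, bounds, normalised GPR), stoichiometry and
#' the objective, all up to row/column order.
#'
#' @param a,b models to compare.
#' @param tol numeric tolerance on stoichiometric coefficients and bounds.
#' @return logical.
#' @export
models_equivalent <- function(a, b, tol = 1e-9) {
  if (!setequal(a$species$id, b$species$id)) return(FALSE)
  if (!setequal(a$reactions$id, b$reactions$id)) return(FALSE)
  sa <- a$species[order(a$species$id), ]
  sb <- b$species[order(b$species$id), ]
  if (!all(sa$compartment == sb$compartment) ||
      !all(sa$category == sb$category)) return(FALSE)
  # an unset SBO term is equivalent to the category default
  sboa <- ifelse(is.na(sa$sbo), SBO_BY_CATEGORY[sa$category], sa$sbo)
  sbob <- ifelse(is.na(sb$sbo), SBO_BY_CATEGORY[sb$category], sb$sbo)
  if (!all(sboa == sbob)) return(FALSE)
  ra <- a$reactions[order(a$reactions$id), ]
  rb <- b$reactions[order(b$reactions$id), ]
  if (any(abs(ra$lb - rb$lb) > tol) || any(abs(ra$ub - rb$ub) > tol)) return(FALSE)
  if (!all(gpr_normalise(ra$gpr) == gpr_normalise(rb$gpr))) return(FALSE)
  Sa <- a$S[order(rownames(a$S)), order(colnames(a$S)), drop = FALSE]
  Sb <- b$S[order(rownames(b$S)), order(colnames(b$S)), drop = FALSE]
  if (max(abs(Sa - Sb)) > tol) return(FALSE)
  identical(a$objective, b$objective)
}
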