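# Biomass cofactor coefficients.
#
# Iron entities (haems, Fe-S clusters, mono-iron centres) are anchored to
# proteins through specific amino-acid residues in characteristic ratios
# (e.g. one haem b per cysteine, a Rieske 2Fe-2S per 2 His + 2 Cys).  Given
# the biomass stoichiometric coefficients of the amino acids and the
# fraction of the proteome carrying each entity, a biomass coefficient for
# the entity itself can be reconstructed:
#
#   c_e = p_e * ( sum of the binding amino acids' biomass coefficients )
#               / ( total residues binding one entity ).
#
# The formula is deliberately isolated behind a strategy interface so an
# alternative weighting can be swapped in without touching callers.

#' Amino-acid binding rules for iron entities
#'
#' One row per (entity, amino acid) pair; entities bound through several
#' amino acids (e.g. Rieske 2Fe-2S) take several rows whose ratios add up to
#' the total residues per entity.
#'
#' @param entity entity names (e.g. `"haem_b"`, `"4Fe-4S"`).
#' @param amino_acid binding amino acid names.
#' @param ratio residues of that amino acid per entity (positive integers).
#' @return a binding-rule data.frame.
#' @export
binding_rules <- function(entity, amino_acid, ratio) {
  df <- data.frame(entity = entity, amino_acid = amino_acid,
                   ratio = as.numeric(ratio), stringsAsFactors = FALSE)
  if (any(df$ratio < 1)) stop("binding ratios must be >= 1")
  if (anyDuplicated(paste(df$entity, df$amino_acid)))
    stop("duplicate (entity, amino acid) rule")
  df
}

#' Read binding rules from a TSV table (`entity  amino_acid  ratio`)
#' @param path TSV path.
#' @return binding-rule data.frame.
#' @export
read_binding_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entity", "amino_acid", "ratio")
  if (!all(need %in% names(df)))
    stop("binding rules table must have columns: ", paste(need, collapse = ", "))
  binding_rules(df$entity, df$amino_acid, df$ratio)
}

#' Default ratio-weighted coefficient strategy
#'
#' `c_e = p_e * sum(c_a) / sum(r)` over the entity's rules.
#'
#' @param p_e proteome fraction of proteins bearing the entity.
#' @param aa_coeffs biomass coefficients of the entity's binding amino acids
#'   (mmol/gDW).
#' @param ratios residues per entity for each amino acid.
#' @return the entity's biomass coefficient (mmol/gDW).
#' @export
ratio_weighted_strategy <- function(p_e, aa_coeffs, ratios) {
  p_e * sum(aa_coeffs) / sum(ratios)
}

#' Biomass coefficients of iron entities
#'
#' @param aa_biomass_coefficients named numeric vector: amino acid ->
#'   biomass coefficient (mmol/gDW), all non-negative.
#' @param entity_proteome_fraction named numeric vector: entity -> fraction
#'   of the proteome carried by proteins bearing that entity, in `[0, 1]`.
#'   Whether this fraction is a residue-count, protein-copy or mass fraction
#'   is a property of the upstream proteomics summary; the formula treats it
#'   as a dimensionless weight.
#' @param rules binding rules from [binding_rules()].
#' @param strategy plug-in function `(p_e, aa_coeffs, ratios) -> coefficient`;
#'   defaults to [ratio_weighted_strategy()].
#' @return named numeric vector: entity -> biomass coefficient (mmol/gDW).
#' @export
biomass_cofactor_coefficients <- function(aa_biomass_coefficients,
                                          entity_proteome_fraction,
                                          rules,
                                          strategy = ratio_weighted_strategy) {
  if (any(aa_biomass_coefficients < 0)) stop("amino acid coefficients must be >= 0")
  if (any(entity_proteome_fraction < 0 | entity_proteome_fraction > 1))
    stop("proteome fractions must lie in [0, 1]")
  entities <- names(entity_proteome_fraction)
  out <- stats::setNames(numeric(length(entities)), entities)
  for (e in entities) {
    sub <- rules[rules$entity == e, , drop = FALSE]
    if (!nrow(sub)) stop("no binding rule for entity: ", e)
    miss <- setdiff(sub$amino_acid, names(aa_biomass_coefficients))
    if (length(miss))
      stop("missing amino acid biomass coefficient: ", paste(miss, collapse = ", "))
    out[e] <- strategy(entity_proteome_fraction[[e]],
                       aa_biomass_coefficients[sub$amino_acid],
                       sub$ratio)
  }
  out
}

#' Inject iron-entity terms into the biomass reaction
#'
#' Adds each entity as a biomass substrate at its coefficient.  Entities are
#' added individually rather than as free iron, so the iron flux is routed
#' through the entities' biosynthesis rather than syphoned straight to
#' biomass.
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction.
#' @param coeffs named numeric vector: entity species id -> coefficient
#'   (mmol/gDW); zero entries are ignored.
#' @param biomass_reaction biomass reaction id; defaults to the objective.
#' @return the updated model.
#' @export
inject_biomass_terms <- function(model, coeffs,
                                 biomass_reaction = model$objective) {
  j <- match(biomass_reaction, model$reactions$id)
  if (is.na(j)) stop("biomass reaction not found: ", biomass_reaction)
  for (e in names(coeffs)) {
    if (coeffs[[e]] == 0) next
    if (!e %in% model$species$id) stop("entity species absent from model: ", e)
    model$S[e, j] <- model$S[e, j] - coeffs[[e]]
  }
  model
}
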