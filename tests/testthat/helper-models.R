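# Hand-built miniature models used across the test files.

# linear chain: EX_A (uptake <= 1) -> A -> B -> biomass, unit stoichiometry
chain_model <- function(uptake = 1) {
  m <- metabolic_model("chain", compartments = c(c = "cytoplasm"))
  m <- add_species(m, "A", compartment = "c")
  m <- add_species(m, "B", compartment = "c")
  m <- add_reaction(m, "EX_A", c(A = -1), lb = -uptake, ub = 1000)
  m <- add_reaction(m, "T1", c(A = -1, B = 1), gpr = "g1 or g2")
  m <- add_reaction(m, "BIO", c(B = -1), is_exchange = FALSE)
  set_objective(m, "BIO")
}

# two parallel equivalent paths of capacity 1 feeding a demand of 1
parallel_model <- function() {
  m <- metabolic_model("parallel", compartments = c(c = "cytoplasm"))
  m <- add_species(m, "A", compartment = "c")
  m <- add_species(m, "B", compartment = "c")
  m <- add_reaction(m, "EX_A", c(A = -1), lb = -1, ub = 0)
  m <- add_reaction(m, "P1", c(A = -1, B = 1), lb = 0, ub = 1)
  m <- add_reaction(m, "P2", c(A = -1, B = 1), lb = 0, ub = 1)
  m <- add_reaction(m, "BIO", c(B = -1), is_exchange = FALSE)
  set_objective(m, "BIO")
}

# small network with a capacity-limited branch, used for enumeration tests:
# EX_A (<=1) -> A; A -> B via P1 (free) or P2 (<= 0.6); B -> biomass
mini_model <- function() {
  m <- metabolic_model("mini", compartments = c(c = "cytoplasm"))
  m <- add_species(m, "A", compartment = "c")
  m <- add_species(m, "B", compartment = "c")
  m <- add_reaction(m, "EX_A", c(A = -1), lb = -1, ub = 0)
  m <- add_reaction(m, "P1", c(A = -1, B = 1), lb = 0, ub = 1000)
  m <- add_reaction(m, "P2", c(A = -1, B = 1), lb = 0, ub = 0.6)
  m <- add_reaction(m, "BIO", c(B = -1), is_exchange = FALSE)
  set_objective(m, "BIO")
}

# rebuild a model with its reactions added in a permuted order
permute_reactions <- function(model, perm) {
  out <- metabolic_model(model$id,
                         stats::setNames(model$compartments$name,
                                         model$compartments$id),
                         model$default_growth_rate)
  for (i in seq_len(nrow(model$species)))
    out <- add_species(out, model$species$id[i], model$species$name[i],
                       model$species$compartment[i], model$species$category[i],
                       model$species$sbo[i])
  for (j in perm) {
    col <- model$S[, j]
    out <- add_reaction(out, model$reactions$id[j], col[col != 0],
                        lb = model$reactions$lb[j], ub = model$reactions$ub[j],
                        gpr = model$reactions$gpr[j],
                        name = model$reactions$name[j],
                        is_exchange = model$reactions$is_exchange[j],
                        membrane_spanning = model$reactions$membrane_spanning[j])
  }
  out <- set_objective(out, model$objective)
  out$cofactor_table <- model$cofactor_table
  out
}
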