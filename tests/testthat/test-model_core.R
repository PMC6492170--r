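test_that("model construction enforces structural invariants", {
  m <- metabolic_model("t", compartments = c(c = "cytoplasm"))
  expect_error(add_species(m, "A", compartment = "nowhere"),
               "undeclared compartment")
  m <- add_species(m, "A", compartment = "c")
  expect_error(add_species(m, "A", compartment = "c"), "already present")
  expect_error(add_reaction(m, "R1", c(ghost = -1), is_exchange = FALSE),
               "unknown species")
  expect_error(add_reaction(m, "R1", c(A = -1), lb = 2, ub = 1),
               "lower bound exceeds")
  m <- add_reaction(m, "EX_A", c(A = -1), lb = -1)
  expect_error(add_reaction(m, "EX_A", c(A = -1)), "already present")
  expect_error(validate_model(m), "no objective")
  m <- set_objective(m, "EX_A")
  expect_silent(validate_model(m))
  expect_error(set_objective(m, "nope"), "not in model")
})

test_that("pseudo-metabolites carry the interaction-outcome SBO term", {
  m <- metabolic_model("t", compartments = c(c = "cytoplasm"))
  m <- add_species(m, "PS", compartment = "c", category = "pseudo_metabolite")
  expect_identical(m$species$sbo[m$species$id == "PS"], "SBO:0000409")
})

test_that("GPR rules parse, evaluate and report genes", {
  expect_setequal(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_identical(gpr_genes(""), character())
  expect_true(gpr_eval("g1 or g2", off = "g1"))
  expect_false(gpr_eval("g1 and g2", off = "g1"))
  expect_false(gpr_eval("(g1 and g2) or (g1 and g3)", off = "g1"))
  expect_true(gpr_eval("(g1 and g2) or g3", off = c("g1")))
  expect_true(gpr_eval("", off = "g1"))      # orphan reactions stay open
  expect_error(gpr_eval("g1 and (g2"), "parenthes")
  expect_error(gpr_eval("and g1"), "malformed")
})

test_that("dead ends respect reversibility, cycles and exchanges", {
  # chain A -> B -> C with an exchange only for A: C dead, B not
  m <- metabolic_model("d", compartments = c(c = "cytoplasm"))
  for (s in c("A", "B", "C")) m <- add_species(m, s, compartment = "c")
  m <- add_reaction(m, "EX_A", c(A = -1), lb = -1, ub = 1000)
  m <- add_reaction(m, "R1", c(A = -1, B = 1))
  m <- add_reaction(m, "R2", c(B = -1, C = 1))
  expect_identical(find_dead_ends(m), "C")

  # closed scaffold cycle: neither member is a dead end
  m2 <- metabolic_model("cyc", compartments = c(m = "mitochondrion"))
  m2 <- add_species(m2, "ES", compartment = "m", category = "pseudo_metabolite")
  m2 <- add_species(m2, "SS", compartment = "m", category = "pseudo_metabolite")
  m2 <- add_reaction(m2, "F", c(ES = -1, SS = 1))
  m2 <- add_reaction(m2, "Bk", c(SS = -1, ES = 1))
  expect_length(find_dead_ends(m2), 0)
  expect_length(find_dead_ends(m2, include_pseudo = FALSE), 0)

  # a model where every species has a reversible exchange has no dead ends
  m3 <- metabolic_model("x", compartments = c(c = "cytoplasm"))
  for (s in c("A", "B")) {
    m3 <- add_species(m3, s, compartment = "c")
    m3 <- add_reaction(m3, paste0("EX_", s),
                       stats::setNames(-1, s), lb = -10, ub = 10)
  }
  m3 <- add_reaction(m3, "R", c(A = -1, B = 1))
  expect_length(find_dead_ends(m3), 0)
})

test_that("model diff counts additions, removals and modifications", {
  fx <- generate_fixture(fixture_config())
  m <- fx$model
  d0 <- diff_models(m, m)
  expect_length(d0$added_reactions, 0)
  expect_length(d0$removed_reactions, 0)
  expect_length(d0$modified_reactions, 0)
  expect_setequal(d0$matched_reactions, m$reactions$id)

  m2 <- m
  for (i in 1:3)
    m2 <- add_reaction(m2, paste0("NEW", i), c(glc_c = -1), is_exchange = TRUE)
  m2 <- set_bounds(m2, "FERM", ub = 7)
  d <- diff_models(m, m2)
  expect_length(d$added_reactions, 3)
  expect_identical(d$modified_reactions, "FERM")

  # swapping arguments swaps added/removed exactly
  dr <- diff_models(m2, m)
  expect_setequal(dr$removed_reactions, d$added_reactions)
  expect_setequal(dr$added_reactions, d$removed_reactions)
})

test_that("stoichiometry-based matching pairs renamed reactions", {
  a <- chain_model()
  b <- chain_model()
  # rename T1 in b
  j <- match("T1", b$reactions$id)
  b$reactions$id[j] <- "T1_renamed"
  colnames(b$S) <- b$reactions$id
  d_plain <- diff_models(a, b)
  expect_identical(d_plain$added_reactions, "T1_renamed")
  d_canon <- diff_models(a, b, match_by_stoich = TRUE)
  expect_length(d_canon$added_reactions, 0)
  expect_length(d_canon$removed_reactions, 0)
})
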