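test_that("free-to-spent augmentation writes the expected stoichiometry", {
  m <- chain_model()
  m <- add_species(m, "haem_b", compartment = "c")
  m <- add_reaction(m, "HS", c(haem_b = 1), lb = 0, ub = 1000)
  m <- augment_reaction(m, "T1", "haem_b", 1e-3)
  st <- reaction_stoich(m, "T1")
  expect_equal(st[["haem_b"]], -1e-3)
  expect_equal(st[["haem_b_spent"]], 1e-3)
  expect_equal(st[["A"]], -1)              # original metabolites untouched
  expect_equal(st[["B"]], 1)
  expect_true("DM_haem_b_spent" %in% m$reactions$id)
  expect_error(augment_reaction(m, "T1", "haem_b", 1e-3), "duplicate")
  expect_error(augment_reaction(m, "T1", "A", -1), "negative")
  expect_error(augment_reaction(m, "T1", "ghost", 1), "missing cofactor")
})

test_that("zero coefficient and literal mode leave the matrix unchanged", {
  m <- chain_model()
  m <- add_species(m, "X", compartment = "c")
  m <- add_reaction(m, "HX", c(X = 1), lb = 0, ub = 1000)
  m0 <- augment_reaction(m, "T1", "X", 0)
  expect_equal(m0$S[, "T1"], m$S[, "T1"])
  expect_equal(nrow(m0$cofactor_table), 1L)   # requirement still recorded
  ml <- augment_reaction(m, "T1", "X", 0.4, mode = "literal_both_sides")
  expect_equal(ml$S, m$S)
  expect_equal(optimize_growth(ml)$objective_value,
               optimize_growth(m)$objective_value, tolerance = 1e-12)
})

test_that("augmentation is growth-neutral when the cofactor is unconstrained", {
  fx <- generate_fixture(fixture_config())
  g_aug <- optimize_growth(fx$model)$objective_value
  g_base <- optimize_growth(fx$model_unaugmented)$objective_value
  expect_equal(g_aug, g_base, tolerance = 1e-8)
  expect_equal(g_aug, fx$bundle$growth, tolerance = 1e-8)
})

test_that("a binding cofactor supply strictly reduces growth", {
  # no structural biomass iron: only the augmentation consumes iron
  cfg <- fixture_config(biomass_haem_coeff = 0, iron_exchange_bound = 1e-7)
  fx <- generate_fixture(cfg)
  g_base <- optimize_growth(fx$model_unaugmented)$objective_value
  g_aug <- optimize_growth(fx$model)$objective_value
  expect_equal(g_base, 0.7, tolerance = 1e-8)
  # analytic: growth = iron bound / (2 clusters-iron x) = 1e-7 / 2e-6
  expect_equal(g_aug, 1e-7 / (2 * cfg$cofactor_magnitude), tolerance = 1e-6)
  expect_lt(g_aug, g_base * 0.999)
})

test_that("scaffold cycle conserves the ES/SS moiety and couples fluxes", {
  fx <- generate_fixture(fixture_config())
  m <- fx$model
  # indicator on {ES, SS} is a left null vector of every column
  expect_equal(max(abs(m$S["ES_m", ] + m$S["SS_m", ])), 0)
  sol <- optimize_growth(m)
  expect_equal(sol$fluxes[["fes_m_scaffold_load"]],
               sol$fluxes[["fes_m_maturation"]], tolerance = 1e-9)
  # blocking loading blocks cluster production (and, here, growth)
  mb <- set_bounds(m, "fes_m_scaffold_load", ub = 0)
  sb <- optimize_growth(mb, selection_rule = "solver_default")
  expect_equal(sb$fluxes[["fes_m_maturation"]], 0, tolerance = 1e-9)
  expect_equal(sb$objective_value, 0, tolerance = 1e-9)
})

test_that("multiple maturation routes each get their own reaction", {
  m <- metabolic_model("sc", compartments = c(m = "mitochondrion"))
  m <- add_species(m, "cys_m", compartment = "m")
  m <- add_species(m, "fe_m", compartment = "m")
  m <- build_scaffold_cycle(m, list(
    donor = "cys_m", iron = "fe_m", compartment = "m",
    clusters = list(list(species = "fe4s4_m", iron_per_cluster = 4,
                         routes = c("gLIP5 or gSDH2", "gISA1")))))
  expect_true(all(c("fe4s4_m_maturation_1", "fe4s4_m_maturation_2") %in%
                    m$reactions$id))
  expect_error(build_scaffold_cycle(m, list(donor = "nope", iron = "fe_m",
                                            compartment = "m",
                                            clusters = list())),
               "missing donor")
})

test_that("regulon circuit gates high-affinity uptake without other effects", {
  # abundant low-affinity capacity: high-affinity route stays silent
  fx_ab <- generate_fixture(fixture_config(conversion_factor = 1))
  sol_ab <- optimize_growth(fx_ab$model)
  expect_equal(sol_ab$fluxes[["FETHI"]], 0, tolerance = 1e-9)

  # low-affinity route blocked: high-affinity carries all the iron flux
  fx <- generate_fixture(fixture_config())
  m_lo_off <- delete_gene(fx$model, "gFET4")
  sol_off <- optimize_growth(m_lo_off)
  expect_equal(sol_off$objective_value, fx$bundle$growth, tolerance = 1e-8)
  expect_equal(sol_off$fluxes[["FETHI"]], fx$bundle$iron_demand,
               tolerance = 1e-6)
  expect_equal(sol_off$fluxes[["FETLO"]], 0, tolerance = 1e-9)

  # removing the circuit leaves real-metabolite exchange fluxes untouched
  fx_nr <- generate_fixture(fixture_config(include_regulon = FALSE))
  sol_r <- optimize_growth(fx$model)
  sol_nr <- optimize_growth(fx_nr$model)
  for (ex in c("EX_glc", "EX_o2", "EX_fe", "EX_cu", "EX_so4"))
    expect_equal(sol_nr$fluxes[[ex]], sol_r$fluxes[[ex]], tolerance = 1e-8)

  expect_error(build_regulon_circuit(chain_model(), list()),
               "requires a scaffold")
})

test_that("haem coupling makes low-affinity uptake haem-dependent", {
  m <- chain_model()
  m2 <- couple_haem_to_low_affinity(m, c("hem1", "hem2"), "T1")
  expect_false(gpr_eval(m2$reactions$gpr[m2$reactions$id == "T1"],
                        off = "hem1"))
  expect_true(gpr_eval(m2$reactions$gpr[m2$reactions$id == "T1"],
                       off = "other"))
  expect_identical(couple_haem_to_low_affinity(m, character(), "T1"), m)
  # in the fixture, deleting a haem gene closes FETLO
  fx <- generate_fixture(fixture_config())
  md <- delete_gene(fx$model, "gHEM1")
  j <- match("FETLO", md$reactions$id)
  expect_equal(md$reactions$ub[j], 0)
})

test_that("threshold concentrations convert to flux bounds", {
  expect_equal(threshold_to_bound(affinity_threshold("iron", 1, 1e-3)), 1e-3)
  expect_equal(threshold_to_bound(affinity_threshold("copper",
                                                     conversion_factor = 1e-3)),
               2e-2)   # 20 uM default for copper
  expect_error(affinity_threshold("iron", 1, 0), "positive")
  expect_error(affinity_threshold("iron", -2, 1), "positive")
})

test_that("growth is monotone non-increasing in the cofactor magnitude", {
  cfg <- fixture_config(biomass_haem_coeff = 0, iron_exchange_bound = 1e-4)
  fx <- generate_fixture(cfg)
  sw <- sweep_coefficient(fx$model_unaugmented, fx$model$cofactor_table,
                          magnitudes = c(0, 1e-6, 1e-5, 5e-5, 7e-5, 1e-4,
                                         5e-4, 1e-3))
  g <- sw$curve$growth
  expect_true(all(diff(g) <= 1e-9))
  expect_equal(g[1], sw$baseline, tolerance = 1e-9)
})
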