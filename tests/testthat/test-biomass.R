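rules <- read_binding_rules(system.file("extdata", "iron_binding_rules.tsv",
                                        package = "cofactorflux"))

test_that("entity coefficients follow the ratio-weighted reconstruction", {
  aa <- c(cysteine = 0.05, histidine = 0.03, arginine = 0.02)
  # haem b: one cysteine per entity
  expect_equal(biomass_cofactor_coefficients(aa, c(haem_b = 0.01), rules),
               c(haem_b = 0.01 * 0.05 / 1))
  # haem c: two cysteines per entity halve the coefficient
  expect_equal(biomass_cofactor_coefficients(aa, c(haem_c = 0.01), rules),
               c(haem_c = 0.01 * 0.05 / 2))
  # Rieske 2Fe-2S: 2 His + 2 Cys -> (c_his + c_cys) / 4
  expect_equal(biomass_cofactor_coefficients(aa, c(`2Fe-2S_Rieske` = 0.2),
                                             rules),
               c(`2Fe-2S_Rieske` = 0.2 * (0.03 + 0.05) / 4))
  # zero proteome fraction gives a zero coefficient
  expect_equal(unname(biomass_cofactor_coefficients(aa, c(`4Fe-4S` = 0),
                                                    rules)), 0)
  expect_error(biomass_cofactor_coefficients(c(histidine = 1),
                                             c(haem_b = 0.1), rules),
               "cysteine")
  expect_error(biomass_cofactor_coefficients(aa, c(unknown_entity = 0.1),
                                             rules), "no binding rule")
})

test_that("coefficients are homogeneous in c_a and monotone in p_e and r", {
  aa <- c(cysteine = 0.05, histidine = 0.03, arginine = 0.02)
  fr <- c(haem_c = 0.02, `4Fe-4S` = 0.3)
  base <- biomass_cofactor_coefficients(aa, fr, rules)
  expect_equal(biomass_cofactor_coefficients(aa * 3, fr, rules), base * 3)
  more <- biomass_cofactor_coefficients(aa, fr * 1.5, rules)
  expect_true(all(more >= base))
  # doubling every binding ratio halves every coefficient
  rules2 <- rules; rules2$ratio <- rules2$ratio * 2
  expect_equal(biomass_cofactor_coefficients(aa, fr, rules2), base / 2)
})

test_that("a custom strategy can replace the default formula", {
  aa <- c(cysteine = 0.05)
  got <- biomass_cofactor_coefficients(aa, c(haem_b = 0.5), rules,
                                       strategy = function(p, ca, r) p * 7)
  expect_equal(unname(got), 3.5)
})

test_that("biomass term injection adds demand without side effects", {
  fx <- generate_fixture(fixture_config())
  m <- fx$model
  g0 <- optimize_growth(m)$objective_value
  expect_equal(inject_biomass_terms(m, c(haem_c = 0))$S, m$S)
  expect_error(inject_biomass_terms(m, c(ghost = 0.1)), "absent")
  m2 <- inject_biomass_terms(m, c(haem_c = 0.05))
  expect_equal(reaction_stoich(m2, "BIOMASS")[["haem_c"]],
               reaction_stoich(m, "BIOMASS")[["haem_c"]] - 0.05)
  g2 <- optimize_growth(m2)$objective_value
  expect_lte(g2, g0 + 1e-9)             # added demand never helps
  # under scarce iron the added haem demand strictly bites
  m3 <- scale_exchange(m, "fe_e", 0.1)
  m4 <- scale_exchange(m2, "fe_e", 0.1)
  expect_lt(optimize_growth(m4)$objective_value,
            optimize_growth(m3)$objective_value)
  # only iron-entity-producing routes change: the energy backbone keeps its
  # flux pattern (respiration stays at the oxygen cap)
  s4 <- optimize_growth(m4)
  expect_equal(s4$fluxes[["RESP"]],
               min(fx$bundle$params$O, s4$objective_value / fx$bundle$params$y),
               tolerance = 1e-6)
})
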