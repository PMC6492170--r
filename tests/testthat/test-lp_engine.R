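test_that("growth optimisation solves simple networks exactly", {
  sol <- optimize_growth(chain_model())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("EX_A", "T1", "BIO")]), c(-1, 1, 1),
               tolerance = 1e-9)

  # objective capped at zero
  m0 <- set_bounds(chain_model(), "BIO", ub = 0)
  expect_equal(optimize_growth(m0)$objective_value, 0, tolerance = 1e-12)

  # infeasible bounds propagate as a status, not a crash
  mi <- chain_model()
  mi <- set_bounds(mi, "EX_A", lb = 0.5, ub = 0.5)  # forced A secretion
  expect_identical(optimize_growth(mi)$status, "infeasible")
})

test_that("optimum matches exhaustive vertex enumeration on small models", {
  for (m in list(chain_model(), parallel_model(), mini_model())) {
    sol <- optimize_growth(m, selection_rule = "solver_default")
    expect_equal(sol$objective_value, oracle_fba(m), tolerance = 1e-8)
  }
})

test_that("steady-state residual stays below 10x the tolerance", {
  for (m in list(mini_model(), generate_fixture(fixture_config())$model)) {
    sol <- optimize_growth(m)
    expect_lt(sol$residual, 1e-8)
    expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-8)
    expect_true(all(sol$fluxes >= m$reactions$lb - 1e-8 &
                      sol$fluxes <= m$reactions$ub + 1e-8))
  }
})

test_that("FVA matches enumeration and brackets the selected fluxes", {
  m <- mini_model()
  for (fr in c(1.0, 0.5)) {
    got <- flux_variability(m, fraction_of_optimum = fr)
    want <- oracle_fva(m, fraction = fr)
    expect_equal(got$min, want$min, tolerance = 1e-8)
    expect_equal(got$max, want$max, tolerance = 1e-8)
  }
  # chain: a unique pathway gives degenerate ranges
  fc <- flux_variability(chain_model(), 1.0)
  expect_equal(fc$min, fc$max, tolerance = 1e-9)
  # parallel equivalent paths of capacity 1 feeding demand 1: each in (0, 1)
  fp <- flux_variability(parallel_model(), 1.0)
  expect_equal(unlist(fp[fp$reaction == "P1", c("min", "max")]),
               c(min = 0, max = 1), tolerance = 1e-9)
  expect_equal(unlist(fp[fp$reaction == "P2", c("min", "max")]),
               c(min = 0, max = 1), tolerance = 1e-9)
  # FVA min <= selected flux <= FVA max on the fixture
  fx <- generate_fixture(fixture_config())
  sol <- optimize_growth(fx$model)
  fv <- flux_variability(fx$model, 1.0)
  expect_true(all(fv$min - 1e-7 <= sol$fluxes[fv$reaction]))
  expect_true(all(sol$fluxes[fv$reaction] <= fv$max + 1e-7))
})

test_that("parsimonious selection is idempotent and order-independent", {
  fx <- generate_fixture(fixture_config())
  sol <- optimize_growth(fx$model)
  sol2 <- optimize_growth(fx$model)
  expect_identical(sol$fluxes, sol2$fluxes)
  set.seed(11)
  perm <- sample(nrow(fx$model$reactions))
  mp <- permute_reactions(fx$model, perm)
  solp <- optimize_growth(mp)
  expect_equal(solp$fluxes[names(sol$fluxes)], sol$fluxes, tolerance = 1e-6)
})

test_that("precision guard applies the 100x-tolerance rule and rescaling", {
  m <- chain_model()
  m <- add_species(m, "X", compartment = "c")
  m <- add_reaction(m, "HX", c(X = 1), lb = 0, ub = 1000)  # X source
  m <- augment_reaction(m, "T1", "X", 1e-14)
  g_fail <- precision_guard(m, solver_feasibility_tol = 1e-9)
  expect_false(g_fail$pass)
  expect_gte(g_fail$suggested_k, 7)
  g_pass <- precision_guard(m, solver_feasibility_tol = 1e-16)
  expect_true(g_pass$pass)

  before <- optimize_growth(m)$objective_value
  m2 <- rescale_cofactor_species(m, c("X", "X_spent"), k = 8)
  expect_true(precision_guard(m2, 1e-9)$pass)
  after <- optimize_growth(m2)$objective_value
  expect_equal(after, before, tolerance = 1e-9)
})
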