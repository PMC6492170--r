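test_that("turnover totals follow the coefficient-weighted flux sum", {
  m <- chain_model()
  m <- add_species(m, "X", compartment = "c")
  m <- add_reaction(m, "HX", c(X = 1), lb = 0, ub = 1000)
  m <- set_bounds(m, "EX_A", lb = -2)
  m <- augment_reaction(m, "T1", "X", 1e-3)
  sol <- optimize_growth(m)             # T1 carries 2
  tv <- total_turnover(m, sol)
  expect_equal(tv$total, 2e-3, tolerance = 1e-12)
  expect_equal(tv$spent_pool_influx, 2e-3, tolerance = 1e-12)
  expect_true(tv$minimum <= tv$total + 1e-12 &&
                tv$total <= tv$maximum + 1e-12)
  # zero flux everywhere gives zero turnover
  m0 <- set_bounds(m, "EX_A", lb = 0, ub = 0)
  tv0 <- total_turnover(m0, optimize_growth(m0))
  expect_equal(tv0$total, 0)
  expect_error(total_turnover(chain_model(), sol), "no cofactor requirement")
})

test_that("sum formula and spent-pool influx agree on the fixture", {
  fx <- generate_fixture(fixture_config())
  sol <- optimize_growth(fx$model)
  tv <- total_turnover(fx$model, sol)
  tab <- fx$model$cofactor_table
  free <- tab[tab$mode == "free_to_spent", ]
  free_total <- sum(free$coefficient * abs(sol$fluxes[free$reaction_id]))
  expect_equal(tv$spent_pool_influx, free_total,
               tolerance = 1e-9 * max(free_total, 1e-30))
  expect_true(tv$minimum <= tv$total + 1e-12)
  expect_true(tv$total <= tv$maximum + 1e-12)
  expect_equal(tv$total, sum(tv$per_reaction), tolerance = 1e-15)
  # the parsimonious solution sits at the theoretical minimum usage here:
  # high-affinity uptake (the costliest cofactor user) is minimal
  expect_equal(tv$total, tv$minimum, tolerance = 1e-8 * max(tv$total, 1e-30))
  expect_gt(tv$maximum, tv$total)   # rewiring onto high-affinity raises it
})

test_that("range gaps are plain arithmetic with undefined zero cases", {
  r <- structure(list(total = 1.0, minimum = 1.0, maximum = 1.34),
                 class = "turnover_result")
  g <- turnover_range_gap(r)
  expect_equal(g$rel_gap_to_min, 0)
  expect_equal(g$rel_gap_to_max, 0.34)
  r0 <- structure(list(total = 0, minimum = 0, maximum = 0),
                  class = "turnover_result")
  g0 <- turnover_range_gap(r0)
  expect_true(is.na(g0$rel_gap_to_min))
})

test_that("coefficient sweep finds the knee at the analytic magnitude", {
  B <- 1e-4
  cfg <- fixture_config(biomass_haem_coeff = 0, iron_exchange_bound = B)
  fx <- generate_fixture(cfg)
  mags <- c(0, 1e-6, 1e-5, 5e-5, 7e-5, 1e-4, 1e-3)
  sw <- sweep_coefficient(fx$model_unaugmented, fx$model$cofactor_table, mags)
  expect_equal(sw$baseline, 0.7, tolerance = 1e-8)
  expect_equal(sw$curve$growth[1], sw$baseline, tolerance = 1e-9)
  # iron demand is 2*m*mu (two irons per cluster); growth is unimpaired
  # while 2*m*0.7 <= B, i.e. m <= 7.14e-5: the knee is the 7e-5 grid point
  expect_equal(sw$knee, 7e-5)
  # beyond the knee the curve follows B / (2 m)
  g_at <- function(m) sw$curve$growth[sw$curve$magnitude == m]
  expect_equal(g_at(1e-3), B / (2 * 1e-3), tolerance = 1e-6)
  expect_true(all(diff(sw$curve$growth) <= 1e-9))
  # a single magnitude reproduces the per-point growth of the sweep
  one <- sweep_coefficient(fx$model_unaugmented, fx$model$cofactor_table,
                           magnitudes = 1e-3)
  expect_equal(one$curve$growth, g_at(1e-3), tolerance = 1e-12)
  expect_error(sweep_coefficient(fx$model_unaugmented,
                                 fx$model$cofactor_table, c(0.2, 0.1)),
               "ascending")
})
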