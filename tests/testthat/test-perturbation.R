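test_that("reduction of function caps bounds in the wild-type direction", {
  m <- chain_model()
  m <- set_bounds(m, "EX_A", lb = -10)
  wt <- optimize_growth(m)            # T1 carries 10 forward
  red <- reduce_function(m, "g1", 0.5, wt)
  j <- match("T1", red$reactions$id)
  expect_equal(c(red$reactions$lb[j], red$reactions$ub[j]), c(0, 5))
  expect_error(reduce_function(m, "g1", 1, wt), "strictly between")
  expect_error(reduce_function(m, "g1", 0, wt), "strictly between")
  expect_error(reduce_function(m, "gZZ", 0.5, wt), "unknown gene")
  # a gene with zero wild-type flux leaves the model unchanged, with warning
  m2 <- add_species(m, "C", compartment = "c")
  m2 <- add_reaction(m2, "IDLE", c(C = 1), lb = 0, ub = 1000, gpr = "g9")
  wt2 <- optimize_growth(m2)
  expect_warning(red2 <- reduce_function(m2, "g9", 0.5, wt2), "no wild-type")
  expect_equal(red2$reactions, m2$reactions)
})

test_that("exchange scaling obeys the 10% rule and resource monotonicity", {
  fx <- generate_fixture(fixture_config())
  m <- fx$model
  j <- match("EX_fe", m$reactions$id)
  m10 <- scale_exchange(m, "fe_e", 0.1)
  expect_equal(m10$reactions$lb[match("EX_fe", m10$reactions$id)],
               0.1 * m$reactions$lb[j])
  expect_identical(scale_exchange(m, "fe_e", 1)$reactions, m$reactions)
  # factor 0 blocks uptake; iron is essential, so growth collapses
  g0 <- optimize_growth(scale_exchange(m, "fe_e", 0))$objective_value
  expect_equal(g0, 0, tolerance = 1e-9)
  expect_error(scale_exchange(m, "prec_c", 0.5), "no exchange")
  # growth is monotone in the iron supply factor
  gs <- vapply(c(0, 0.05, 0.1, 0.5, 1),
               function(f) optimize_growth(
                 scale_exchange(m, "fe_e", f))$objective_value, numeric(1))
  expect_true(all(diff(gs) >= -1e-9))
})

test_that("flux-change classification labels match hand arithmetic", {
  v1 <- c(a = 1, b = 2, c = 0, d = -1, e = 0.5, f = 1)
  same <- classify_flux_changes(v1, v1)
  expect_true(all(same$table$label %in% c("unchanged", "inactive_both")))
  expect_equal(unname(same$counts["unchanged"]), 5L)
  expect_equal(unname(same$counts["inactive_both"]), 1L)

  v2 <- c(a = 1.1,    # +10%: changed below default threshold
          b = 3,      # +50%: changed above threshold
          c = 0.4,    # zero -> nonzero: rewired
          d = 1,      # sign flip: rewired
          e = 0.5,    # unchanged
          f = 0)      # nonzero -> zero: rewired
  cl <- classify_flux_changes(v1, v2)
  want <- c(a = "changed_below_threshold", b = "changed_above_threshold",
            c = "rewired", d = "rewired", e = "unchanged", f = "rewired")
  expect_identical(stats::setNames(cl$table$label, cl$table$reaction), want)

  # expected-scale mode: exact halving is scaled_as_expected
  cs <- classify_flux_changes(c(r = 4, s = 2, t = 1), c(r = 2, s = 2, t = 1.4),
                              expected_scale = 0.5)
  lab <- stats::setNames(cs$table$label, cs$table$reaction)
  expect_identical(unname(lab["r"]), "scaled_as_expected")
  expect_identical(unname(lab["s"]), "unchanged")
  expect_identical(unname(lab["t"]), "rewired")
  expect_error(classify_flux_changes(c(x = 1), c(y = 1)), "share no reactions")
})

test_that("threshold sensitivity is monotone and consistent", {
  fx <- generate_fixture(fixture_config())
  wt <- optimize_growth(fx$model)
  red <- reduce_function(fx$model, "gARH1", 0.5, wt)
  new <- optimize_growth(red)
  ths <- seq(0.15, 0.35, by = 0.05)
  sens <- threshold_sensitivity(wt, new, ths)
  expect_equal(sens$threshold, ths)
  expect_true(all(diff(sens$changed_above_threshold) <= 0))
  one <- classify_flux_changes(wt, new, threshold = 0.25)
  expect_equal(sens$changed_above_threshold[sens$threshold == 0.25],
               unname(one$counts["changed_above_threshold"]))
  allsame <- threshold_sensitivity(wt, wt, ths)
  expect_true(all(allsame$changed_above_threshold == 0))
  expect_error(threshold_sensitivity(wt, new, c(0.3, 0.2)), "sorted")
})

test_that("qualitative benchmarks need a valid scenario and reporters", {
  fx <- generate_fixture(fixture_config())
  expect_error(qualitative_benchmark(fx$model, list(), "nope"),
               "missing reporter")
  none <- qualitative_benchmark(fx$model, list(), c("EX_o2", "BIOMASS"))
  expect_true(all(none == "same"))
})
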