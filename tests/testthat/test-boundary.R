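test_that("total PA resistance converts clinical units correctly", {
  # 10 mmHg over 5 L/min
  expect_equal(total_pa_resistance(10, 5, pressure_unit = "mmHg",
                                   flow_unit = "l_min"),
               10 * 1333.22 / (5000 / 60), tolerance = 1e-12)
  expect_equal(total_pa_resistance(10, 5, pressure_unit = "mmHg",
                                   flow_unit = "l_min"),
               159.99, tolerance = 1e-4)
  # 13 mmHg over 83.33 mL/s
  expect_equal(total_pa_resistance(13, 83.33, pressure_unit = "mmHg"),
               208.0, tolerance = 1e-3)
  # zero driving pressure
  expect_error(total_pa_resistance(10, 5, distal_pressure = 10), "exceed")
  expect_error(total_pa_resistance(10, 0), "positive")
})

test_that("side resistances form a parallel split proportional to flow", {
  expect_equal(side_resistances(100, 0.5), c(RPA = 200, LPA = 200))
  rs <- side_resistances(100, 0.614)
  expect_equal(unname(rs), c(100 / 0.614, 100 / 0.386), tolerance = 1e-12)
  expect_equal(unname(rs), c(162.87, 259.07), tolerance = 1e-4)
  expect_equal(1 / rs[["RPA"]] + 1 / rs[["LPA"]], 1 / 100, tolerance = 1e-14)
  expect_error(side_resistances(100, 0), "strictly inside")
  expect_error(side_resistances(100, 1e-9), "strictly inside")
})

test_that("Murray fractions follow r^exponent weighting", {
  # symmetry
  expect_equal(murray_fractions(c(2, 2)), c(0.5, 0.5))
  # radii (1, 2), exponent 2.3: direct evaluation of 2^2.3
  f <- murray_fractions(pi * c(1, 2)^2, exponent = 2.3)
  expect_equal(f, c(1, 2^2.3) / (1 + 2^2.3), tolerance = 1e-14)
  expect_equal(f, c(0.1688, 0.8312), tolerance = 1e-4)
  # exponent 2 reduces to area proportions
  a <- c(0.3, 1.1, 2.2)
  expect_equal(murray_fractions(a, exponent = 2), a / sum(a),
               tolerance = 1e-14)
  expect_error(murray_fractions(numeric(0)), "non-empty")
  expect_error(murray_fractions(c(1, -1)), "positive")
})

test_that("Murray fractions are permutation-equivariant and scale-invariant", {
  set.seed(42)
  for (i in 1:5) {
    a <- runif(7, 0.05, 3)
    f <- murray_fractions(a)
    expect_equal(sum(f), 1, tolerance = 1e-14)
    p <- sample(7)
    expect_equal(murray_fractions(a[p]), f[p], tolerance = 1e-14)
    expect_equal(murray_fractions(a * 17.3), f, tolerance = 1e-12)
  }
})

test_that("RCR assembly splits resistance and sets compliance from tau", {
  r <- assemble_rcr(100, proximal_fraction = 0.1, tau = 1.0)
  expect_equal(r$Rp, 10)
  expect_equal(r$Rd, 90)
  expect_equal(r$C, 1 / 90, tolerance = 1e-14)
  # conservation for any fraction
  for (f in c(0, 0.25, 0.6)) {
    r2 <- assemble_rcr(250, f, tau = 0.8)
    expect_equal(r2$Rp + r2$Rd, 250, tolerance = 1e-12)
  }
  expect_equal(assemble_rcr(100, 0, tau = 1)$Rp, 0)
  expect_error(assemble_rcr(100, 1, tau = 1), "proximal_fraction")
})

test_that("resistance budgets reconstruct the total in parallel", {
  tr <- generate_pa_tree(10, 1.3, 0.3, seed = 5)
  for (f in c(0.5, 0.614)) {
    b <- resistance_budget(tr, 371, f)
    expect_equal(1 / sum(1 / b$outlet_resistances), 371,
                 tolerance = 371 * 1e-9)
    for (s in c("RPA", "LPA")) {
      expect_equal(sum(b$outlet_fractions[b$outlet_side == s]), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("raising one outlet's resistance lowers its flow share", {
  tr <- toy_tree()
  wf <- constant_waveform(20)
  base <- symmetric_rcr_pair()
  sol <- solve_network(tr, base, wf, steps_per_cycle = 64)
  f0 <- pahemo:::achieved_rpa_fraction(tr, sol)
  harder <- base
  harder[["2"]] <- windkessel_rcr(10 * 1.5, 0.01, 90 * 1.5, 0)
  sol2 <- solve_network(tr, harder, wf, steps_per_cycle = 64)
  f1 <- pahemo:::achieved_rpa_fraction(tr, sol2)
  expect_lt(f1, f0)
})

test_that("flow-split calibration converges and preserves total resistance", {
  tr <- generate_pa_tree(6, 1.2, 0.3, seed = 9)
  wf <- generate_inflow_waveform(75, 0.9, pr_target = 0.44,
                                 n_samples = 128)
  R <- total_pa_resistance(13, 46.5, pressure_unit = "mmHg")
  b <- resistance_budget(tr, R, 0.5)

  # symmetric start, symmetric target: converged at iteration 0
  cal0 <- calibrate_flow_split(tr, b, wf, 0.5, steps_per_cycle = 64)
  expect_true(cal0$report$converged)
  expect_equal(cal0$report$iterations, 0L)

  # asymmetric target within tolerance
  cal <- calibrate_flow_split(tr, b, wf, 0.614, tolerance = 0.02,
                              max_iter = 10, steps_per_cycle = 64)
  expect_true(cal$report$converged)
  expect_lte(cal$report$relative_error, 0.02)
  expect_equal(1 / sum(1 / cal$budget$outlet_resistances), R,
               tolerance = R * 1e-6)

  # zero tolerance cannot be met in finite iterations: flagged, no error
  cal2 <- calibrate_flow_split(tr, b, wf, 0.614, tolerance = 0,
                               max_iter = 2, steps_per_cycle = 64)
  expect_false(cal2$report$converged)
})
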