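test_that("Poiseuille tube resistance matches the hand-evaluated formula", {
  # independent SI evaluation: 8 * 1.81e-5 * 0.3 / (pi * 0.0025^4)
  # = 3.53981e5 Pa s/m^3 = 3.53981e-3 mbar s/mL
  expect_equal(tube_resistance(300, 5), 3.5398096527e-3, tolerance = 1e-9)
  # linear in length, r^-4 in diameter
  expect_equal(tube_resistance(600, 5), 2 * tube_resistance(300, 5))
  expect_equal(tube_resistance(300, 2.5), 16 * tube_resistance(300, 5))
  expect_error(tube_resistance(-1, 5), "positive")
  expect_error(tube_resistance(300, 0), "positive")
})

test_that("orifice pressure drop follows the quadratic law", {
  # hand oracle: rho Q^2 / (2 Cd^2 A^2) at Q = 80.6 mL/s
  expect_equal(element_dp(orifice_element(4.03), 80.6), 0.66545530,
               tolerance = 1e-7)
  expect_equal(element_dp(orifice_element(1.07), 80.6), 133.90720947,
               tolerance = 1e-7)
  expect_equal(element_dp(orifice_element(2.64), 0), 0)
  # sign-preserving odd law
  q <- c(-120, -5, 0.3, 80.6)
  o <- orifice_element(1.93)
  expect_equal(element_dp(o, -q), -element_dp(o, q))
  expect_error(orifice_element(-2), "positive")
  expect_error(orifice_element(2, discharge_coefficient = 1.5), "\\(0, 1\\]")
})

test_that("series airway pressure drops add and stay odd", {
  tube <- tube_element()
  orf <- orifice_element(1.07)
  chain <- airway(tube, orf)
  expect_equal(airway_dp(airway(tube), 50), element_dp(tube, 50))
  expect_equal(airway_dp(chain, 80.6),
               element_dp(tube, 80.6) + element_dp(orf, 80.6))
  q <- seq(-100, 100, by = 12.5)
  expect_equal(airway_dp(chain, -q), -airway_dp(chain, q))
  expect_error(airway(), "at least one")
  expect_error(airway(tube, list(a = 1)), "airway elements")
})

test_that("every airway dP is strictly increasing in flow with dP(0) = 0", {
  q <- seq(0, 200, by = 10)
  airways <- list(
    airway(tube_element()),
    airway(orifice_element(2.64)),
    airway(tube_element(), orifice_element(1.07)),
    airway(tube_element(), orifice_element(4.03), resistor_element(1e-3))
  )
  for (aw in airways) {
    dp <- airway_dp(aw, q)
    expect_equal(dp[1], 0)
    expect_true(all(diff(dp) > 0))
  }
})

test_that("smaller orifices resist more at every flow", {
  diameters <- c(4.03, 3.25, 2.64, 1.93, 1.07)
  for (q in c(5, 40, 80.6, 150)) {
    dp <- vapply(diameters, function(d) element_dp(orifice_element(d), q),
                 numeric(1))
    expect_true(all(diff(dp) > 0))
  }
})

test_that("lung and storage constructors validate their parameters", {
  expect_error(compliant_lung(compliance = -0.7), "positive")
  expect_error(compliant_lung(v_min = 65, v_max = 30), "v_min < v_max")
  expect_error(storage_compartment(-5), "non-negative")
  expect_error(storage_compartment(10, entrainment = 1.2), "\\[0, 1\\]")
  expect_error(storage_compartment(10, retention = -0.1), "\\[0, 1\\]")
})

test_that("polyfill presets map layers linearly onto storage parameters", {
  s2 <- polyfill_storage(2)
  s4 <- polyfill_storage(4)
  expect_equal(s4$storage_volume, 2 * s2$storage_volume)
  expect_equal(s4$resistance, 2 * s2$resistance)
  expect_null(polyfill_storage(0))
  # wrapped preset stores more than one tidal volume: full entrainment
  w <- storage_preset("wrapped")
  expect_true(w$storage_volume > 35)
  expect_identical(storage_preset("2 layers")$storage_volume,
                   polyfill_storage(2)$storage_volume)
})
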