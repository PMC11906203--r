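test_that("fraction/partial-pressure conversion reproduces textbook values", {
  # fresh air, dry convention at 760 mm Hg
  expect_equal(fraction_to_partial_pressure(0.21), 159.6)
  expect_equal(round(fraction_to_partial_pressure(0.21)), 160)
  expect_equal(fraction_to_partial_pressure(0.0004), 0.304)
  expect_equal(round(fraction_to_partial_pressure(0.0004), 1), 0.3)
  expect_equal(fraction_to_partial_pressure(0), 0)
  # BTPS subtracts 47 mm Hg of water vapor
  expect_equal(fraction_to_partial_pressure(0.21, convention_btps()),
               0.21 * 713)
  # hand division oracle: 35 mm Hg at dry 760
  expect_equal(partial_pressure_to_fraction(35), 35 / 760)
  expect_equal(round(partial_pressure_to_fraction(35), 4), 0.0461)
})

test_that("conversions round-trip and are strictly monotone", {
  for (conv in list(convention_dry(), convention_btps())) {
    f <- seq(0, 1, by = 0.05)
    p <- fraction_to_partial_pressure(f, conv)
    expect_equal(partial_pressure_to_fraction(p, conv), f,
                 tolerance = 1e-12)
    expect_true(all(diff(p) > 0))
  }
})

test_that("conversion domain errors are raised", {
  expect_error(fraction_to_partial_pressure(1.2), "\\[0, 1\\]")
  expect_error(fraction_to_partial_pressure(-0.1), "\\[0, 1\\]")
  expect_error(partial_pressure_to_fraction(-1), "mm Hg")
  expect_error(partial_pressure_to_fraction(800), "mm Hg")
  expect_error(pressure_convention(40, 47))
})

test_that("gas mixtures enforce their invariants", {
  g <- gas_mixture(0.044, 0.164)
  expect_equal(sum(unclass(g)), 1)
  expect_error(gas_mixture(0.5, 0.6, 0.2), "sum to 1")
  expect_error(gas_mixture(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(gas_mixture(NA_real_, 0.2), "finite")
})

test_that("mixing is conservative, idempotent and volume-weighted", {
  a <- gas_mixture(0.044, 0.164)
  b <- fresh_air()
  # equal-volume mean oracle
  m <- mix_gas(a, 35, b, 35)
  expect_equal(m[["f_co2"]], (0.044 + 0.0004) / 2, tolerance = 1e-12)
  expect_equal(round(m[["f_co2"]], 4), 0.0222)
  # idempotence and zero-volume identity
  expect_equal(unclass(mix_gas(a, 3, a, 97)), unclass(a), tolerance = 1e-12)
  expect_equal(unclass(mix_gas(a, 5, b, 0)), unclass(a), tolerance = 1e-12)
  # species conservation over a deterministic sweep of volumes/mixtures
  for (va in c(0.5, 10, 35)) {
    for (vb in c(1, 20, 80)) {
      m <- mix_gas(a, va, b, vb)
      before <- a[["f_co2"]] * va + b[["f_co2"]] * vb
      after <- m[["f_co2"]] * (va + vb)
      expect_equal(after, before, tolerance = 1e-12)
    }
  }
  expect_error(mix_gas(a, 0, b, 0), "zero-volume")
  expect_error(mix_gas(a, -1, b, 1), "non-negative")
})
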