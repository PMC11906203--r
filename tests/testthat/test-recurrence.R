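test_that("fresh-air limit of the per-breath map is exact", {
  ss <- breath_steady_state(storage_volume = 0)
  expect_equal(ss$lung_fCO2, 0.0004 + default_injection_per_breath() / 35,
               tolerance = 1e-12)
  expect_true(ss$bounded)
})

test_that("direct 2x2 solve agrees with the iterated map", {
  cases <- list(
    list(v = 20, b = 0.5, a = 0.5),
    list(v = 40, b = 1, a = 0.5),
    list(v = 10, b = 1, a = 0.9),
    list(v = 5, b = 0.2, a = 0.3)
  )
  for (cs in cases) {
    ss <- breath_steady_state(storage_volume = cs$v, entrainment = cs$b,
                              retention = cs$a)
    it <- breath_map_iterate(600, storage_volume = cs$v,
                             entrainment = cs$b, retention = cs$a)
    expect_equal(it$lung_fCO2[600], ss$lung_fCO2, tolerance = 1e-10)
    expect_equal(it$storage_fCO2[600], ss$storage_fCO2, tolerance = 1e-10)
  }
})

test_that("no fixed point exists under full entrainment and retention", {
  ss <- breath_steady_state(storage_volume = 40, entrainment = 1,
                            retention = 1)
  expect_false(ss$bounded)
  expect_true(is.na(ss$lung_fCO2))
})

test_that("engine equilibrium matches the analytic fixed point", {
  for (layers in c(0, 2, 4, 8)) {
    sim <- run_simulation(quick_config(layers = layers))
    ss <- breath_steady_state(storage_volume = 5 * layers)
    expect_true(sim$summary$converged)
    # <= 0.05 vol% absolute discrepancy
    expect_lt(abs(sim$summary$co2_pct / 100 - ss$lung_fCO2), 5e-4)
    expect_lt(abs(sim$summary$o2_pct / 100 - ss$lung_fO2), 5e-4)
  }
})

test_that("steady-state CO2 rises and O2 falls with storage", {
  vols <- c(0, 5, 10, 20, 40)
  ss <- dplyr::bind_rows(lapply(vols, function(v) {
    breath_steady_state(storage_volume = v)
  }))
  expect_true(all(diff(ss$lung_fCO2) > 0))
  expect_true(all(diff(ss$lung_fO2) < 0))
  # and monotone in entrainment at fixed volume
  betas <- c(0.1, 0.3, 0.6, 1)
  ssb <- vapply(betas, function(b) {
    breath_steady_state(storage_volume = 40, entrainment = b)$lung_fCO2
  }, numeric(1))
  expect_true(all(diff(ssb) > 0))
})
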