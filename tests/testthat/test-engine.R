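test_that("breathing patterns span the prescribed excursion", {
  for (wf in c("sinusoid", "trapezoid")) {
    pat <- breathing_pattern(waveform = wf)
    t <- seq(0, 3 * pat$period, length.out = 2000)
    v <- pattern_volume(pat, t, v_min = 30)
    expect_true(all(v >= 30 - 1e-9 & v <= 65 + 1e-9))
    expect_equal(pattern_volume(pat, 0, 30), 30)
    expect_equal(pattern_volume(pat, pat$period / 2, 30), 65,
                 tolerance = 1e-9)
    # periodicity and flow = dV/dt (numeric derivative check)
    expect_equal(pattern_volume(pat, t + pat$period, 30), v,
                 tolerance = 1e-9)
    h <- 1e-6
    q_num <- (pattern_volume(pat, t + h, 30) -
                pattern_volume(pat, t - h, 30)) / (2 * h)
    expect_equal(pattern_flow(pat, t), q_num, tolerance = 1e-4)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(pattern = breathing_pattern(tidal_volume = 30)),
               "v_max - v_min")
  expect_error(sim_config(timestep = 1), "200")
  expect_error(sim_config(max_breaths = 1), "at least 2")
  expect_error(metabolic_source(co2_mL_min = -1), "non-negative")
})

test_that("a zero-resistance airway produces identically zero pressure", {
  cfg <- sim_config(airway = airway(resistor_element(0)), max_breaths = 10)
  sim <- run_simulation(cfg)
  expect_true(all(sim$trace$p_mbar == 0))
  expect_equal(sim$summary$wob_J_min, 0)
  expect_equal(sim$summary$peak_neg_p_mbar, 0)
})

test_that("no-storage equilibrium matches the per-breath mass balance", {
  sim <- run_simulation(quick_config())
  expect_true(sim$summary$converged)
  expect_lt(sim$summary$breaths_to_equilibrium, 200)
  # exhaled CO2 = ambient + injection per breath / tidal volume
  expected <- 0.0004 + default_injection_per_breath() / 35
  expect_equal(sim$summary$co2_pct / 100, expected, tolerance = 2e-4)
  # O2 falls below ambient, CO2-for-O2 exchange
  expect_lt(sim$summary$o2_pct, 21)
})

test_that("trace satisfies the simulator invariants", {
  sim <- run_simulation(quick_config(layers = 2, max_breaths = 60))
  tr <- sim$trace
  expect_true(all(tr$V_mL >= 30 - 1e-9 & tr$V_mL <= 65 + 1e-9))
  fr <- c(tr$lung_fCO2, tr$lung_fO2, tr$storage_fCO2)
  expect_true(all(fr >= 0 & fr <= 1))
  # flow is the time derivative of volume, to discretization tolerance
  dt <- diff(tr$t_s[1:2])
  q_mid <- (tr$Q_mL_s[-1] + tr$Q_mL_s[-nrow(tr)]) / 2
  dv <- diff(tr$V_mL)
  expect_lt(max(abs(dv - q_mid * dt)), 0.02)
  # uniform grid
  expect_equal(max(abs(diff(tr$t_s) - dt)), 0, tolerance = 1e-9)
})

test_that("equilibrium detection follows the windowed-difference rule", {
  expect_identical(detect_equilibrium(rep(0.04, 10)),
                   list(converged = TRUE, breaths = 2L))
  growing <- cumsum(rep(1e-3, 50))
  expect_false(detect_equilibrium(growing, tol = 1e-4)$converged)
  expect_false(detect_equilibrium(0.04, tol = 1e-4)$converged)
  # a settling trace converges only once 5 consecutive changes are small
  x <- c(0.01, 0.02, 0.03, rep(0.0312, 8))
  expect_equal(detect_equilibrium(x, tol = 1e-4)$breaths, 9L)
})

test_that("full rebreathing with full retention never equilibrates", {
  st <- storage_compartment(40, entrainment = 1, retention = 1)
  sim <- run_simulation(sim_config(storage = st, max_breaths = 40))
  expect_false(sim$summary$converged)
  expect_true(all(diff(sim$breaths$exhaled_fCO2) > 0))
  expect_equal(sim$summary$breaths_run, 40)
})

test_that("injected CO2 equals net vented CO2 at steady state", {
  sim <- run_simulation(quick_config(layers = 4), extra_breaths = 50)
  b <- sim$breaths
  last <- b[(nrow(b) - 49):nrow(b), ]
  injected <- sum(last$injected_co2_mL)
  vented <- sum(last$net_vented_co2_mL)
  expect_equal(vented, injected, tolerance = 5e-3)
})

test_that("net volume mode shifts airway flow by the metabolic imbalance", {
  cfg_net <- sim_config(source = metabolic_source(volume_mode = "net"),
                        max_breaths = 30)
  sim <- run_simulation(cfg_net)
  expect_true(sim$summary$converged)
  # peak inspiratory flow exceeds the prescribed dV/dt peak by (u - r)
  q0 <- 35 / 2 * 2 * pi * 44 / 60
  imbalance <- (0.044 * 35 * 44) * (1 / 0.8 - 1) / 60
  expect_equal(max(sim$trace$Q_mL_s), q0 + imbalance, tolerance = 1e-3)
})
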