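# Binding, protonation and electrostatic models.

test_that("quadratic isotherm reproduces its worked examples", {
  m <- quadratic_binding_model(f0 = 100, fb = 10, kd = 1.5, probe_total = 100)
  # frozen against the zero-competitor mass-balance solver (see below)
  expect_equal(eq1_fluorescence(m, 100), 20.36835, tolerance = 1e-6)
  expect_identical(eq1_fluorescence(m, 0), 100)

  # stoichiometric limit: infinitely tight binding at psi = probe saturates
  m2 <- quadratic_binding_model(100, 10, 1e-9, 100)
  expect_equal(eq1_fluorescence(m2, 100), 10, tolerance = 1e-3)
})

test_that("quadratic isotherm validates its inputs", {
  m <- quadratic_binding_model(100, 10, 1.5, 100)
  expect_error(eq1_fluorescence(m, -1), class = "fneo_domain_error")
  expect_error(eq1_fluorescence(m, NaN), class = "fneo_validation_error")
  expect_error(quadratic_binding_model(100, 10, -1, 100),
               class = "fneo_validation_error")
  expect_error(quadratic_binding_model(100, 10, 1.5, 0),
               class = "fneo_validation_error")
  expect_error(quadratic_binding_model(Inf, 10, 1.5, 100),
               class = "fneo_validation_error")
  # fb >= f0 (signal-increasing probes) is allowed
  expect_silent(eq1_fluorescence(quadratic_binding_model(10, 100, 1.5, 100), 50))
})

test_that("competitive solver matches its worked examples", {
  eq <- solve_competitive_equilibrium(100, 100, 1.5)
  # closed form (S - sqrt(S^2 - 4 psi P))/2
  s <- 100 + 100 + 1.5
  expect_equal(eq$bound_probe, (s - sqrt(s^2 - 4 * 100 * 100)) / 2,
               tolerance = 1e-10)
  expect_equal(eq$bound_probe, 88.4796, tolerance = 1e-5)

  all_free <- solve_competitive_equilibrium(100, 0, 1.5, 0)
  expect_equal(all_free$free_sites, 100, tolerance = 1e-12)
  expect_equal(all_free$bound_probe, 0)

  tight <- solve_competitive_equilibrium(100, 100, 1.5, 100, 1e-9)
  expect_lt(tight$bound_probe, 1)
})

test_that("closed form and numeric solver agree to 1e-8 over a grid", {
  probe <- 100
  for (kd in c(0.01, 0.1, 1, 10, 100, 1000)) {
    m <- quadratic_binding_model(100, 10, kd, probe)
    psi <- seq(0, 10 * probe, length.out = 41)
    f_closed <- eq1_fluorescence(m, psi)
    b <- solve_competitive_equilibrium(psi, probe, kd)$bound_probe
    f_solver <- 100 + (10 - 100) * b / probe
    expect_equal(f_closed, f_solver, tolerance = 1e-8)
  }
})

test_that("bound probe is monotone in competitor strength and amount", {
  set.seed(101)
  for (i in 1:25) {
    site <- runif(1, 10, 500)
    probe <- runif(1, 10, 500)
    kd_p <- 10^runif(1, -2, 2)
    kd_c <- 10^runif(1, -2, 3)
    ct <- sort(runif(8, 0, 1000))
    b <- solve_competitive_equilibrium(site, probe, kd_p, ct, kd_c)$bound_probe
    expect_true(all(diff(b) <= 1e-9))
    # tighter competitor (smaller kd) binds more, leaving less probe bound
    b2 <- solve_competitive_equilibrium(site, probe, kd_p, ct[5], kd_c / 10)
    expect_lte(b2$bound_probe, b[5] + 1e-9)
  }
})

test_that("solver outputs satisfy all mass balances to 1e-9 relative", {
  set.seed(202)
  for (i in 1:40) {
    site <- runif(1, 0, 500); probe <- runif(1, 0, 500)
    ct <- runif(1, 0, 500)
    kd_p <- 10^runif(1, -3, 3); kd_c <- 10^runif(1, -3, 3)
    eq <- solve_competitive_equilibrium(site, probe, kd_p, ct, kd_c)
    scale <- max(site, probe, ct, 1)
    expect_lt(abs(eq$bound_probe + eq$free_probe - probe), 1e-9 * scale)
    expect_lt(abs(eq$bound_competitor + eq$free_competitor - ct), 1e-9 * scale)
    expect_lt(abs(eq$free_sites + eq$bound_probe + eq$bound_competitor - site),
              1e-9 * scale)
    expect_true(all(unlist(eq[1:5]) >= 0))
  }
})

test_that("dianion fraction has the Henderson-Hasselbalch shape", {
  expect_identical(dianion_fraction(6.37, 6.37), 0.5)
  expect_equal(dianion_fraction(7.37, 6.37), 10 / 11, tolerance = 1e-12)
  expect_equal(dianion_fraction(4.37, 6.37), 1 / 101, tolerance = 1e-12)
  ph <- seq(2, 12, by = 0.1)
  fr <- dianion_fraction(ph, 6.37)
  expect_true(all(diff(fr) > 0))
  # symmetry about the pKa
  x <- runif(20, 0, 4)
  expect_equal(dianion_fraction(6.37 + x, 6.37) +
                 dianion_fraction(6.37 - x, 6.37),
               rep(1, 20), tolerance = 1e-12)
  pm <- protonation_model(6.37, 0.2, 1.0)
  ps <- protonation_signal(pm, 6.37)
  expect_equal(ps$signal, 0.6)
  expect_error(protonation_model(6.37, 0.5, 0.5),
               class = "fneo_validation_error")
})

test_that("pKa-shift potential follows phi = -2.303 delta_pKa", {
  res <- electrostatic_potential(6.37, 7.45)
  expect_equal(res$phi_kt_per_e, -2.303 * 1.08, tolerance = 1e-12)
  expect_equal(res$delta_pka, 1.08)
  expect_identical(electrostatic_potential(7.0, 7.0)$phi_kt_per_e, 0)
  expect_equal(electrostatic_potential(7.0, 6.0)$phi_kt_per_e, 2.303)
  # linear in delta with slope -2.303; volts = kT/e at the given temperature
  kt_e <- 8.312 * 298.2 / (6.023e23 * 1.602e-19)
  for (d in c(-1.3, -0.2, 0.4, 2.1)) {
    r <- electrostatic_potential(7, 7 + d)
    expect_equal(r$phi_kt_per_e, -2.303 * d, tolerance = 1e-12)
    expect_equal(r$phi_volts, r$phi_kt_per_e * kt_e, tolerance = 1e-12)
    expect_equal(sign(r$phi_kt_per_e), -sign(r$delta_pka))
  }
  expect_error(electrostatic_potential(0, 7), class = "fneo_validation_error")
})
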