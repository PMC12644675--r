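cond0 <- collision_conditions(z = 5, ion_mass = 9238.7, gas_mass = 39.948,
                              T_amb = 295)

test_that("voltage-to-temperature transform is affine with the pinned oracle value", {
  expect_equal(dcv_to_temperature(0, cond0), 295)
  t1 <- dcv_to_temperature(10, cond0) - 295
  t2 <- dcv_to_temperature(20, cond0) - 295
  expect_equal(t2, 2 * t1)
  # hand-evaluated center-of-mass energy oracle:
  # 5 * 1.602176634e-19 C * 13.5 V * [39.948/(39.948+9238.7)] / 1.380649e-23
  expect_equal(dcv_to_temperature(13.5, cond0), 3667.41665699, tolerance = 1e-9)
  # dof divisor scales the temperature rise
  cond10 <- collision_conditions(z = 5, ion_mass = 9238.7, T_amb = 295,
                                 dof_factor = 10)
  expect_equal(dcv_to_temperature(13.5, cond10) - 295,
               (dcv_to_temperature(13.5, cond0) - 295) / 10)
  expect_error(dcv_to_temperature(-1, cond0), ">= 0")
})

test_that("survival-to-rate conversion has the stated fixed points", {
  expect_equal(rate_from_survival(1), 0)
  expect_equal(rate_from_survival(exp(-1)), 1)
  expect_equal(rate_from_survival(0.5), log(2))
  expect_true(all(diff(rate_from_survival(seq(0.1, 1, by = 0.1))) < 0))
  expect_error(rate_from_survival(0), "> 0")
  expect_error(rate_from_survival(1.5), "<= 1")
})

test_that("Eyring free energy has its fixed point and log-linearity", {
  Tc <- 500
  k_free <- cond0$k_B * Tc / cond0$h
  expect_equal(free_energy_from_rate(k_free, Tc, cond0), 0, tolerance = 1e-9)
  g1 <- free_energy_from_rate(2, Tc, cond0)
  g2 <- free_energy_from_rate(2 / exp(1), Tc, cond0)
  expect_equal(g2 - g1, cond0$R * Tc / 1000, tolerance = 1e-9)
  # algebraic round trip
  for (dG in c(10, 23.9, 63.9)) {
    k <- (cond0$k_B * Tc / cond0$h) * exp(-dG * 1000 / (cond0$R * Tc))
    expect_equal(free_energy_from_rate(k, Tc, cond0), dG, tolerance = 1e-9)
  }
  expect_error(free_energy_from_rate(0, Tc, cond0), "> 0")
})

test_that("Arrhenius fit recovers a known line exactly", {
  Ts <- c(400, 500, 650, 800)
  lnA <- 20; Ea <- 60  # kJ/mol
  k <- exp(lnA - Ea * 1000 / (8.31446261815324 * Ts))
  fit <- fit_arrhenius(Ts, k)
  expect_equal(fit$ln_A, lnA, tolerance = 1e-9)
  expect_equal(fit$E_a, Ea, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_arrhenius(c(500, 500), c(1, 2)), "distinct")
  # two exact points determine the line
  f2 <- fit_arrhenius(Ts[1:2], k[1:2])
  expect_equal(f2$E_a, Ea, tolerance = 1e-9)
})

test_that("Ellingham fit returns enthalpy intercept and entropy slope", {
  Ts <- seq(400, 700, by = 50)
  dG <- 60 - 0.04 * Ts
  fit <- fit_ellingham(Ts, dG)
  expect_equal(fit$dH, 60, tolerance = 1e-9)
  expect_equal(fit$dS, 0.04, tolerance = 1e-12)
  # shifting temperatures leaves the slope unchanged
  fit2 <- fit_ellingham(Ts + 10, 60 - 0.04 * (Ts + 10))
  expect_equal(fit2$dS, fit$dS, tolerance = 1e-12)
  expect_equal(fit2$dH, 60, tolerance = 1e-9)
  expect_error(fit_ellingham(rep(500, 3), 1:3), "distinct")
})

test_that("ambient extrapolation satisfies the thermodynamic identities", {
  arr <- structure(list(ln_A = 20, E_a = 60, r_squared = 1),
                   class = "arrhenius_fit")
  ell <- structure(list(dH = 63.9, dS = 40.0 / 295, r_squared = 1),
                   class = "ellingham_fit")
  res <- extrapolate_ambient(arr, ell, cond0)
  expect_equal(res$dG_m0g, res$dH_m0g - res$TdS_m0g, tolerance = 1e-12)
  expect_equal(res$dG_m0g, 23.9, tolerance = 1e-9)
  expect_equal(res$KD_m0g, exp(-23.9e3 / (cond0$R * 295)), tolerance = 1e-12)
  expect_equal(res$k_m0g, exp(20 - 60e3 / (cond0$R * 295)), tolerance = 1e-12)
})

test_that("the tangent-derived points are near-collinear in both diagrams", {
  fit <- structure(list(A1 = 100, A2 = 0, x0 = 13.5, dx = 1.2, r_squared = 1),
                   class = "boltzmann_fit")
  # full default sampling window (10-90% survival): frozen oracle values
  an <- analyze_thermokinetics(fit, cond0)
  expect_gte(an$arrhenius$r_squared, 0.985)
  expect_gte(an$ellingham$r_squared, 0.995)
  expect_equal(an$result$dG_m0g, an$result$dH_m0g - an$result$TdS_m0g,
               tolerance = 1e-9)
  # interior window avoids the curved sigmoid tails: near-collinear
  an2 <- analyze_thermokinetics(fit, cond0, sy_bounds = c(25, 75))
  expect_gte(an2$arrhenius$r_squared, 0.99)
  expect_gte(an2$ellingham$r_squared, 0.999)
})

test_that("a later midpoint voltage gives a larger ambient free energy", {
  dgs <- vapply(c(10, 12, 13.5, 15), function(x0) {
    fit <- structure(list(A1 = 100, A2 = 0, x0 = x0, dx = 1.2, r_squared = 1),
                     class = "boltzmann_fit")
    analyze_thermokinetics(fit, cond0)$result$dG_m0g
  }, numeric(1))
  expect_true(all(diff(dgs) > 0))
})
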