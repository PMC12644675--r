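make_norm_table <- function(dcv, reps, sy_fun) {
  do.call(rbind, lapply(reps, function(r)
    do.call(rbind, lapply(dcv, function(v) {
      sy <- sy_fun(v, r)
      data.frame(delta_cv = v, replicate_id = r,
                 species = c("trimer", "monomer"),
                 percent = c(sy, 100 - sy))
    }))))
}

test_that("curve assembly averages replicates and checks the schedule", {
  dcv <- c(0, 5, 10, 15)
  tab <- make_norm_table(dcv, c("r1", "r2"), function(v, r) 100 - 2 * v)
  cv <- assemble_curve(tab)
  expect_s3_class(cv, "sy_curve")
  expect_equal(cv$sy_sd, rep(0, 4))
  expect_equal(cv$n_replicates, rep(2L, 4))

  tab2 <- make_norm_table(dcv, c("r1", "r2"),
                          function(v, r) if (r == "r1") 80 else 90)
  expect_equal(assemble_curve(tab2)$sy_mean, rep(85, 4))

  # mismatched schedules name the missing pairs
  tab3 <- tab[!(tab$replicate_id == "r2" & tab$delta_cv == 10), ]
  expect_error(assemble_curve(tab3), "r2, 10")
  expect_error(assemble_curve(tab[tab$delta_cv < 6, ]), ">= 3 distinct")
})

test_that("the 11-step voltage schedule yields an 11-point curve", {
  sim <- generate_dissociation_series(
    dissociation_series_spec(foldon_sequences()[["foldon0"]], seed = 3))
  tab <- normalize_spectra(sim$spectra, sim$targets)
  cv <- assemble_curve(tab)
  expect_equal(nrow(cv), 11)
  expect_equal(cv$delta_cv, c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50))
})

test_that("Boltzmann fitting recovers exact model data to 1e-6", {
  cv <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
  crv <- sy_curve(cv, boltzmann(cv, 100, 0, 13.5, 1.2))
  fit <- fit_boltzmann(crv)
  expect_equal(fit$A1, 100, tolerance = 1e-6)
  expect_equal(fit$A2, 0, tolerance = 1e-6)
  expect_equal(fit$x0, 13.5, tolerance = 1e-6)
  expect_equal(fit$dx, 1.2, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # free plateaus away from 100/0
  crv2 <- sy_curve(cv, boltzmann(cv, 92, 6, 11, 1.8))
  fit2 <- fit_boltzmann(crv2)
  expect_equal(c(fit2$A1, fit2$A2, fit2$x0, fit2$dx), c(92, 6, 11, 1.8),
               tolerance = 1e-6)
  # pinned variant
  fit3 <- fit_boltzmann(crv, pin_plateaus = TRUE)
  expect_equal(c(fit3$A1, fit3$A2), c(100, 0))
  expect_equal(fit3$x0, 13.5, tolerance = 1e-6)
})

test_that("fits warn on rising data and require enough points", {
  cv <- seq(0, 40, by = 4)
  set.seed(5)
  rising <- pmin(pmax(boltzmann(cv, 0, 100, 15, 2) + rnorm(length(cv), 0, 0.5),
                      0), 100)
  expect_warning(fit <- fit_boltzmann(sy_curve(cv, rising)), "decay")
  expect_gt(fit$A2, fit$A1)  # rising orientation preserved, dx kept positive
  expect_gt(fit$dx, 0)
  expect_error(fit_boltzmann(sy_curve(c(0, 10, 20), c(90, 50, 10))), ">= 4")
})

test_that("Boltzmann fit is translation equivariant in voltage", {
  cv <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
  set.seed(21)
  y <- pmin(pmax(boltzmann(cv, 100, 0, 13.5, 1.2) + rnorm(11, 0, 1), 0), 100)
  f0 <- fit_boltzmann(sy_curve(cv, y))
  for (shift in c(3.7, 10)) {
    f1 <- fit_boltzmann(sy_curve(cv + shift, y))
    expect_equal(f1$x0, f0$x0 + shift, tolerance = 1e-5)
    expect_equal(f1$dx, f0$dx, tolerance = 1e-5)
    expect_equal(f1$A1, f0$A1, tolerance = 1e-5)
  }
})

test_that("midpoint recovery: median error < 0.3 V at 2 percent noise", {
  cv <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- rowMeans(vapply(1:2, function(r)
      pmin(pmax(boltzmann(cv, 100, 0, 13.5, 1.2) + rnorm(11, 0, 2), 0), 100),
      numeric(11)))
    fit_boltzmann(sy_curve(cv, y))$x0 - 13.5
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.3)
})

test_that("parameter bias vanishes as noise goes to zero", {
  cv <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
  bias <- vapply(c(2, 0.5, 0.05), function(sd) {
    errs <- vapply(1:40, function(s) {
      set.seed(1000 + s)
      y <- pmin(pmax(boltzmann(cv, 100, 0, 13.5, 1.2) + rnorm(11, 0, sd), 0), 100)
      fit_boltzmann(sy_curve(cv, y))$x0 - 13.5
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 1e-6)
  expect_lt(bias[3], 0.02)
})

test_that("the midpoint tangent matches the closed form and a numeric derivative", {
  fit <- fit_boltzmann(sy_curve(c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50),
                                boltzmann(c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50),
                                          100, 0, 13.5, 1)))
  line <- tangent_at_midpoint(fit)
  expect_equal(line$slope, -25, tolerance = 1e-5)
  expect_equal(line$intercept + line$slope * fit$x0, 50, tolerance = 1e-5)
  # numerical-derivative oracle
  h <- 1e-5
  num <- (boltzmann(fit$x0 + h, fit$A1, fit$A2, fit$x0, fit$dx) -
            boltzmann(fit$x0 - h, fit$A1, fit$A2, fit$x0, fit$dx)) / (2 * h)
  expect_equal(line$slope, num, tolerance = 1e-9)
})

test_that("tangent sampling is linear, bounded and clipped", {
  fit <- structure(list(A1 = 100, A2 = 0, x0 = 13.5, dx = 1.2, r_squared = 1),
                   class = "boltzmann_fit")
  line <- tangent_at_midpoint(fit)
  pts <- sample_tangent(fit, line, n_points = 2, sy_bounds = c(25, 75))
  expect_equal(pts$sy, c(75, 25))
  expect_equal(line$intercept + line$slope * pts$delta_cv, pts$sy)

  pts5 <- sample_tangent(fit, line, n_points = 5)
  expect_true(all(pts5$sy > 0 & pts5$sy < 100))
  expect_equal(diff(pts5$delta_cv), rep(diff(pts5$delta_cv)[1], 4))
  # a regression through the sampled points returns the tangent slope exactly
  co <- coef(lm(sy ~ delta_cv, data = pts5))
  expect_equal(unname(co[2]), line$slope, tolerance = 1e-9)
  expect_error(sample_tangent(fit, line, sy_bounds = c(0, 90)), "bounds")
  expect_error(sample_tangent(fit, line, n_points = 1), "n_points")
})
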