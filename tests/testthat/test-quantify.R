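# Bead arithmetic, standard curves, inversion, normalisation and
# dispersion-rate regression.

test_that("bead formula evaluates the solids-to-count conversion", {
  expect_equal(beads_per_ml(0.02, 1.055, 2), 4.5257e9, tolerance = 1e-4)
  expect_equal(beads_per_ml(0, 1.055, 2), 0)      # documented boundary
  expect_error(beads_per_ml(0.02, 0, 2), "positive")
  expect_error(beads_per_ml(0.02, 1.055, -1), "positive")
  # linear in S, inverse-cubic in phi
  set.seed(21)
  for (i in 1:20) {
    S <- runif(1, 0.005, 0.1); rho <- runif(1, 0.9, 1.3); phi <- runif(1, 0.05, 5)
    expect_equal(beads_per_ml(3 * S, rho, phi), 3 * beads_per_ml(S, rho, phi))
    expect_equal(beads_per_ml(S, rho, 2 * phi), beads_per_ml(S, rho, phi) / 8)
  }
})

test_that("reference stocks and injected doses match the protocol", {
  specs <- fluosphere_specs()
  expect_equal(specs$green$stock_concentration, 4.143e13)
  expect_equal(specs$red$stock_concentration, 1.326e8)
  # 50 ul of a 1:1 mix delivers stock * 0.025 ml per channel
  expect_equal(injected_dose(specs$green, 50, 0.5), 1.03575e12)
  expect_equal(injected_dose(specs$red, 50, 0.5), 3.315e6)
  expect_equal(injected_dose(specs$green, 0, 1), 0)
})

test_that("serial dilution series is geometric and strictly decreasing", {
  expect_equal(make_dilution_series(1e6, 10, 3), c(1e5, 1e4, 1e3))
  expect_equal(make_dilution_series(8, 2, 1), 4)
  expect_true(all(diff(make_dilution_series(1e12, 3.7, 12)) < 0))
  expect_error(make_dilution_series(1e6, 1, 3))
})

test_that("standard curve fit and inversion are exact on noiseless data", {
  conc <- make_dilution_series(1e12, 4, 8)
  readings <- 2e-9 * conc + 5
  curve <- fit_standard_curve(conc, readings)
  expect_equal(curve$slope, 2e-9)
  expect_equal(curve$intercept, 5)
  expect_equal(curve$r_squared, 1)
  # round trip is the identity
  expect_equal(as.numeric(reading_to_concentration(curve, readings)), conc)
  # reading at or below the fitted background clamps to 0 with a flag
  at_bg <- reading_to_concentration(curve, c(5, 4))
  expect_equal(as.numeric(at_bg), c(0, 0))
  expect_true(all(attr(at_bg, "below_background")))
  expect_error(fit_standard_curve(rep(1e6, 4), c(1, 2, 3, 4)), "distinct")
  expect_error(fit_standard_curve(c(1, 2), c(1, 2)), ">= 3")
})

test_that("noisy standard curves recover the slope within 5%", {
  conc <- make_dilution_series(1e12, 4, 10)
  set.seed(31)
  readings <- 2e-9 * conc + 5 + rnorm(10, 0, 0.02 * max(2e-9 * conc + 5))
  curve <- fit_standard_curve(conc, readings)
  expect_equal(curve$slope, 2e-9, tolerance = 0.05)
  expect_gt(curve$r_squared, 0.99)
})

test_that("percent of injected dose normalises against compartment and dose", {
  dose <- injected_dose(fluosphere_specs()$green, 50, 0.5)
  expect_equal(percent_injected(1e10, 250, dose), 0.24137, tolerance = 1e-4)
  expect_equal(percent_injected(0, 250, dose), 0)
  # concentration equal to dose per compartment volume -> 100%
  expect_equal(percent_injected(dose / 0.25, 250, dose), 100)
  expect_error(percent_injected(1e10, 250, 0), "positive")
})

test_that("dispersion rate is the least-squares accumulation slope", {
  k <- 3.1e9
  exact <- dispersion_rate(data.frame(time_h = c(2, 4),
                                      concentration = c(2 * k, 4 * k)),
                           anchor_origin = TRUE)
  expect_equal(exact$rate, k)
  expect_equal(exact$n_points, 3)

  flat <- dispersion_rate(data.frame(time_h = c(2, 4), concentration = c(7, 7)))
  expect_equal(flat$rate, 0)

  expect_error(dispersion_rate(data.frame(time_h = 2, concentration = 1)),
               "2 distinct")
  # channel filtering
  df <- data.frame(time_h = c(2, 4, 2, 4), concentration = c(2, 4, 20, 40),
                   channel = c("green", "green", "red", "red"))
  expect_equal(dispersion_rate(df, channel = "red")$rate, 10)
})

test_that("dispersion regression is unbiased at 5% multiplicative noise", {
  true_rate <- 1.6e10
  sdlog <- sqrt(log(1 + 0.05^2))
  set.seed(41)
  est <- vapply(1:200, function(s) {
    t <- rep(c(2, 4), 6)
    y <- true_rate * t * rlnorm(length(t), -sdlog^2 / 2, sdlog)
    dispersion_rate(data.frame(time_h = t, concentration = y))$rate
  }, numeric(1))
  expect_lt(abs(mean(est) / true_rate - 1), 0.02)
  expect_lt(abs(stats::median(est) / true_rate - 1), 0.1)
})

test_that("species fold ratio reproduces the reported 20 nm and 2000 nm ratios", {
  expect_equal(species_fold_ratio(1.62e10, 6.15e9), 2.634, tolerance = 1e-3)
  expect_equal(species_fold_ratio(3.59e3, 2.45e3), 1.465, tolerance = 1e-3)
  expect_equal(species_fold_ratio(5, 5), 1)
  a <- dispersion_rate(data.frame(time_h = c(2, 4), concentration = c(2, 4)))
  b <- dispersion_rate(data.frame(time_h = c(2, 4), concentration = c(4, 8)))
  expect_equal(species_fold_ratio(a, b), 0.5)
  expect_error(species_fold_ratio(1, 0), "positive")
})
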