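# Seeded measurement-process generators.

test_that("pressure traces follow P = F/C with reproducible AR(1) noise", {
  clean <- simulate_pressure_trace(0.25, noise_sd_mmhg = 0)
  expect_true(all(clean$pressures == 2.4 / 0.25))
  expect_equal(mean(clean$pressures), 9.6)

  a <- simulate_pressure_trace(0.25, noise_sd_mmhg = 0.3, seed = 5)
  b <- simulate_pressure_trace(0.25, noise_sd_mmhg = 0.3, seed = 5)
  c <- simulate_pressure_trace(0.25, noise_sd_mmhg = 0.3, seed = 6)
  expect_identical(a$pressures, b$pressures)
  expect_false(identical(a$pressures, c$pressures))

  drifted <- simulate_pressure_trace(0.25, duration_min = 120,
                                     noise_sd_mmhg = 0, drift_mmhg_per_h = 1)
  expect_equal(drifted$pressures[length(drifted$pressures)] -
                 drifted$pressures[1], 2)
})

test_that("transfer kinetics: no transfer means an empty anterior chamber", {
  m <- transfer_model(c(green = 1e12), c(green = 0), noise_cv = 0)
  kin <- simulate_transfer_kinetics(m)
  expect_true(all(kin$concentration == 0))
})

test_that("transfer kinetics conserve beads exactly in the noiseless model", {
  for (washout in c(0, 1.2, 2.4)) {
    m <- transfer_model(c(green = 1.036e12, red = 3.3e6),
                        c(green = 4e-3, red = 2e-4),
                        ac_volume_ul = 250, washout_rate = washout,
                        noise_cv = 0)
    kin <- simulate_transfer_kinetics(m, sample_times_h = c(1, 2, 4))
    cons <- attr(kin, "truth")$conservation
    total <- cons$vitreous + cons$ac + cons$washed + cons$sampled
    expect_equal(total, cons$dose, tolerance = 1e-6)
    expect_true(all(cons$washed >= -1e-6 * cons$dose))
  }
})

test_that("small-k noiseless accumulation is linear with slope k*dose/V", {
  m <- transfer_model(c(green = 1e12), c(green = 1e-4), ac_volume_ul = 250,
                      washout_rate = 0, noise_cv = 0)
  kin <- simulate_transfer_kinetics(m, sample_volume_ul = 0)
  truth <- attr(kin, "truth")$channels$green
  expect_equal(truth$rate_true, truth$rate_small_k, tolerance = 1e-3)
  # concentrations themselves are near-proportional to time
  expect_equal(kin$concentration[2] / kin$concentration[1], 2, tolerance = 1e-3)
})

test_that("kinetics with washout match an independent fine-step integration", {
  m <- transfer_model(c(green = 1e10), c(green = 0.3), ac_volume_ul = 250,
                      washout_rate = 2.4, noise_cv = 0)
  kin <- simulate_transfer_kinetics(m, sample_times_h = c(2, 4),
                                    sample_volume_ul = 30)
  # Euler oracle at dt = 1e-4 h with the same sampling events
  k <- 0.3; q <- 2.4 * 60 / 250; dt <- 1e-4
  Nv <- 1e10; Na <- 0; out <- numeric(0); t <- 0
  for (target in c(2, 4)) {
    while (t < target - dt / 2) {
      dNv <- -k * Nv; dNa <- k * Nv - q * Na
      Nv <- Nv + dt * dNv; Na <- Na + dt * dNa; t <- t + dt
    }
    out <- c(out, Na * 1000 / 250)
    Na <- Na * (1 - 30 / 250)
  }
  expect_equal(kin$concentration_true, out, tolerance = 1e-3)
})

test_that("sampling withdrawal dilutes the following time point", {
  base <- transfer_model(c(green = 1e12), c(green = 1e-4), noise_cv = 0)
  with_sampling <- simulate_transfer_kinetics(base, sample_volume_ul = 30)
  no_sampling <- simulate_transfer_kinetics(base, sample_volume_ul = 0)
  expect_equal(with_sampling$concentration_true[1],
               no_sampling$concentration_true[1])
  expect_lt(with_sampling$concentration_true[2],
            no_sampling$concentration_true[2])
})

test_that("plate readings follow the line with seeded multiplicative noise", {
  conc <- c(0, 1e8, 5e9)
  expect_equal(simulate_plate_readings(conc, 2e-9, 5), 2e-9 * conc + 5)
  expect_equal(simulate_plate_readings(0, 2e-9, 5), 5)

  r1 <- simulate_plate_readings(rep(1e9, 500), 2e-9, 5, noise_cv = 0.02, seed = 9)
  r2 <- simulate_plate_readings(rep(1e9, 500), 2e-9, 5, noise_cv = 0.02, seed = 9)
  expect_identical(r1, r2)
  line <- 2e-9 * 1e9 + 5
  expect_gte(mean(abs(r1 / line - 1) <= 0.10), 0.95)
})

test_that("particle fields carry exact ground truth and reproduce per seed", {
  empty <- simulate_particle_field(0, image_px = 64, seed = 1)
  expect_equal(nrow(attr(empty, "truth")), 0)
  expect_equal(detect_particles(empty, threshold = 1.0)$count, 0)

  two <- simulate_particle_field(2, image_px = 256, seed = 2)
  expect_equal(nrow(attr(two, "truth")), 2)

  a <- simulate_particle_field(10, image_px = 128, seed = 4)
  b <- simulate_particle_field(10, image_px = 128, seed = 4)
  expect_identical(a$pixels, b$pixels)
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  expect_error(simulate_particle_field(500, image_px = 64, seed = 1,
                                       max_tries = 20), "place")
})

test_that("size populations separate end to end through the detector", {
  med <- function(median_um, seed) {
    img <- simulate_particle_field(15, median_diameter_um = median_um,
                                   image_px = 384, seed = seed)
    stats::median(detect_particles(img, threshold = 1.0)$diameters_um)
  }
  ratios <- vapply(1:10, function(s) med(15, s) / med(7.5, 100 + s), numeric(1))
  # the two formulation regimes (10-20 um vs 5-10 um) differ by ~2x
  expect_gte(mean(abs(ratios - 2) < 0.4), 0.9)
  expect_equal(stats::median(ratios), 2, tolerance = 0.15)
})

test_that("small-vs-large bead worlds reproduce the qualitative size effect", {
  m <- reference_transfer_model("pig", noise_cv = 0)
  kin <- simulate_transfer_kinetics(m)
  rates <- vapply(attr(kin, "truth")$channels, `[[`, numeric(1), "rate_true")
  expect_gte(rates[["green"]] / rates[["red"]], 1e6)
  # large beads stay near baseline as a percent of injected dose
  red_c4 <- kin$concentration_true[kin$channel == "red" & kin$time_h == 4]
  pct_red <- percent_injected(red_c4, 250, m$injected_dose[["red"]])
  expect_lt(pct_red, 0.1)
  # conservation caps percent injected at 100 for every channel/time
  pct_all <- percent_injected(kin$concentration_true, 250,
                              m$injected_dose[match(kin$channel,
                                                    names(m$injected_dose))])
  expect_true(all(pct_all <= 100))
})
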