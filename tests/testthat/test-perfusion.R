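# Perfusion QC: calibration, outflow facility, inclusion gating,
# drug-response detection.

test_that("transducer calibration recovers exact and noisy lines", {
  cal <- calibrate_transducer(c(0, 1, 2), c(0, 10, 20))
  expect_equal(cal$slope, 10)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  expect_equal(predict(cal, 1.5), 15)

  set.seed(101)
  v <- seq(0, 5, by = 0.5)
  p_ref <- 15 * v + 2 + rnorm(length(v), 0, 0.5)
  noisy <- calibrate_transducer(v, p_ref)
  expect_equal(noisy$slope, 15, tolerance = 0.05)

  expect_error(calibrate_transducer(c(1, 1, 1), c(5, 6, 7)), "distinct")
})

test_that("outflow facility is Flow/IOP and homogeneous in flow", {
  expect_equal(outflow_facility(2.4, 12), 0.2)
  expect_equal(outflow_facility(2.4, 6.857), 0.35, tolerance = 1e-4)
  expect_equal(outflow_facility(0, 10), 0)
  expect_error(outflow_facility(2.4, 0), "positive")
  expect_error(outflow_facility(2.4, -3), "positive")
  set.seed(5)
  for (i in 1:20) {
    fl <- runif(1, 1, 5); pr <- runif(1, 5, 25); c0 <- runif(1, 0.5, 3)
    expect_equal(outflow_facility(c0 * fl, pr), c0 * outflow_facility(fl, pr))
  }
})

test_that("facility series masks transient non-positive pressures", {
  rec <- perfusion_record("e1", "pig", 2.4, 0:4, c(12, 12, 0, 12, 12))
  fs <- facility_series(rec)
  expect_equal(fs[c(1, 2, 4, 5)], rep(0.2, 4))
  expect_true(is.na(fs[3]))

  const <- perfusion_record("e2", "pig", 2.4, 0:10, rep(12, 11))
  expect_equal(facility_series(const), rep(0.2, 11))
})

test_that("facility estimate on synthetic stable traces recovers the truth", {
  rec <- simulate_pressure_trace(0.25, noise_sd_mmhg = 0.3, seed = 3)
  expect_equal(mean(facility_series(rec)), 0.25, tolerance = 0.03)
  # unbiased recovery across 100 seeds: mean error < 2%
  est <- vapply(1:100, function(s) {
    mean(facility_series(simulate_pressure_trace(0.25, duration_min = 120,
                                                 noise_sd_mmhg = 0.3, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(est) / 0.25 - 1), 0.02)
})

test_that("inclusion gating applies species ranges, drift and both reason codes", {
  pig <- inclusion_criteria("pig")
  human <- inclusion_criteria("human")
  expect_equal(c(pig$facility_min, pig$facility_max), c(0.18, 0.35))
  expect_equal(c(human$facility_min, human$facility_max), c(0.18, 0.40))

  steady <- function(C) perfusion_record("e", "pig", 2.4, 0:60, rep(2.4 / C, 61))
  expect_true(check_inclusion(steady(0.25), pig)$pass)

  r38 <- steady(0.38)
  expect_false(check_inclusion(r38, pig)$pass)
  expect_match(check_inclusion(r38, pig)$reasons, "upper bound", all = FALSE)
  expect_true(check_inclusion(r38, human)$pass)

  # drift 0.30 -> 0.15 inside the window: drift + lower-bound violations
  drifting <- perfusion_record("e", "pig", 2.4, 0:30,
                               2.4 / seq(0.30, 0.15, length.out = 31))
  res <- check_inclusion(drifting, pig)
  expect_false(res$pass)
  expect_match(res$reasons, "drift", all = FALSE)
  expect_match(res$reasons, "lower bound", all = FALSE)

  short <- perfusion_record("e", "pig", 2.4, 0:10, rep(10, 11))
  expect_error(check_inclusion(short, pig), "shorter")
})

test_that("widening the inclusion range never turns a pass into a fail", {
  set.seed(11)
  for (i in 1:25) {
    rec <- simulate_pressure_trace(runif(1, 0.1, 0.5), duration_min = 60,
                                   noise_sd_mmhg = 0.4, seed = 1000 + i)
    crit <- inclusion_criteria(facility_min = 0.18, facility_max = 0.35)
    wide <- inclusion_criteria(facility_min = 0.10, facility_max = 0.50)
    if (check_inclusion(rec, crit)$pass) {
      expect_true(check_inclusion(rec, wide)$pass)
    }
  }
})

test_that("facility response reports contralateral-controlled fold change", {
  step_rec <- function(pre, post, id) {
    perfusion_record(id, "pig", 2.4, 0:240,
                     2.4 / c(rep(pre, 121), rep(post, 120)))
  }
  treated <- step_rec(0.2, 0.4, "t")
  control <- step_rec(0.2, 0.2, "c")
  expect_equal(facility_response(treated, control, 120), 2.0)
  expect_equal(facility_response(control, control, 120), 1.0)

  # cytochalasin-like +60% step under seeded noise
  noisy_step <- function(fold, seed, id) {
    base <- simulate_pressure_trace(0.2, duration_min = 240,
                                    noise_sd_mmhg = 0.15, seed = seed, eye_id = id)
    p <- base$pressures
    p[base$times > 120] <- p[base$times > 120] / fold
    perfusion_record(id, "pig", 2.4, base$times, p)
  }
  folds <- vapply(1:20, function(s) {
    facility_response(noisy_step(1.6, s, "t"), noisy_step(1.0, 100 + s, "c"), 120)
  }, numeric(1))
  expect_equal(mean(folds), 1.6, tolerance = 0.1 / 1.6)

  flat0 <- perfusion_record("z", "pig", 2.4, 0:240, rep(1e9, 241))
  expect_error(facility_response(step_rec(0.2, 0.2, "a"),
                                 perfusion_record("b", "pig", 2.4, c(0, 240),
                                                  c(10, 10)), 120),
               "baseline")
})

test_that("perfusion record validates its invariants", {
  expect_error(perfusion_record("e", "pig", 0, 0:2, c(1, 2, 3)), "positive")
  expect_error(perfusion_record("e", "pig", 2.4, c(0, 0, 1), c(1, 2, 3)),
               "increasing")
  expect_error(perfusion_record("e", "dog", 2.4, 0:2, c(1, 2, 3)))
})
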