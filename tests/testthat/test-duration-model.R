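test_that("speed_at reproduces hand evaluations of the rational model", {
  expect_equal(speed_at(reri_params(9.0, 0.08, 0.0185), 0), 9.0)
  p <- reri_params(10.0, 0.111, 0.0185)
  expect_equal(speed_at(p, 100), (10 + 11.1) / (1 + 1.85), tolerance = 1e-12)
  p2 <- reri_params(9.0, 0.0740, 0.0185)
  expect_lt(abs(speed_at(p2, 1e6) - 0.0740 / 0.0185), 1e-3)
  expect_error(speed_at(p, -1), "non-negative")
})

test_that("energy_at shares the algebra and checks the parameter type", {
  e0 <- reri_params(2.05, 0, 0.0185, type = "energy")
  expect_equal(energy_at(e0, 0), 2.05)
  e <- reri_params(2.0, 0.0148, 0.0185, type = "energy")
  expect_equal(energy_at(e, 60), (2 + 0.888) / (1 + 1.11), tolerance = 1e-12)
  expect_lt(abs(energy_at(e, 1e7) - 0.80), 1e-4)
  expect_error(energy_at(reri_params(9, 0.08, 0.0185), 10), "energy")
})

test_that("parameter invariants are enforced and degeneracy flagged", {
  expect_error(reri_params(-1, 0.1, 0.0185), "MAnS")
  expect_error(reri_params(9, -0.1, 0.0185), "non-negative")
  expect_error(reri_params(9, 0.1, 0), "positive")
  expect_warning(reri_params(4, 0.1, 0.0185), "degenerate")
})

test_that("inversion solves the race-time quadratic, matching bisection", {
  p <- reri_params(10.0, 0.111, 0.0185)
  t800 <- invert_for_duration(p, 800)
  expect_equal(t800, invert_oracle(p, 800), tolerance = 1e-8)
  expect_equal(round(t800, 2), 109.23)
  expect_equal(speed_at(p, t800) * t800, 800, tolerance = 1e-6)
  expect_error(invert_for_duration(p, -5), "positive")
})

test_that("inversion handles the linear b = 0 case and its breakdown", {
  p0 <- reri_params(10.0, 0, 1e-12)
  expect_equal(invert_for_duration(p0, 800), 80, tolerance = 1e-6)
  p <- reri_params(10.0, 0, 0.0185)
  expect_equal(invert_for_duration(p, 400), 400 / (10 - 0.0185 * 400),
               tolerance = 1e-12)
  expect_error(invert_for_duration(p, 800), "no finite race time")
})

test_that("inversion identity holds over random parameters and distances", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_params()
    d <- runif(1, 50, 1e4)
    t_star <- invert_for_duration(p, d)
    expect_equal(speed_at(p, t_star) * t_star, d, tolerance = 1e-6)
  }
})

test_that("valid parameters give a strictly decreasing speed curve", {
  set.seed(7)
  tt <- seq(0, 5000, length.out = 1e4)
  for (i in 1:20) {
    p <- random_params()
    v <- speed_at(p, tt)
    expect_true(all(diff(v) < 0))
    expect_lt(abs(speed_at(p, 1e6) - p$MAS), 1e-3)
  }
})

test_that("two-trial calibration interpolates model-consistent points exactly", {
  p <- reri_params(9.0, 0.10, 0.0185)
  trials <- simulate_trials(p, durations = c(10, 200))
  m <- two_trial_calibrate(run_trial(trials$duration_s[1], speed = trials$speed_ms[1]),
                           run_trial(trials$duration_s[2], speed = trials$speed_ms[2]))
  expect_equal(coef(m)[["MAnS"]], 9.0, tolerance = 1e-12)
  expect_equal(coef(m)[["b"]], 0.10, tolerance = 1e-12)
  expect_lt(max(abs(residuals(m))), 1e-12)
})

test_that("two-trial calibration matches the linear-solve oracle on race data", {
  tr <- coe_trials()
  m <- two_trial_calibrate(tr$short, tr$long)
  oracle <- two_trial_oracle(47.05, 400 / 47.05, 227.33, 1609 / 227.33)
  expect_equal(coef(m)[["MAnS"]], oracle$MAnS, tolerance = 1e-12)
  expect_equal(coef(m)[["b"]], oracle$b, tolerance = 1e-12)
  expect_equal(round(coef(m)[["MAnS"]], 2), 10.44)
  expect_equal(round(coef(m)[["b"]], 4), 0.1162)
  # both inputs reproduced to machine precision
  expect_lt(max(abs(residuals(m))), 1e-12)
})

test_that("two-trial calibration rejects equal durations", {
  expect_error(
    two_trial_calibrate(run_trial(60, speed = 8), run_trial(60, speed = 7)),
    "distinct"
  )
})

test_that("noise-free fits recover the generating parameters", {
  p <- reri_params(9.03, 0.0770, 0.0185)
  d <- simulate_trials(p, durations = c(7, 25, 60, 150, 400))
  m_fix <- reri_model(d, fix_c = 0.0185)
  expect_equal(coef(m_fix)[["MAnS"]], 9.03, tolerance = 1e-8)
  expect_equal(coef(m_fix)[["b"]], 0.0770, tolerance = 1e-8)
  m_free <- reri_model(d, free_c = TRUE)
  expect_equal(coef(m_free)[["MAnS"]], 9.03, tolerance = 1e-6)
  expect_equal(coef(m_free)[["c"]], 0.0185, tolerance = 1e-6)
})

test_that("the two-point fixed-c fit equals the two-trial calibration", {
  p <- reri_params(8.5, 0.09, 0.0185)
  d <- simulate_trials(p, durations = c(12, 300))
  m_fit <- reri_model(d, fix_c = 0.0185)
  m_tt <- two_trial_calibrate(
    run_trial(d$duration_s[1], speed = d$speed_ms[1]),
    run_trial(d$duration_s[2], speed = d$speed_ms[2])
  )
  expect_equal(coef(m_fit), coef(m_tt), tolerance = 1e-12)
})

test_that("noisy seeded fits recover parameters within 5%", {
  p <- reri_params(9.03, 0.0770, 0.0185)
  d <- simulate_trials(p, durations = seq(10, 600, length.out = 20),
                       noise_sd = 0.05, seed = 7)
  m <- reri_model(d, fix_c = 0.0185)
  expect_equal(coef(m)[["MAnS"]], 9.03, tolerance = 0.05)
  expect_equal(coef(m)[["b"]], 0.0770, tolerance = 0.05)
})

test_that("fitting rejects under-determined or duplicated input", {
  p <- reri_params(9, 0.08, 0.0185)
  one <- simulate_trials(p, durations = 30)
  expect_error(reri_model(one, fix_c = 0.0185), "at least 2")
  two <- simulate_trials(p, durations = c(30, 200))
  expect_error(reri_model(two, free_c = TRUE), "at least 3")
  dup <- simulate_trials(p, durations = c(30, 30, 200))
  expect_error(reri_model(dup), "distinct")
})

test_that("energy-variant fitting recovers energy parameters", {
  e <- reri_params(1.91, 0.0159, 0.0185, type = "energy")
  tt <- c(10, 60, 180, 600)
  d <- data.frame(duration_s = tt, energy = energy_at(e, tt))
  m <- reri_model(d, type = "energy")
  expect_equal(coef(m)[["MAnS"]], 1.91, tolerance = 1e-8)
  expect_equal(coef(m)[["b"]], 0.0159, tolerance = 1e-8)
})

test_that("prediction fills speeds, ratios and percent errors", {
  tr <- coe_trials()
  m <- two_trial_calibrate(tr$short, tr$long)
  pr <- predict(m, distance = 800, actual_duration = 101.7)
  expect_equal(round(pr$predicted_duration_s, 1), 103.9)
  expect_equal(pr$predicted_speed_ms * pr$predicted_duration_s, 800,
               tolerance = 1e-9)
  expect_equal(round(pr$percent_error, 1), 2.1)
  expect_equal(pr$ratio, pr$predicted_speed_ms / (800 / 101.7),
               tolerance = 1e-12)
  # duration target at zero returns the anaerobic maximum
  pr0 <- predict(m, duration = 0)
  expect_equal(pr0$predicted_speed_ms, coef(m)[["MAnS"]])
})

test_that("model-consistent targets predict with zero error", {
  p <- reri_params(9.0, 0.10, 0.0185)
  t_star <- invert_for_duration(p, 1500)
  pr <- predict_performance(p, distance = 1500, actual_duration = t_star)
  expect_equal(pr$percent_error, 0, tolerance = 1e-9)
})

test_that("batch prediction summarises cohort agreement", {
  p <- reri_params(9.0, 0.10, 0.0185)
  dists <- c(200, 400, 800, 1500, 3000)
  targets <- data.frame(distance_m = dists,
                        actual_duration_s = invert_for_duration(p, dists))
  b <- batch_predict(p, targets)
  expect_equal(b$mean_percent_error, 0, tolerance = 1e-9)
  expect_equal(b$r_squared, 1, tolerance = 1e-9)
  # single target: SD undefined, reported as NA
  b1 <- batch_predict(p, targets[1, ])
  expect_true(is.na(b1$sd_percent_error))
  expect_error(batch_predict(p, targets[0, ]), "non-empty")
})

test_that("a noisy synthetic cohort is predicted within 3% mean error", {
  set.seed(11)
  errs <- c()
  for (i in 1:10) {
    p <- random_params()
    obs <- simulate_trials(p, durations = c(15, 45, 120, 300, 700),
                           noise_sd = 0.05, seed = 11 + i)
    m <- reri_model(obs[c(1, 5), ], fix_c = 0.0185)
    targets <- data.frame(distance_m = obs$distance_m[2:4],
                          actual_duration_s = obs$duration_s[2:4])
    errs <- c(errs, batch_predict(m, targets)$mean_percent_error)
  }
  expect_lt(mean(errs), 3)
})
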