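test_that("resampling and smoothing preserves constants and is idempotent", {
  tr <- vo2_trace(time = seq(0, 120, by = 2.5), vo2 = rep(40, 49))
  sm <- resample_and_smooth(tr)
  expect_true(all(sm$vo2 == 40))
  expect_equal(resample_and_smooth(sm)$vo2, sm$vo2)
  expect_equal(sm$time, 0:120)
})

test_that("interior points of a linear ramp pass the moving average unchanged", {
  tr <- vo2_trace(time = 0:100, vo2 = 10 + 0.3 * (0:100))
  sm <- resample_and_smooth(tr)
  interior <- 3:99  # indices with a full 5-point window
  expect_equal(sm$vo2[interior], tr$vo2[interior], tolerance = 1e-12)
})

test_that("a unit step smears into the hand-computed 5-point ramp", {
  v <- ifelse(0:30 < 10, 20, 30)
  sm <- resample_and_smooth(vo2_trace(0:30, v))
  # centred 5 s window: ramp across t = 8..12
  expect_equal(sm$vo2[sm$time %in% 7:12],
               c(20, 20 + 10 * (1:4) / 5, 30), tolerance = 1e-12)
})

test_that("trace validation rejects non-increasing time", {
  expect_error(vo2_trace(c(0, 5, 5), c(1, 2, 3)), "strictly increasing")
  expect_error(vo2_trace(c(0, 5), c(1, -2)), "non-negative")
})

test_that("a noise-free mono-exponential is recovered by the 2-term fit", {
  tr <- simulate_vo2_trace(baseline = 10, amplitudes = 40, taus = 25,
                           delays = 5, duration = 300)
  fit <- fit_vo2_kinetics(tr, n_terms = 2)
  est <- coef(fit)
  expect_equal(est[["baseline"]], 10, tolerance = 1e-4)
  i_main <- which.max(fit$terms$amplitude)
  expect_equal(fit$terms$amplitude[i_main], 40, tolerance = 1e-4)
  expect_equal(fit$terms$tau[i_main], 25, tolerance = 1e-4)
  expect_equal(fit$terms$delay[i_main], 5, tolerance = 1e-3)
  expect_lt(fit$terms$amplitude[-i_main], 1e-3)
  # plateau is baseline plus the summed amplitudes
  expect_equal(fit$plateau, fit$baseline + sum(fit$terms$amplitude))
  expect_equal(fit$plateau, 50, tolerance = 1e-3)
})

test_that("terms come back sorted by delay with valid constraints", {
  tr <- simulate_vo2_trace(12, c(35, 8), c(20, 60), c(2, 45), 360)
  fit <- fit_vo2_kinetics(tr, n_terms = 2)
  expect_true(all(diff(fit$terms$delay) >= 0))
  expect_true(all(fit$terms$amplitude >= 0))
  expect_true(all(fit$terms$tau > 0))
})

test_that("a noisy bi-exponential recovers the primary time constant within 15%", {
  tr <- simulate_vo2_trace(12, c(35, 8), c(20, 60), c(2, 45), 360,
                           noise_sd = 1.0, seed = 13)
  fit <- fit_vo2_kinetics(resample_and_smooth(tr), n_terms = 2)
  i_main <- which.max(fit$terms$amplitude)
  expect_equal(fit$terms$tau[i_main], 20, tolerance = 0.15)
})

test_that("adding a third term never increases the weighted SSE", {
  tr <- simulate_vo2_trace(12, c(35, 8), c(20, 60), c(2, 45), 360,
                           noise_sd = 1.0, seed = 17)
  sm <- resample_and_smooth(tr)
  f2 <- fit_vo2_kinetics(sm, n_terms = 2)
  f3 <- fit_vo2_kinetics(sm, n_terms = 3)
  expect_lte(f3$weighted_sse, f2$weighted_sse * (1 + 1e-6))
  auto <- fit_vo2_kinetics(sm, n_terms = "auto")
  expect_true(auto$n_terms %in% 2:3)
})

test_that("fitting refuses traces shorter than a minute", {
  tr <- simulate_vo2_trace(10, 40, 25, 5, duration = 45)
  expect_error(fit_vo2_kinetics(tr), "60 s")
})

test_that("time to VO2max is the first grid time crossing 95%", {
  # analytic crossing of baseline 10, A = 50, tau = 30 through 0.95 * 60 = 57
  t_cross <- -30 * log(1 - 47 / 50)
  tr <- simulate_vo2_trace(10, 50, 30, 0, duration = 200)
  ta <- time_to_vo2max(tr, vo2max = 60)
  expect_equal(as.numeric(ta), ceiling(t_cross))
  expect_false(attr(ta, "secondary_criteria_required"))
})

test_that("an unattained criterion returns NA with the secondary-criteria flag", {
  tr <- simulate_vo2_trace(10, 44, 25, 0, duration = 300)  # plateaus at 90%
  ta <- time_to_vo2max(tr, vo2max = 60)
  expect_true(is.na(ta))
  expect_true(attr(ta, "secondary_criteria_required"))
})

test_that("time to VO2max is non-decreasing in the VO2max argument", {
  tr <- simulate_vo2_trace(10, 50, 30, 0, duration = 400)
  tas <- vapply(seq(40, 62, by = 2),
                function(vm) as.numeric(time_to_vo2max(tr, vm)), numeric(1))
  expect_true(all(diff(tas[!is.na(tas)]) >= 0))
})

test_that("the five maximal-test criteria are scored with inclusive bounds", {
  r <- evaluate_vo2max_criteria(age = 25, plateau_delta = 1.5, rer = 1.12,
                                peak_bla = 9.0, hr = 0.85 * 195,
                                exhaustion = TRUE)
  expect_equal(r$count, 4)
  expect_true(r$satisfied)
  # RER exactly 1.1 counts (inclusive), lactate exactly 8 does not (strict)
  r2 <- evaluate_vo2max_criteria(age = 30, rer = 1.1, peak_bla = 8)
  expect_true(r2$detail[["rer"]])
  expect_false(r2$detail[["lactate"]])
  r3 <- evaluate_vo2max_criteria(age = 30, rer = 1.2, exhaustion = TRUE)
  expect_equal(r3$count, 2)
  expect_false(r3$satisfied)
  expect_equal(r3$apmhr, 190)
})

test_that("the log-log breakpoint recovers a noise-free lactate threshold", {
  d <- simulate_lactate_curve(3.8, speeds = seq(2.8, 5.2, by = 0.3))
  lt <- lactate_threshold_loglog(d)
  expect_equal(lt$vLT, 3.8, tolerance = 0.01)
})

test_that("single-slope lactate data yield a no-threshold error", {
  d <- data.frame(speed_ms = seq(3, 5, length.out = 8))
  d$bla <- exp(0.5 + 1.2 * log(d$speed_ms))
  expect_error(lactate_threshold_loglog(d), "no lactate threshold")
  expect_error(lactate_threshold_loglog(d[1:5, ]), "at least 6")
})

test_that("a noisy seeded lactate curve recovers the threshold within 5%", {
  d <- simulate_lactate_curve(3.8, speeds = seq(2.6, 5.4, by = 0.2),
                              noise_sd = 0.05, seed = 21)
  lt <- lactate_threshold_loglog(d)
  expect_equal(lt$vLT, 3.8, tolerance = 0.05)
})

test_that("delta-50 velocity and the Vsub95 adjustment are simple averages", {
  expect_equal(v_delta50(4.0, 5.0), 4.5)
  expect_equal(vsub95_adjust(4.5, 5.0, 0.05), 4.75)
  expect_equal(vsub95_adjust(4.5, 5.0, -0.05), 4.25)
  expect_error(v_delta50(5.0, 5.0), "below")
})
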