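exact_line <- function(slope = 0.18, intercept = 0.05,
                       speeds = seq(2.5, 5, by = 0.5)) {
  data.frame(speed_ms = speeds, vo2 = intercept + slope * speeds)
}

test_that("the submax regression recovers an exact line with r^2 = 1", {
  fit <- fit_submax(exact_line())
  expect_equal(fit$slope, 0.18, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate submax input is rejected", {
  expect_error(fit_submax(exact_line()[1:2, ]), "at least 3")
  flat <- data.frame(speed_ms = rep(4, 5), vo2 = 1:5)
  expect_error(fit_submax(flat), "degenerate")
})

test_that("a noisy seeded submax line is recovered within 5%", {
  set.seed(5)
  d <- exact_line(speeds = seq(2.2, 5.4, by = 0.4))
  d$vo2 <- d$vo2 + rnorm(nrow(d), 0, 0.01)
  fit <- fit_submax(d)
  expect_equal(fit$slope, 0.18, tolerance = 0.05)
})

test_that("energy extrapolation is the regression line evaluated at speed", {
  reg <- list(slope = 0.18, intercept = 0.05)
  expect_equal(extrapolate_energy(reg, 4.16), 0.7988, tolerance = 1e-12)
  expect_equal(extrapolate_energy(reg, 0), 0.05)
  s <- 3.3  # linearity: E(2s) - E(s) = slope * s
  expect_equal(extrapolate_energy(reg, 2 * s) - extrapolate_energy(reg, s),
               0.18 * s, tolerance = 1e-12)
})

test_that("vVO2max inverts the submax regression at measured VO2max", {
  reg <- fit_submax(exact_line())
  v <- vvo2max_from_submax(reg, vo2max = 1.0)
  expect_equal(extrapolate_energy(reg, v), 1.0, tolerance = 1e-12)
})

test_that("reserve indices reproduce the published group means", {
  expect_equal(round(reri_spd(9.86, 3.64), 2), 2.71)  # sprint-trained
  expect_equal(round(reri_spd(9.07, 4.13), 2), 2.20)  # middle distance
  expect_equal(round(reri_e(2.05, 0.78), 2), 2.63)    # sprint-trained
  expect_equal(reri_spd(5, 5), 1.0)
  expect_equal(reri_e(1.2, 1.2), 1.0)
  expect_error(reri_spd(9, 0), "positive")
  expect_error(reri_e(2, -1), "positive")
})

test_that("the speed index is invariant to a common speed rescaling", {
  set.seed(31)
  for (i in 1:20) {
    mans <- runif(1, 7, 11); mas <- runif(1, 3, 5.5); k <- runif(1, 0.1, 10)
    expect_equal(reri_spd(k * mans, k * mas), reri_spd(mans, mas),
                 tolerance = 1e-12)
  }
})

test_that("a zero-intercept submax regression makes both indices identical", {
  slope <- 0.21
  mas <- 4.3; mans <- 9.2
  reg <- list(slope = slope, intercept = 0)
  expect_identical(
    reri_e(extrapolate_energy(reg, mans), extrapolate_energy(reg, mas)),
    reri_spd(mans, mas)
  )
})

test_that("athlete profiles enforce the speed ordering", {
  p <- athlete_profile(MAS = 4.13, MAnS = 9.07, E_MAS = 0.88, E_MAnS = 1.99)
  expect_equal(round(p$RERI_spd, 2), 2.20)
  expect_gt(p$RERI_E, 1)
  expect_error(athlete_profile(MAS = 5, MAnS = 4), "exceed")
})

test_that("nearest-centroid classification follows the published centroids", {
  expect_equal(classify_group(2.70), "ST")
  expect_equal(classify_group(1.80), "ET")
  expect_equal(classify_group(2.21), "MD")
  # exact midpoint ties break toward the slower group
  expect_equal(classify_group(2.455), "MD")
  expect_equal(classify_group((2.20 + 1.75) / 2), "ET")
  p <- athlete_profile(MAS = 3.64, MAnS = 9.86)
  expect_equal(classify_group(p), "ST")
  expect_error(classify_group(NA_real_), "missing")
})
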