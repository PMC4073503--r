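test_that("mass loss converts to cumulative CO2 per liter", {
  flat <- co2FromMass(c(0, 1, 2), c(500, 500, 500), volume_L = 1)
  expect_true(all(curveCO2(flat) == 0))

  cv <- co2FromMass(c(0, 10, 20), c(510, 505, 500), volume_L = 1)
  expect_equal(curveCO2(cv), c(0, 5, 10))   # 10 g lost in 1 L -> 10 g/L

  half <- co2FromMass(c(0, 10), c(510, 500), volume_L = 2)
  expect_equal(curveCO2(half)[2], 5)

  expect_error(co2FromMass(c(0, 5, 5), c(3, 2, 1), 1), "strictly increasing")
  expect_error(co2FromMass(1, 500, 1), "at least 2")
})

test_that("weighing blips are absorbed into a monotone curve", {
  tt <- c(0, 1, 2, 3)
  mass <- c(100, 99, 99.05, 98)   # +0.05 g blip at t = 2
  expect_warning(cv <- co2FromMass(tt, mass, volume_L = 1,
                                   precision_g = 0.01),
                 "clamped")
  expect_equal(curveCO2(cv), c(0, 1, 1, 2))
  # at coarser weighing precision (0.1 g) the blip is within tolerance
  expect_silent(cv2 <- co2FromMass(tt, mass, volume_L = 1,
                                   precision_g = 0.1))
  expect_equal(curveCO2(cv2), c(0, 1, 1, 2))
})

test_that("trailing-window fit recovers polynomial rates exactly", {
  tt <- seq(0, 10, by = 0.25)
  quad <- FermentationCurve(tt, 3 * tt^2)
  r <- co2Rate(quad, window_points = 10, degree = 2)
  expect_true(all(is.na(r[1:9])))
  expect_equal(r[10:length(tt)], 6 * tt[10:length(tt)], tolerance = 1e-9)

  lin <- FermentationCurve(tt, 2.5 * tt + 1)
  rl <- co2Rate(lin, window_points = 10, degree = 2)
  expect_equal(rl[-(1:9)], rep(2.5, length(tt) - 9), tolerance = 1e-9)

  expect_error(co2Rate(FermentationCurve(1:5, 1:5), window_points = 10),
               "fewer samples")
  expect_error(co2Rate(quad, window_points = 2, degree = 2), "degree")
})

test_that("rate estimation on noisy linear data matches least squares", {
  set.seed(31)
  tt <- seq(0, 20, by = 1 / 3)
  y <- tt + rnorm(length(tt), 0, 0.01)
  cv <- FermentationCurve(tt, y)
  r <- co2Rate(cv, 10, 2)
  expect_lt(abs(mean(r, na.rm = TRUE) - 1), 0.01)
  # spot-check one window against an lm() oracle
  i <- 25L
  j <- (i - 9L):i
  fit <- lm(y[j] ~ x + I(x^2), data = data.frame(x = tt[j] - tt[i]))
  expect_equal(unname(r[i]), unname(coef(fit)["x"]), tolerance = 1e-8)
})

test_that("rate is shift-invariant in time and scale-equivariant in CO2", {
  set.seed(32)
  tt <- seq(0, 15, by = 0.5)
  y <- cumsum(abs(rnorm(length(tt))))
  r0 <- co2Rate(FermentationCurve(tt, y), 10, 2)
  rShift <- co2Rate(FermentationCurve(tt + 7.3, y), 10, 2)
  rScale <- co2Rate(FermentationCurve(tt, 2 * y), 10, 2)
  expect_equal(r0, rShift, tolerance = 1e-8)
  expect_equal(2 * r0, rScale, tolerance = 1e-8)
})

test_that("checkpoint phenotype interpolates linearly", {
  cv <- FermentationCurve(c(88, 89, 90), c(10, 11, 12))
  expect_equal(phenotypeAt(cv, 89), 11)             # exact sample
  cv2 <- FermentationCurve(c(88, 90), c(10, 12))
  expect_equal(phenotypeAt(cv2, 89), 11)            # midpoint
  expect_error(phenotypeAt(cv2, 95), "outside")

  # 20-min grid from the generator: interpolation vs the analytic curve
  gen <- simulateFermentationCurve(50, duration_h = 100, step_min = 20)
  analytic <- function(t) 50 * pgamma(t, 2, scale = 20) /
    pgamma(89, 2, scale = 20)
  expect_equal(phenotypeAt(gen, 89), 50)
  expect_lt(abs(phenotypeAt(gen, 89.1) - analytic(89.1)), 1e-3)
})
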