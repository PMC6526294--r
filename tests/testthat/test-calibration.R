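test_that("dilution planning matches the bench series and conserves mass", {
  plan <- plan_standard_dilutions(c(5, 7.5, 10, 15, 20, 30), 2500, 25000)
  expect_equal(plan$stock_uL, c(50, 75, 100, 150, 200, 300))
  expect_equal(plan$water_uL, c(24950, 24925, 24900, 24850, 24800, 24700))
  # mass balance on the unrounded volumes
  expect_equal(plan$stock_uL_exact * 2500, plan$target_mg_L * plan$total_uL)

  zero <- plan_standard_dilutions(0, 2500, 25000)
  expect_equal(zero$stock_uL, 0)
  expect_equal(zero$water_uL, 25000)

  expect_error(plan_standard_dilutions(3000, 2500, 25000), "infeasible")
  expect_error(plan_standard_dilutions(-1, 2500, 25000))
})

test_that("dilution mass balance holds for arbitrary feasible targets", {
  set.seed(11)
  for (i in 1:50) {
    stock <- runif(1, 100, 5000)
    total <- runif(1, 1000, 50000)
    targets <- runif(4, 0, stock * 0.9)
    plan <- plan_standard_dilutions(targets, stock, total)
    expect_equal(plan$stock_uL_exact * stock, targets * total)
    expect_true(all(plan$stock_uL >= 0 & plan$water_uL >= 0))
    expect_true(all(abs(plan$stock_uL - plan$stock_uL_exact) <= 0.5))
  }
})

test_that("plasma mixing is the volume-weighted dilution", {
  m <- mix_with_plasma(c(5, 7.5, 10, 15, 20, 30), 200, 200)
  expect_equal(m$final_mg_L, c(2.5, 3.75, 5, 7.5, 10, 15))
  # no-dilution identity
  expect_equal(mix_with_plasma(12.3, 150, 0)$final_mg_L, 12.3)
  # final conc never exceeds the premix
  set.seed(12)
  for (i in 1:20) {
    m <- mix_with_plasma(runif(1, 1, 30), runif(1, 1, 400), runif(1, 0, 400))
    expect_lte(m$final_mg_L, m$premix_mg_L)
  }
  expect_error(mix_with_plasma(5, -1, 200), "volumes")
  expect_error(mix_with_plasma(5, 0, 0), "both")
})

test_that("well averaging gives the mean and n-1 CV", {
  a <- average_wells(c(0.10, 0.10, 0.10))
  expect_equal(a$mean, 0.10)
  expect_equal(a$cv_pct, 0)
  b <- average_wells(c(0.09, 0.10, 0.11))
  expect_equal(b$mean, 0.10)
  expect_equal(b$cv_pct, 10.0)
  expect_true(is.na(average_wells(0.2)$cv_pct))
  expect_error(average_wells(numeric(0)), "empty")
  expect_error(average_wells(c(0.1, NA)))
})

test_that("calibration fit recovers a noise-free line and matches the OLS oracle", {
  conc <- c(2.5, 3.75, 5, 7.5, 10)
  cal <- fit_calibration(conc, 0.04 * conc + 0.05)
  expect_equal(cal$slope, 0.04, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cal$r, 1)
  expect_equal(cal$n_points, 5)
  expect_equal(cal$valid_range, c(0, 15))

  # symmetric perturbation, frozen oracle values from the normal equations
  y <- 0.04 * conc + 0.05 + c(0.002, -0.002, 0, 0.002, -0.002)
  cal2 <- fit_calibration(conc, y)
  expect_equal(cal2$slope, 0.039793103448275816, tolerance = 1e-10)
  expect_equal(cal2$intercept, 0.05118965517241407, tolerance = 1e-10)
  expect_equal(cal2$r, 0.9998741710940797, tolerance = 1e-10)

  expect_error(fit_calibration(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_calibration(c(5, 5, 5), c(0.1, 0.2, 0.3)), "singular")
  expect_error(fit_calibration(c(1, 2, 20), c(0.1, 0.2, 0.9)), "0, 15")
})

test_that("calibration OLS equals the normal-equation oracle on random inputs", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    conc <- sort(runif(n, 0, 15))
    if (sd(conc) == 0) next
    y <- runif(1, 0.01, 0.1) * conc + runif(1, 0, 0.2) + rnorm(n, 0, 0.01)
    cal <- fit_calibration(conc, y)
    o <- ols_oracle(conc, y)
    expect_equal(cal$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(cal$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("absorbance inversion is exact, clamped, and monotone", {
  conc <- c(2.5, 5, 10)
  cal <- fit_calibration(conc, 0.04 * conc + 0.05)
  expect_equal(as.numeric(invert_absorbance(cal, 0.25)), 5)
  expect_equal(as.numeric(invert_absorbance(cal, cal$intercept)), 0)

  # round trip over the valid range
  cc <- seq(0, 15, by = 0.5)
  back <- as.numeric(invert_absorbance(cal, predict(cal, cc)))
  expect_equal(back, cc, tolerance = 1e-9)

  # above-range and clamping flags
  expect_warning(hi <- invert_absorbance(cal, 0.8), "above the linear range")
  expect_true(attr(hi, "flags")$above_range)
  expect_warning(lo <- invert_absorbance(cal, 0.01), "clamped")
  expect_equal(as.numeric(lo), 0)

  # strictly increasing in absorbance
  a <- seq(0.06, 0.6, by = 0.01)
  v <- as.numeric(suppressWarnings(invert_absorbance(cal, a)))
  expect_true(all(diff(v) > 0))

  bad <- cal
  bad$slope <- -0.01
  expect_error(invert_absorbance(bad, 0.2), "slope")
})
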