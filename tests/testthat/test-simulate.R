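test_that("participant simulation is deterministic and respects bounds", {
  a <- simulate_participant(seed = 101)
  b <- simulate_participant(seed = 101)
  expect_identical(a, b)

  set.seed(102)
  draws <- replicate(500, {
    p <- simulate_participant()
    c(p$record$weight_kg, p$record$height_cm, p$truth$true_k_per_min,
      p$truth$true_pv_L)
  })
  expect_true(all(draws[1, ] >= 45 & draws[1, ] <= 100))
  expect_true(all(draws[2, ] >= 145 & draws[2, ] <= 185))
  expect_true(all(draws[3, ] >= 0.10 & draws[3, ] <= 0.45))
  expect_true(all(draws[4, ] >= 1.0 & draws[4, ] <= 3.5))
  # sample mean weight within 3 SE of the target distribution mean
  expect_lt(abs(mean(draws[1, ]) - 63.8), 3 * 7.4 / sqrt(500))
  # dose follows 0.25 mg/kg and the syringe weights encode it
  p <- simulate_participant(seed = 103)
  expect_equal(p$truth$dose_mg, 0.25 * p$record$weight_kg)
  expect_equal((p$record$syringe_pre_g - p$record$syringe_post_g) * 2.5,
               p$truth$dose_mg)
})

test_that("ground-truth concentration has the stated kinetic form", {
  p <- simulate_participant(seed = 104, mixing_tau_s = 0)
  tr <- p$truth
  # instantaneous mixing: C(0) = dose / PV exactly
  expect_equal(simulate_concentration(tr, 0),
               tr$dose_mg / tr$true_pv_L, tolerance = 1e-12)
  # pure mono-exponential at all times
  t_s <- c(0, 60, 120, 300)
  expect_equal(simulate_concentration(tr, t_s),
               tr$dose_mg / tr$true_pv_L * exp(-tr$true_k_per_min * t_s / 60),
               tolerance = 1e-12)

  p2 <- simulate_participant(seed = 105, mixing_tau_s = 30)
  tr2 <- p2$truth
  tt <- seq(0, 600, by = 1)
  cc <- simulate_concentration(tr2, tt)
  # bounded by the well-mixed concentration
  expect_true(all(cc <= tr2$dose_mg / tr2$true_pv_L + 1e-12))
  # strictly decreasing beyond 5 mixing time constants
  late <- cc[tt > 5 * tr2$mixing_tau_s]
  expect_true(all(diff(late) < 0))
})

test_that("plate simulation encodes the calibration response and round-trips", {
  p <- noise_free_participant(seed = 106)
  plate <- simulate_plate(p$truth, seed = 107)
  expect_identical(names(plate), c("well", "label", "role",
                                   "nominal_conc_mg_L", "draw_time_s",
                                   "absorbance"))
  # triplicates throughout; 1 blank + 5 standards + 5 samples
  expect_equal(nrow(plate), 3 * 11)
  std <- plate[plate$role == "standard", ]
  expect_equal(std$absorbance,
               p$truth$cal_slope_true * std$nominal_conc_mg_L +
                 p$truth$cal_intercept_true,
               tolerance = 1e-12)
  # CSV round trip through the reader is lossless
  f <- tempfile(fileext = ".csv")
  write.csv(plate, f, row.names = FALSE, na = "")
  back <- read_plate_csv(f)
  expect_equal(back$absorbance, plate$absorbance)
  expect_equal(back$draw_time_s, plate$draw_time_s)
  unlink(f)
})

test_that("noise-free pipeline recovers truth end to end", {
  p <- noise_free_participant(seed = 108)
  plate <- simulate_plate(p$truth, seed = 109)
  fit <- pv_from_plate(plate, p$truth$dose_mg, p$record$weight_kg,
                       p$record$height_cm)
  expect_equal(fit$pv$pv_t0_L, p$truth$true_pv_L, tolerance = 1e-6)
  expect_equal(fit$pv$k_per_min, p$truth$true_k_per_min, tolerance = 1e-6)
  expect_equal(fit$decay$c0_t0,
               p$truth$dose_mg / p$truth$true_pv_L, tolerance = 1e-6)
  expect_equal(fit$calibration$curve$r, 1, tolerance = 1e-9)
})

test_that("same seed writes byte-identical study directories", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_study(d1, n = 3, seed = 77)
  simulate_study(d2, n = 3, seed = 77)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- file.path(tempdir(), "study_c")
  unlink(d3, recursive = TRUE)
  simulate_study(d3, n = 3, seed = 78)
  expect_false(identical(readLines(file.path(d1, "participants.csv")),
                         readLines(file.path(d3, "participants.csv"))))
  # truth.json covers every ground-truth field
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_identical(
    sort(names(truth[[1]])),
    sort(c("id", "true_pv_L", "true_k_per_min", "mixing_tau_s", "dose_mg",
           "cal_slope_true", "cal_intercept_true", "absorbance_noise_sd",
           "timing_jitter_sd")))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
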