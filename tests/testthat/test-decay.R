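test_that("decay fit recovers exact mono-exponential samples", {
  s <- exact_decay_samples(c0 = 8, k = 0.25)
  fit <- fit_decay(s$t_s, s$conc)
  expect_equal(fit$k_per_min, 0.25, tolerance = 1e-12)
  expect_equal(fit$c0_t0, 8, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  expect_equal(fit$half_life_min, 2.772588722239781, tolerance = 1e-12)
  expect_equal(fit$c_t60, 6.230406264571239, tolerance = 1e-12)
  expect_equal(fit$pdr_pct_per_min, 25, tolerance = 1e-12)
  expect_equal(fit$n_points, 5)
  # residuals vanish for noise-free input
  expect_equal(residuals(fit), rep(0, 5), tolerance = 1e-12)
})

test_that("noise-free recovery holds across the physiologic k range", {
  set.seed(21)
  for (i in 1:30) {
    k <- runif(1, 0.05, 1.0)
    c0 <- runif(1, 2, 20)
    t_s <- sort(120 + sample(0:180, 4))
    s <- exact_decay_samples(c0 = c0, k = k, t_s = t_s)
    fit <- fit_decay(s$t_s, s$conc)
    expect_equal(fit$k_per_min, k, tolerance = 1e-10)
    expect_equal(fit$c0_t0, c0, tolerance = 1e-10)
    # invariant: half-life times k is ln 2 exactly
    expect_equal(fit$half_life_min * fit$k_per_min, log(2))
  }
})

test_that("fit is permutation-invariant and unit-consistent", {
  s <- exact_decay_samples(c0 = 6, k = 0.31,
                           t_s = c(123, 168, 201, 262, 299))
  conc <- s$conc + c(0.05, -0.03, 0.02, -0.01, 0.04)  # mild noise
  fit1 <- fit_decay(s$t_s, conc)
  ord <- c(4, 1, 5, 2, 3)
  fit2 <- fit_decay(s$t_s[ord], conc[ord])
  expect_equal(fit1$k_per_min, fit2$k_per_min)
  expect_equal(fit1$c0_t0, fit2$c0_t0)
  expect_equal(fit1$r, fit2$r)

  # fitting in minutes gives a slope exactly 60x the per-second slope
  fit_min <- lm(log(conc) ~ I(s$t_s / 60))
  expect_equal(unname(coef(fit_min)[2]), fit1$slope_per_s * 60,
               tolerance = 1e-12)
})

test_that("extrapolation evaluates the fitted line at any time", {
  s <- exact_decay_samples()
  fit <- fit_decay(s$t_s, s$conc)
  expect_equal(extrapolate_concentration(fit, 0), 8, tolerance = 1e-12)
  expect_equal(extrapolate_concentration(fit, 60), 6.230406264571239,
               tolerance = 1e-12)
  # predictions at sample times reproduce noise-free observations
  expect_equal(predict(fit, s$t_s), s$conc, tolerance = 1e-12)
  expect_equal(predict(fit), s$conc, tolerance = 1e-12)
})

test_that("decay fit validates its inputs", {
  expect_error(fit_decay(c(120, 200), c(5, 4)), "at least 3")
  expect_error(fit_decay(c(120, 200, 200), c(5, 4, 4)), "distinct")
  expect_error(fit_decay(c(120, 200, 280), c(5, 0, 4)), "onpositive")
  expect_warning(fit_decay(c(120, 200, 280), c(4, 5, 6)), "nonphysiologic")
  # window filtering drops out-of-window samples
  expect_message(
    fit <- fit_decay(c(60, 120, 200, 280), c(9, 8, 6, 4.5)),
    "outside"
  )
  expect_equal(fit$n_points, 3)
  # window = NULL keeps everything
  fit_all <- fit_decay(c(60, 120, 200, 280), c(9, 8, 6, 4.5), window = NULL)
  expect_equal(fit_all$n_points, 4)
})

test_that("clearance is k times PV with input validation", {
  expect_equal(clearance(0.25, 1608), 402)
  expect_equal(clearance(0.30, 2000), 600)
  expect_equal(clearance(0.2, 0), 0)
  expect_error(clearance(0, 1500), "positive")
  expect_error(clearance(0.25, -1))
})
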