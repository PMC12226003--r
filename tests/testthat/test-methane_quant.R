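test_that("calibration recovers exact linear curves and inverts them", {
  std <- c(2.02, 4.99, 10.1, 100, 1000)
  cal <- fit_calibration(std, 2 * std)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$ppm(2 * std), std)      # inverse consistency

  expect_error(fit_calibration(c(5, 5), c(1, 2)), "distinct standards")
  expect_error(fit_calibration(std, rep(7, 5)), "non-physical")
  expect_error(fit_calibration(std, rev(2 * std)), "non-physical")
})

test_that("calibration slope recovery on noisy data stays within 3 standard errors", {
  set.seed(77)
  std <- c(2.02, 4.99, 10.1, 100, 1000)
  for (i in 1:20) {
    true_slope <- runif(1, 0.5, 5)
    areas <- true_slope * std + 3 + rnorm(5, 0, true_slope)
    cal <- fit_calibration(std, areas)
    fit <- lm(areas ~ std)
    se <- summary(fit)$coefficients["std", "Std. Error"]
    expect_lt(abs(cal$slope - true_slope), 3 * se + 1e-12)
  }
})

test_that("Bunsen coefficient matches the tabulated 25 C value and is monotone", {
  expect_equal(bunsen_coefficient(298.15, 0), 0.0315, tolerance = 0.02)
  # gas solubility falls with temperature and with salinity
  expect_lt(bunsen_coefficient(303.15, 0), bunsen_coefficient(298.15, 0))
  expect_lt(bunsen_coefficient(298.15, 35), bunsen_coefficient(298.15, 0))
  tgrid <- seq(273.15, 313, length.out = 25)
  expect_true(all(diff(bunsen_coefficient(tgrid, 0)) < 0))
  expect_true(all(diff(bunsen_coefficient(tgrid, 35)) < 0))
  sgrid <- seq(0, 40, length.out = 25)
  expect_true(all(diff(bunsen_coefficient(290, sgrid)) < 0))
  expect_error(bunsen_coefficient(250, 0), "range")
  expect_error(bunsen_coefficient(298.15, 60), "range")
})

test_that("headspace partition reconstructs the bottle inventory", {
  g <- bottle_geometry()
  zero <- headspace_partition(0, g)
  expect_equal(zero$total_nmol, 0)
  expect_equal(zero$dissolved_umol_L, 0)

  p <- headspace_partition(100, g)
  expect_equal(p$headspace_nmol, 422, tolerance = 0.01)
  expect_equal(p$dissolved_umol_L, 0.13, tolerance = 0.01)
  expect_equal(p$total_nmol, 425, tolerance = 0.01)
  # internal consistency of the GasSample fields
  expect_equal(p$total_nmol,
               p$headspace_nmol + p$dissolved_umol_L * g$V_liq * 1000,
               tolerance = 1e-9)
  expect_equal(p$conc_umol_L, p$total_nmol / g$V_liq / 1000, tolerance = 1e-12)

  # linearity: doubling the mixing ratio doubles every amount
  p2 <- headspace_partition(200, g)
  expect_equal(p2$total_nmol, 2 * p$total_nmol, tolerance = 1e-12)
  expect_equal(p2$headspace_nmol, 2 * p$headspace_nmol, tolerance = 1e-12)
  expect_error(headspace_partition(-1, g), "negative")
})

test_that("mixing-ratio reconstruction is exact over a grid (mass conservation)", {
  g <- bottle_geometry()
  ppm <- c(0.01, 0.5, 2.02, 37, 113.7, 1000)
  p <- headspace_partition(ppm, g)
  expect_equal(mixing_ratio_from_total(p$total_nmol, g), ppm,
               tolerance = 1e-9)
  g2 <- bottle_geometry(V_liq = 0.05, V_head = 0.07, temperature = 293.15,
                        salinity = 20)
  p2 <- headspace_partition(ppm, g2)
  expect_equal(mixing_ratio_from_total(p2$total_nmol, g2), ppm,
               tolerance = 1e-9)
  expect_error(bottle_geometry(V_liq = 0.1, V_head = 0.1), "bottle volume")
})

test_that("production rate recovers planted slopes and handles degenerate input", {
  t <- seq(0, 288, by = 12)
  r <- production_rate(t, 92 * t, window = c(0, 288))
  expect_equal(r$rate, 92, tolerance = 1e-9)

  flat <- production_rate(t, rep(500, length(t)))
  expect_equal(flat$rate, 0, tolerance = 1e-12)

  ep <- production_rate(t, 92 * t, method = "endpoint")
  expect_equal(ep$rate, 92, tolerance = 1e-12)

  expect_error(production_rate(c(0), c(1)), "2 distinct timepoints")
  expect_error(production_rate(c(0, 10), c(1, 2), window = c(5, 5)),
               "exceed")
})

test_that("rate estimation is invariant to time-unit rescaling", {
  set.seed(8)
  t <- seq(0, 288, by = 24)
  y <- 92 * t + rnorm(length(t), 0, 50)
  r_h <- production_rate(t, y)$rate
  r_d <- production_rate(t / 24, y)$rate   # days
  expect_equal(r_d / 24, r_h, tolerance = 1e-9)
})

test_that("stoichiometry reproduces the endpoint mass-balance ratio", {
  # endpoint deltas of 25.5 uM CH4 produced per 25.7 uM DOP consumed
  time <- c(0, 288)
  ch4 <- c(0, 25.5)
  tdp <- c(200 + 0.1, 200 - 25.7 + 0.1)   # DOP + constant DIP
  dip <- c(0.1, 0.1)
  st <- stoichiometric_series(time, ch4, tdp, dip)
  expect_equal(st$delta_ch4, 25.5)
  expect_equal(st$delta_dop, 25.7)
  expect_equal(st$ratio, 25.5 / 25.7, tolerance = 1e-12)
  expect_equal(round(st$ratio, 3), 0.992)
})

test_that("stoichiometry guards the ratio floor and flags negative DOP", {
  st <- stoichiometric_series(c(0, 10), c(0, 1), c(5, 5), c(1, 1))
  expect_true(is.na(st$ratio))             # dDOP = 0 -> undefined, no error

  expect_warning(
    neg <- stoichiometric_series(c(0, 10), c(0, 1), c(1, 1), c(2, 2)),
    "negative DOP")
  expect_true(neg$negative_dop_flag)

  expect_error(stoichiometric_series(c(0, 1), c(0, 1, 2), c(1, 1), c(0, 0)),
               "aligned")
})

test_that("dose-response trend detects planted Pi inhibition direction", {
  perfect <- list(`0` = c(24, 25), `5` = c(20, 19), `10` = c(15, 16),
                  `20` = c(10, 11), `30` = c(7, 6), `40` = c(4, 5))
  d <- dose_response_trend(perfect)
  expect_equal(d$spearman_rho, -1)
  expect_true(d$monotone_decreasing)

  flat <- list(`0` = c(5, 5), `10` = c(5, 5), `20` = c(5, 5))
  f <- dose_response_trend(flat)
  expect_equal(f$spearman_rho, 0)
  expect_false(f$monotone_decreasing)

  expect_error(dose_response_trend(list(`0` = 1, `5` = 2)), "3 Pi levels")

  # seeded generator truth
  tab <- simulate_incubation(incubation_sim_spec(seed = 31))
  res <- run_incubation_pipeline(tab)
  expect_lt(res$dose_response$spearman_rho, 0)
})

test_that("repression test flags separation, spares identity, survives zero variance", {
  sig <- repression_test(c(10, 10, 10), c(1, 1, 1.0001))
  expect_true(sig$significant)
  expect_lt(sig$p_value, 0.05)

  same <- repression_test(c(5, 6, 7), c(5, 6, 7))
  expect_false(same$significant)

  degen_eq <- repression_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(degen_eq$p_value, 1)
  expect_false(degen_eq$significant)

  degen_diff <- repression_test(c(3, 3), c(1, 1))
  expect_equal(degen_diff$p_value, 0)
  expect_true(degen_diff$significant)

  expect_error(repression_test(1, c(1, 2)), "at least 2")
})
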