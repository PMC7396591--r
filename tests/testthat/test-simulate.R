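test_that("parameter validation catches impossible configurations", {
  expect_error(fermentation_sim_params(0.2, 3, 4, 0.5, 0.9, 0, 0.9, 10,
                                       seed = 1), "x0 must be < x_max")
  expect_error(fermentation_sim_params(0.2, 3, 0.1, 0.5, 0.9, 0, s0 = 10,
                                       seed = 1), "y_ps")
  expect_error(phb_flask_params(), "seed")
  expect_error(phb_flask_params(seed = 1, yield = 0.95), "below y_ps")
  expect_error(panel_sim_params(data.frame(metabolite = "m", strain = "A",
                                           stage = "D1", mean = 1)),
               "seed")
})

test_that("a fixed seed reproduces bit-identical output", {
  p <- phb_flask_params(seed = 11, noise_sd = 0.1)
  t1 <- simulate_fermentation(p, seq(0, 54, by = 6))
  t2 <- simulate_fermentation(p, seq(0, 54, by = 6))
  expect_identical(t1, t2)
  pp <- panel_sim_params(means = data.frame(metabolite = "m", strain = "A",
                                            stage = "D1", mean = 5),
                         cv = 0.2, seed = 9)
  expect_identical(simulate_panel(pp), simulate_panel(pp))
})

test_that("noise-free simulations reproduce the configured true yield", {
  p <- phb_flask_params(seed = 5, yield = 0.32)
  ts <- simulate_fermentation(p, seq(0, 54, by = 3))
  y <- fermentation_summary(ts, "ethanol")$yield_g_per_g
  expect_equal(y, 0.32, tolerance = 1e-9)
})

test_that("the integrator respects mass balance and the logistic solution", {
  p <- fermentation_sim_params(mu_max = 0.25, x_max = 3, x0 = 0.05,
                               y_xs = 0.5, alpha = 0.8, beta = 0.01,
                               y_ps = 0.9, s0 = 20, noise_sd = 0, seed = 2)
  ts <- simulate_fermentation(p, seq(0, 40, by = 2))
  X <- ts$cdw_g_per_L - ts$product_g_per_L   # catalytic biomass
  dS <- ts$ethanol_g_per_L[1] - ts$ethanol_g_per_L
  dX <- X - X[1]
  dP <- ts$product_g_per_L - ts$product_g_per_L[1]
  expect_equal(dS, dX / p$y_xs + dP / p$y_ps, tolerance = 1e-6)

  # with beta = 0 the biomass path is exactly logistic
  p0 <- fermentation_sim_params(mu_max = 0.25, x_max = 3, x0 = 0.05,
                                y_xs = 0.5, alpha = 0.8, beta = 0,
                                y_ps = 0.9, s0 = 20, noise_sd = 0, seed = 2)
  ts0 <- simulate_fermentation(p0, seq(0, 40, by = 2))
  X0 <- ts0$cdw_g_per_L - ts0$product_g_per_L
  t <- ts0$time_h
  closed <- 3 * 0.05 * exp(0.25 * t) / (3 - 0.05 + 0.05 * exp(0.25 * t))
  expect_equal(X0, closed, tolerance = 1e-6)
})

test_that("feeds are instantaneous and exhaustion halts the culture", {
  p <- fermentation_sim_params(mu_max = 0.5, x_max = 10, x0 = 0.2,
                               y_xs = 0.4, alpha = 0.5, beta = 0,
                               y_ps = 0.9, s0 = 1,
                               feeds = data.frame(time = 20, amount = 5),
                               noise_sd = 0, seed = 3)
  ts <- simulate_fermentation(p, seq(0, 40, by = 1))
  # substrate runs out well before the feed; biomass plateaus
  pre <- ts[ts$time_h >= 10 & ts$time_h <= 20, ]
  expect_true(all(pre$ethanol_g_per_L < 1e-6))
  expect_equal(diff(range(pre$cdw_g_per_L)), 0, tolerance = 1e-8)
  # growth resumes after the feed
  expect_gt(ts$cdw_g_per_L[ts$time_h == 30], pre$cdw_g_per_L[1] + 0.5)
  expect_equal(ts$fed_g_per_L[ts$time_h == 40], 5)
  # consumption accounting uses the cumulative fed column
  expect_equal(substrate_consumed(ts, "ethanol"),
               1 - ts$ethanol_g_per_L[nrow(ts)] + 5, tolerance = 1e-6)
})

test_that("simulated outputs survive the CSV round trip", {
  ts <- simulate_fermentation(phb_flask_params(seed = 8, noise_sd = 0.05),
                              seq(0, 54, by = 6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(ts, f)
  expect_equal(as.data.frame(read_timecourse(f)), as.data.frame(ts),
               tolerance = 1e-9)

  p <- panel_sim_params(
    means = data.frame(metabolite = c("lac", "lac"), strain = c("A", "B"),
                       stage = "D1", mean = c(229.22, 1)),
    cv = 0, seed = 4,
    undetectable = data.frame(metabolite = "lac", strain = "B",
                              stage = "D2"))
  pan <- simulate_panel(p)
  expect_equal(fold_change(pan, "lac", c("A", "D1"), c("B", "D1"))$ratio,
               229.22, tolerance = 1e-12)
})
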