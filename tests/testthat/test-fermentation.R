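make_ts <- function(...) fermentation_timecourse(data.frame(...))

test_that("time-course validation rejects malformed tables", {
  expect_s3_class(make_ts(time_h = c(0, 24), ethanol_g_per_L = c(10, 5)),
                  "fermentation_timecourse")
  expect_error(make_ts(time_h = c(24, 0), ethanol_g_per_L = c(5, 10)),
               "strictly increasing")
  expect_error(make_ts(time_h = c(0, 24), ethanol_g_per_L = c(10, -1)),
               "negative")
  expect_error(make_ts(time_h = 0, ethanol_g_per_L = 10), "at least 2")
  expect_error(fermentation_timecourse(data.frame(time_h = c(0, 1))),
               "concentration column")
  expect_error(fermentation_timecourse(data.frame(x = 1:2)), "time_h")
})

test_that("the CSV reader validates on the way in", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,ethanol_g_per_L,product_g_per_L",
               "0,10,0", "54,0.32,3.12"), f)
  ts <- read_timecourse(f)
  expect_equal(nrow(ts), 2)
  writeLines(c("time_h,ethanol_g_per_L", "54,1", "0,10"), f)
  expect_error(read_timecourse(f), "strictly increasing")
  writeLines(c("time_h,ethanol_g_per_L", "0,10", "54,-2"), f)
  expect_error(read_timecourse(f), "negative")
})

test_that("substrate consumption handles batch, fed-batch and clamping", {
  ts <- make_ts(time_h = c(0, 24, 54), ethanol_g_per_L = c(10, 4.2, 0.32))
  expect_equal(substrate_consumed(ts, "ethanol"), 9.68)
  expect_equal(substrate_consumed(ts, "ethanol", 0, 24) +
                 substrate_consumed(ts, "ethanol", 24, 54),
               substrate_consumed(ts, "ethanol", 0, 54))
  # constant concentration, no feed
  flat <- make_ts(time_h = c(0, 10), ethanol_g_per_L = c(5, 5))
  expect_equal(substrate_consumed(flat, "ethanol"), 0)
  # fed-batch bookkeeping via the cumulative fed column
  fb <- make_ts(time_h = c(0, 115), ethanol_g_per_L = c(1, 0),
                fed_g_per_L = c(0, 129.5))
  expect_equal(substrate_consumed(fb, "ethanol"), 130.5)
  # apparent negative consumption clamps to zero with a warning
  up <- make_ts(time_h = c(0, 10), ethanol_g_per_L = c(5, 5.4))
  expect_warning(v <- substrate_consumed(up, "ethanol"), "clamped")
  expect_equal(v, 0)
  # guards
  expect_error(substrate_consumed(ts, "glucose"), "unknown substrate")
  expect_error(substrate_consumed(ts, "ethanol", 0, 60), "outside")
  expect_error(substrate_consumed(ts, "ethanol", 0, 30), "not a sampled")
})

test_that("yield, content and percent-of-theoretical arithmetic", {
  expect_equal(signif(product_yield(3.12, 9.68), 2), 0.32)
  expect_equal(signif(product_yield(35.67, 130.5), 3), 0.273)
  expect_equal(product_yield(0, 5), 0)
  expect_error(product_yield(1, 0), "> 0")
  # p/s * s recovers p to machine precision
  for (p in c(0.3, 3.12, 35.67)) for (s in c(9.68, 130.5))
    expect_equal(product_yield(p, s) * s, p, tolerance = 1e-15)

  expect_equal(phb_content(3.12, 3.12 / 0.487), 48.7, tolerance = 1e-12)
  expect_equal(phb_content(2.5, 2.5), 100)
  expect_equal(phb_content(0, 4), 0)
  expect_error(phb_content(1, 0), "> 0")

  expect_equal(round(percent_of_theoretical(0.32, 0.935)), 34)
  expect_equal(percent_of_theoretical(0.935, 0.935), 100)
  expect_equal(percent_of_theoretical(0, 0.935), 0)
  expect_error(percent_of_theoretical(0.3, 0), "> 0")
})

test_that("the summary wrapper ties the pieces together", {
  ts <- make_ts(time_h = c(0, 54), ethanol_g_per_L = c(10, 0.32),
                product_g_per_L = c(0, 3.12), cdw_g_per_L = c(0.05, 6.406))
  s <- fermentation_summary(ts, "ethanol", theoretical = 0.935)
  expect_equal(s$consumed_g_per_L, 9.68)
  expect_equal(signif(s$yield_g_per_g, 2), 0.32)
  expect_equal(s$content_pct_cdw, 100 * 3.12 / 6.406, tolerance = 1e-12)
  expect_equal(round(s$pct_of_theoretical), 34)
})
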