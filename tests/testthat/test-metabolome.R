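panel_of <- function(...) metabolite_panel(data.frame(...))

seven <- function(metab, strain, stage, values) {
  data.frame(metabolite = metab, strain = strain, stage = stage,
             replicate = seq_along(values), intensity = values)
}

test_that("cell summaries: mean, SEM, undetectable flag", {
  pan <- metabolite_panel(rbind(
    seven("pyr", "A", "D1", 1:7),
    seven("pyr", "B", "D1", rep(3.5, 7)),
    seven("nadh", "A", "D1", rep(NA_real_, 7))))
  s <- summarize_cell(pan, "pyr", "A", "D1")
  expect_equal(s$mean, 4)
  expect_equal(s$sem, sqrt(28 / 6) / sqrt(7), tolerance = 1e-12)
  expect_equal(s$n, 7L)
  s2 <- summarize_cell(pan, "pyr", "B", "D1")
  expect_equal(s2$sem, 0)
  expect_true(summarize_cell(pan, "nadh", "A", "D1")$undetectable)
  expect_error(summarize_cell(pan, "pyr", "C", "D1"), "no such cell")
})

test_that("fold change is the ratio of cell means with propagated CI", {
  pan <- metabolite_panel(rbind(
    seven("lac", "A", "D1", c(10, 11, 9, 10.5, 9.5, 10, 10)),
    seven("lac", "B", "D1", c(10, 11, 9, 10.5, 9.5, 10, 10)),
    seven("acc", "A", "D1", rep(2, 7)),
    seven("acc", "B", "D1", rep(NA_real_, 7))))
  fc <- fold_change(pan, "lac", c("A", "D1"), c("B", "D1"))
  expect_equal(fc$ratio, 1)
  expect_true(fc$ci_lower <= 1 && fc$ci_upper >= 1)
  # reciprocal pairs multiply to one
  ab <- fold_change(pan, "lac", c("A", "D1"), c("B", "D1"))
  ba <- fold_change(pan, "lac", c("B", "D1"), c("A", "D1"))
  expect_equal(ab$ratio * ba$ratio, 1, tolerance = 1e-12)
  # undetectable denominator -> undefined, no ratio
  und <- fold_change(pan, "acc", c("A", "D1"), c("B", "D1"))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
})

test_that("a known true ratio is recovered from noisy replicates", {
  p <- panel_sim_params(
    means = data.frame(metabolite = "lac", strain = c("A", "B"), stage = "D1",
                       mean = c(10, 1)),
    cv = 0.1, n_reps = 7, seed = 424)
  pan <- simulate_panel(p)
  fc <- fold_change(pan, "lac", c("A", "D1"), c("B", "D1"))
  expect_gt(fc$ratio, 8)
  expect_lt(fc$ratio, 12.5)
})

test_that("ratios are scale-equivariant per batch, invariant globally", {
  base <- rbind(seven("lac", "A", "D1", c(8, 9, 10, 11, 12, 10, 10)),
                seven("lac", "B", "D1", c(1, 1.2, 0.8, 1.1, 0.9, 1, 1)))
  pan <- metabolite_panel(base)
  r0 <- fold_change(pan, "lac", c("A", "D1"), c("B", "D1"))$ratio
  scaled <- base
  scaled$intensity[scaled$strain == "A"] <-
    scaled$intensity[scaled$strain == "A"] * 3
  expect_equal(fold_change(metabolite_panel(scaled), "lac",
                           c("A", "D1"), c("B", "D1"))$ratio,
               3 * r0, tolerance = 1e-12)
  global <- base
  global$intensity <- global$intensity * 7.5
  expect_equal(fold_change(metabolite_panel(global), "lac",
                           c("A", "D1"), c("B", "D1"))$ratio,
               r0, tolerance = 1e-12)
})

test_that("stage reports cover shared metabolites in alphabetical order", {
  pan <- metabolite_panel(rbind(
    seven("zeta", "A", "D1", rep(2, 7)), seven("zeta", "B", "D1", rep(2, 7)),
    seven("alpha", "A", "D1", rep(5, 7)), seven("alpha", "B", "D1", rep(5, 7))))
  rep1 <- stage_report(pan, "A", "B", "D1")
  expect_equal(rep1$metabolite, c("alpha", "zeta"))
  expect_equal(rep1$ratio, c(1, 1))
  one <- metabolite_panel(rbind(seven("only", "A", "D1", rep(1, 7)),
                                seven("only", "B", "D1", rep(2, 7))))
  expect_equal(nrow(stage_report(one, "A", "B", "D1")), 1)
  disj <- metabolite_panel(rbind(seven("m1", "A", "D1", rep(1, 7)),
                                 seven("m2", "B", "D1", rep(1, 7))))
  expect_error(stage_report(disj, "A", "B", "D1"), "no shared")
})

test_that("panel CSV round trip preserves values and ND markers", {
  pan <- metabolite_panel(rbind(seven("lac", "A", "D1", c(1.25, 2.5, NA)),
                                seven("lac", "B", "D1", rep(NA_real_, 3))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, f)
  expect_true(any(grepl("ND", readLines(f))))
  back <- read_panel(f)
  expect_equal(as.data.frame(back), as.data.frame(pan), tolerance = 1e-12)
})
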