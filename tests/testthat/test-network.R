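test_that("balance checking validates conversions and exempts exchanges", {
  net <- builtin_network("glucose", "phb")
  rep_pdh <- check_balance("PDH", net)
  expect_true(rep_pdh$pass)
  expect_identical(rep_pdh$element_imbalance[["C"]], 0)
  expect_identical(rep_pdh$electron_imbalance, 0)

  # deleting the CO2 term forces a one-carbon imbalance
  broken <- reaction("PDH_broken", c(pyr = -1, coa = -1, accoa = 1, nadh = 1),
                     enzyme = "PDH missing CO2")
  rep_broken <- check_balance(broken, net)
  expect_false(rep_broken$pass)
  expect_equal(abs(rep_broken$element_imbalance[["C"]]), 1)

  # exchanges are exempt by rule
  expect_true(check_balance(net$substrate_exchange, net)$pass)
  expect_true(check_balance("OXPHOS_NADH", net)$pass)
  expect_error(check_balance("nope", net), "unknown reaction")
  expect_error(check_balance(reaction("X", c(ghost = -1, pyr = 1)), net),
               "unknown metabolite")
})

test_that("network construction enforces structural invariants", {
  m <- list(metabolite("A", formula = "CH2", role = "exchangeable"))
  r <- list(reaction("EX_A", c(A = 1), kind = "exchange"))
  expect_error(metabolic_network(m, r, "EX_A", "EX_missing"), "not found")
  expect_error(
    metabolic_network(m, list(reaction("EX_A", c(A = 1), kind = "exchange"),
                              reaction("CONV", c(A = -1, B = 1))),
                      "EX_A", "EX_A"),
    "unknown metabolite")
  expect_error(
    metabolic_network(c(m, m), r, "EX_A", "EX_A"), "duplicate")
  # a conversion declared as the exchange is rejected
  m2 <- list(metabolite("A", formula = "CH2", role = "exchangeable"),
             metabolite("B", formula = "CH2", role = "exchangeable"))
  r2 <- list(reaction("AB", c(A = -1, B = 1)),
             reaction("EX_A", c(A = 1), kind = "exchange"))
  expect_error(metabolic_network(m2, r2, "EX_A", "AB"), "exchange-kind")
  # unbalanced conversion rejected at validation
  r3 <- list(reaction("BAD", c(A = -1, B = 2)),
             reaction("EX_A", c(A = 1), kind = "exchange"),
             reaction("EX_B", c(B = -1), kind = "exchange"))
  expect_error(metabolic_network(m2, r3, "EX_A", "EX_B"), "unbalanced")
})

test_that("stoichiometric matrix mirrors the reaction list", {
  m <- list(metabolite("A", formula = "CH2"),
            metabolite("B", formula = "CH2", role = "exchangeable"))
  r <- list(reaction("AB", c(A = -1, B = 1)),
            reaction("EX_B", c(B = -1), kind = "exchange"),
            reaction("EX_A", c(A = 1), kind = "exchange"))
  net <- metabolic_network(m, r, "EX_A", "EX_B")
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(2, 3))
  expect_equal(unname(S[, "AB"]), c(-1, 1))

  net2 <- builtin_network("ethanol", "phb")
  S2 <- stoichiometric_matrix(net2)
  expect_equal(ncol(S2), length(net2$reactions))
  expect_equal(nrow(S2), length(net2$metabolites))
  # removing one reaction removes exactly one column
  net3 <- net2
  net3$reactions <- net3$reactions[names(net3$reactions) != "TCA"]
  expect_equal(ncol(stoichiometric_matrix(net3)), ncol(S2) - 1)
})

test_that("network JSON round trip is exact, including rational coefficients", {
  net <- builtin_network("acetate", "3hp")
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  net2 <- read_network_json(f)
  expect_identical(stoichiometric_matrix(net), stoichiometric_matrix(net2))
  expect_identical(net2$route_flags$acetate, "acs")

  # rational-string coefficients survive exactly
  m <- list(metabolite("A", formula = "C3H6"),
            metabolite("B", formula = "CH2", role = "exchangeable"))
  r <- list(reaction("SPLIT", c(A = "-1/3", B = 1)),
            reaction("EX_A", c(A = 1), kind = "exchange"),
            reaction("EX_B", c(B = -1), kind = "exchange"))
  net3 <- metabolic_network(m, r, "EX_A", "EX_B")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(net3, f2)
  net4 <- read_network_json(f2)
  expect_identical(net4$reactions$SPLIT$coef_n, c(-1, 1))
  expect_identical(net4$reactions$SPLIT$coef_d, c(3, 1))
})
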