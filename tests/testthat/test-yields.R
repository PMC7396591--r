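test_that("maximum yields match hand-balanced stoichiometry", {
  fw <- formula_weight

  # ethanol -> PHB via AdhE: 2 ethanol give 2 acetyl-CoA + 4 NADH; one
  # monomer needs 2 acetyl-CoA + 1 NADPH; carbon-limited at 1/2 mol/mol
  eth <- max_yield(builtin_network("ethanol", "phb"))
  expect_equal(eth$status, "optimal")
  expect_equal(eth$mol_yield, 0.5)
  expect_equal(eth$mass_yield, 0.5 * fw("C4H6O2") / fw("C2H6O"),
               tolerance = 1e-12)
  expect_equal(eth$co2_net, 0)

  # glucose -> PHB: 2 acetyl-CoA + 4 NADH + 2 ATP per glucose covers one
  # monomer's demand; 1 mol/mol
  glc <- max_yield(builtin_network("glucose", "phb"))
  expect_equal(glc$mol_yield, 1)
  expect_equal(glc$mass_yield, fw("C4H6O2") / fw("C6H12O6"), tolerance = 1e-12)
  expect_equal(glc$co2_net, 2)

  # acetate via ACS: algebraic oracle — the monomer deficit is 4 ATP
  # (2 activations) + 1 NAD(P)H (2.5 ATP-equiv) = 6.5; each extra acetate
  # oxidized nets 3*2.5 + 1.5 + 1 - 2 = 8 ATP, so x = 6.5/8 extra acetate
  # and yield = 1 / (2 + 6.5/8) mol/mol
  ace <- max_yield(builtin_network("acetate", "phb"))
  expect_equal(ace$mol_yield, 1 / 2.8125, tolerance = 1e-12)
  expect_equal(ace$mass_yield, fw("C4H6O2") / (2.8125 * fw("C2H4O2")),
               tolerance = 1e-12)

  # Pta-AckA activation (1 ATP): deficit 2 + 2.5, surplus 9 per extra acetate
  pta <- max_yield(builtin_network("acetate", "phb",
                                   acetate_route = "pta_ackA"))
  expect_equal(pta$mol_yield, 1 / 2.5, tolerance = 1e-12)

  # trivial identity network
  expect_equal(max_yield(identity_network())$mol_yield, 1)
  # toy dimerization
  expect_equal(max_yield(toy_dimer_network())$mol_yield, 0.5)
})

test_that("infeasible and unbounded models are reported as such", {
  # substrate has no consumer: uptake of 1 cannot reach steady state
  m <- list(metabolite("A", formula = "CH2", role = "exchangeable"),
            metabolite("B", formula = "CH2", role = "exchangeable"))
  r <- list(reaction("EX_A", c(A = 1), kind = "exchange"),
            reaction("EX_B", c(B = -1), kind = "exchange"))
  dead <- metabolic_network(m, r, "EX_A", "EX_B")
  expect_equal(max_yield(dead)$status, "infeasible")

  # an energetic source reaction creating product from nothing: unbounded
  r2 <- c(r, list(reaction("AB", c(A = -1, B = 1)),
                  reaction("MAGIC", c(B = 1), kind = "energetic")))
  magic <- metabolic_network(m, r2, "EX_A", "EX_B")
  expect_equal(max_yield(magic)$status, "unbounded")
})

test_that("LP optimum equals exact basic-solution enumeration", {
  # spot checks here; the exhaustive sweep lives in the acceptance suite
  for (net in list(toy_dimer_network(),
                   builtin_network("ethanol", "phb"),
                   builtin_network("acetate", "phb"))) {
    expect_equal(max_yield(net)$mol_yield, brute_force_max_yield(net),
                 tolerance = 1e-9)
  }
})

test_that("yields respond monotonically to the energy policy", {
  net <- builtin_network("acetate", "phb")  # energy-limited case
  y <- vapply(c(2.5, 1.5, 0.5), function(po)
    max_yield(net, cofactor_policy(po_nadh = po))$mol_yield, 0)
  expect_true(all(diff(y) <= 1e-12))
  ym <- vapply(c(0, 2, 6), function(m)
    max_yield(net, cofactor_policy(maintenance_atp = m))$mol_yield, 0)
  expect_true(all(diff(ym) <= 1e-12))
  yf <- vapply(c(1.5, 0.5), function(po)
    max_yield(net, cofactor_policy(po_fadh2 = po))$mol_yield, 0)
  expect_true(all(diff(yf) <= 1e-12))
})

test_that("strict NADPH accounting never beats the pooled policy", {
  for (cmb in list(c("glucose", "phb"), c("ethanol", "phb"),
                   c("acetate", "3hp"))) {
    net <- builtin_network(cmb[1], cmb[2])
    y_free <- max_yield(net, cofactor_policy(nadph_pooling = "free"))$mol_yield
    y_strict <- max_yield(net,
                          cofactor_policy(nadph_pooling = "strict"))$mol_yield
    expect_lte(y_strict, y_free + 1e-12)
  }
})

test_that("yields are invariant to the uptake scale", {
  net <- builtin_network("ethanol", "phb")
  r1 <- max_yield(net, uptake = 1)
  r2 <- max_yield(net, uptake = 2)
  expect_equal(r2$mol_yield, r1$mol_yield, tolerance = 1e-12)
  expect_equal(r2$flux[["EX_phb"]], 2 * r1$flux[["EX_phb"]],
               tolerance = 1e-12)
  expect_equal(r2$mass_yield, r1$mass_yield, tolerance = 1e-12)
})

test_that("carbon recovery matches the catabolic route", {
  eth <- builtin_network("ethanol", "accoa")
  expect_equal(carbon_recovery(max_yield(eth), eth), 100)
  exa <- builtin_network("ethanol", "accoa", ethanol_route = "exaABC")
  expect_equal(carbon_recovery(max_yield(exa), exa), 100)
  glc <- builtin_network("glucose", "accoa")
  expect_equal(carbon_recovery(max_yield(glc), glc), 200 / 3,
               tolerance = 1e-12)
  idn <- identity_network()
  expect_equal(carbon_recovery(max_yield(idn), idn), 100)
  # CO2-fixing product pathways are flagged when recovery exceeds 100%
  e3 <- builtin_network("ethanol", "3hp")
  r3 <- max_yield(e3)
  cr <- carbon_recovery(r3, e3)
  expect_gt(cr, 100)
  expect_true(isTRUE(attr(cr, "co2_fixed")))
})

test_that("net overall stoichiometry is carbon-conserving and canonical", {
  net <- builtin_network("ethanol", "phb")
  res <- max_yield(net)
  ov <- overall_stoichiometry(res, net)
  expect_identical(ov$carbon_balance, 0)
  # 2 ethanol -> 1 monomer + 3 surplus pooled NAD(P)H, zero net CO2
  expect_equal(res$net_stoichiometry[["etoh"]], -1)
  expect_equal(res$net_stoichiometry[["phb"]], 0.5)
  expect_equal(res$net_stoichiometry[["nadh"]] +
                 res$net_stoichiometry[["nadph"]], 1.5)
  expect_equal(res$net_stoichiometry[["co2"]], 0)
  expect_match(ov$equation, "^2 ethanol ->")
  expect_match(ov$equation, "3 NAD\\(P\\)H")

  # glucose -> PHB releases 2 CO2 per monomer
  g <- builtin_network("glucose", "phb")
  rg <- max_yield(g)
  expect_equal(rg$net_stoichiometry[["co2"]] / rg$mol_yield, 2)
  expect_identical(overall_stoichiometry(rg, g)$carbon_balance, 0)
})
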