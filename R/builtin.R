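#' Curated builtin networks: central metabolism plus engineered pathways
#'
#' Builds the curated small-scale stoichiometric model linking one substrate
#' (glucose, ethanol or acetate) to one product pathway:
#'
#' * **Catabolism** — lumped EMP glycolysis
#'   (glucose -> 2 pyruvate + 2 ATP + 2 NADH), pyruvate dehydrogenase
#'   (pyruvate -> acetyl-CoA + CO2 + NADH), and a lumped TCA cycle
#'   (acetyl-CoA -> 2 CO2 + 3 NAD(P)H + FADH2 + GTP). Glycolysis and TCA are
#'   deliberately single lumped reactions: the substrate comparison reasons
#'   at that granularity and per-step expansion adds nothing to the yields.
#' * **Substrate assimilation routes** — ethanol via the bifunctional
#'   reductase AdhE run oxidatively in two NADH-producing steps
#'   (`ethanol_route = "adhE"`), or via the quinoprotein ExaABC system
#'   (ethanol -> acetaldehyde with a cytochrome-c-level electron pair, then
#'   acetaldehyde -> acetate + NADH, followed by acetate activation;
#'   `ethanol_route = "exaABC"`); acetate via AMP-forming ACS (2
#'   ATP-equivalents per activation, `acetate_route = "acs"`) or via
#'   Pta-AckA (1 ATP, `acetate_route = "pta_ackA"`).
#' * **Product pathways** — PHB via PhaA/PhaB/PhaC
#'   (2 acetyl-CoA + NADPH -> one C4H6O2 repeat unit), 3-hydroxypropionate
#'   via ACC + MCR (acetyl-CoA + CO2 + ATP -> malonyl-CoA; + 2 NADPH -> 3HP),
#'   phloroglucinol via ACC + PhlD (3 malonyl-CoA -> C6H6O3 + 3 CO2),
#'   the bare acetyl moiety (`"accoa"`, for carbon-recovery analyses), or
#'   `"none"` (net ATP is the exported product; used for complete-oxidation
#'   energetics).
#' * **Energetics** — oxidative phosphorylation reactions converting NAD(P)H,
#'   FADH2 and cytochrome-level pairs to ATP at the [cofactor_policy()]
#'   rates, GTP/ATP equivalence, the reversible NADH/NADPH pool exchange
#'   (free pooling), and exchange reactions for substrate, product, CO2 and
#'   surplus ATP.
#'
#' CoA thioesters carry acid-equivalent formulas so that every conversion
#' reaction passes exact carbon and electron balance ([check_balance()]).
#'
#' @param substrate `"glucose"`, `"ethanol"` or `"acetate"`.
#' @param product `"phb"`, `"3hp"`, `"pg"`, `"accoa"` or `"none"`.
#' @param ethanol_route `"adhE"` (default) or `"exaABC"`; only valid with
#'   ethanol.
#' @param acetate_route `"acs"` (default) or `"pta_ackA"`; only valid when an
#'   acetate-activation step is present (acetate substrate, or ethanol via
#'   ExaABC).
#' @param policy a [cofactor_policy()] used to instantiate the energetic
#'   reactions (re-instantiated at solve time by [max_yield()]).
#' @return a validated `metabolic_network`.
#' @examples
#' net <- builtin_network("ethanol", "phb")
#' net
#' all(validate_network(net)$pass)
#' @export
builtin_network <- function(substrate = c("glucose", "ethanol", "acetate"),
                            product = c("phb", "3hp", "pg", "accoa", "none"),
                            ethanol_route = NULL, acetate_route = NULL,
                            policy = cofactor_policy()) {
  substrate <- match.arg(substrate)
  product <- match.arg(product)

  if (!is.null(ethanol_route) && substrate != "ethanol")
    stop("ethanol_route is only valid with substrate = \"ethanol\"",
         call. = FALSE)
  if (substrate == "ethanol") {
    ethanol_route <- if (is.null(ethanol_route)) "adhE"
                     else match.arg(ethanol_route, c("adhE", "exaABC"))
  }
  acetate_node <- substrate == "acetate" ||
    (substrate == "ethanol" && identical(ethanol_route, "exaABC"))
  if (!is.null(acetate_route) && !acetate_node)
    stop("acetate_route requires an acetate-activation step ",
         "(acetate substrate, or ethanol via exaABC)", call. = FALSE)
  if (acetate_node) {
    acetate_route <- if (is.null(acetate_route)) "acs"
                     else match.arg(acetate_route, c("acs", "pta_ackA"))
  }

  mets <- list()
  rxns <- list()
  add_met <- function(...) { m <- metabolite(...); mets[[m$id]] <<- m }
  add_rxn <- function(...) { r <- reaction(...); rxns[[r$id]] <<- r }

  # -- cofactor pseudo-species (carbon-free; 2 electrons per reduced pair)
  add_met("nadh",  "NAD(P)H (pooled reduced equivalent)", NULL,
          role = "cofactor", electrons = 2)
  add_met("fadh2", "FADH2", NULL, role = "cofactor", electrons = 2)
  add_met("atp",   "ATP equivalent", NULL, role = "cofactor", electrons = 0)
  add_met("gtp",   "GTP", NULL, role = "cofactor", electrons = 0)
  add_met("coa",   "coenzyme A (carrier)", NULL, role = "cofactor",
          electrons = 0)

  # -- shared carbon species
  add_met("accoa", "acetyl-CoA (acid-equivalent C2 unit)", "C2H4O2",
          role = "internal")
  add_met("co2", "carbon dioxide", "CO2", role = "exchangeable")

  # -- substrate block
  if (substrate == "glucose") {
    add_met("glc", "D-glucose", "C6H12O6", role = "exchangeable")
    add_met("pyr", "pyruvate", "C3H4O3", role = "internal")
    add_rxn("GLYC", c(glc = -1, pyr = 2, nadh = 2, atp = 2),
            enzyme = "EMP glycolysis (lumped)")
    add_rxn("PDH", c(pyr = -1, coa = -1, accoa = 1, co2 = 1, nadh = 1),
            enzyme = "PDH, pyruvate dehydrogenase")
    sub_id <- "glc"
  } else if (substrate == "ethanol") {
    add_met("etoh", "ethanol", "C2H6O", role = "exchangeable")
    add_met("acald", "acetaldehyde", "C2H4O", role = "internal")
    sub_id <- "etoh"
    if (ethanol_route == "adhE") {
      add_rxn("ADHE1", c(etoh = -1, acald = 1, nadh = 1),
              enzyme = "AdhE A267T/E568K (alcohol dehydrogenase step)")
      add_rxn("ADHE2", c(acald = -1, coa = -1, accoa = 1, nadh = 1),
              enzyme = "AdhE A267T/E568K (acetaldehyde dehydrogenase step)")
    } else {
      add_met("cytc", "cytochrome-c-level electron pair", NULL,
              role = "cofactor", electrons = 2)
      add_met("ac", "acetate", "C2H4O2", role = "internal")
      add_rxn("EXAA", c(etoh = -1, acald = 1, cytc = 1),
              enzyme = "ExaA, PQQ-dependent ethanol dehydrogenase")
      add_rxn("EXAC", c(acald = -1, ac = 1, nadh = 1),
              enzyme = "ExaC, NAD+-dependent acetaldehyde dehydrogenase")
      add_rxn("OXPHOS_CYTC", c(cytc = -1, atp = policy$po_cytc),
              enzyme = "oxphos-cytc", kind = "energetic")
    }
  } else {
    add_met("ac", "acetate", "C2H4O2", role = "exchangeable")
    sub_id <- "ac"
  }
  if (acetate_node) {
    if (acetate_route == "acs") {
      add_rxn("ACS", c(ac = -1, coa = -1, atp = -2, accoa = 1),
              enzyme = "ACS, AMP-forming acetyl-CoA synthetase (2 ATP-equiv)")
    } else {
      add_rxn("PTA_ACKA", c(ac = -1, coa = -1, atp = -1, accoa = 1),
              enzyme = "AckA-Pta, acetate kinase / phosphotransacetylase")
    }
  }

  # -- TCA and oxidative phosphorylation (always present)
  add_rxn("TCA", c(accoa = -1, co2 = 2, nadh = 3, fadh2 = 1, gtp = 1, coa = 1),
          enzyme = "TCA cycle (lumped; pooled NAD(P)H)")
  add_rxn("OXPHOS_NADH", c(nadh = -1, atp = policy$po_nadh),
          enzyme = "oxphos-NADH", kind = "energetic")
  add_rxn("OXPHOS_FADH2", c(fadh2 = -1, atp = policy$po_fadh2),
          enzyme = "oxphos-FADH2", kind = "energetic")
  add_rxn("GTP_ATP",
          if (policy$gtp_as_atp) c(gtp = -1, atp = 1) else c(gtp = -1),
          enzyme = "NDK, GTP/ATP equivalence", kind = "energetic")

  # -- product block
  needs_nadph <- product %in% c("phb", "3hp")
  if (needs_nadph)
    add_met("nadph", "NADPH", NULL, role = "cofactor", electrons = 2)
  if (product == "phb") {
    add_met("aacoa", "acetoacetyl-CoA (acid-equivalent C4 unit)", "C4H6O3",
            role = "internal")
    add_met("hbcoa", "(R)-3-hydroxybutyryl-CoA (acid-equivalent C4 unit)",
            "C4H8O3", role = "internal")
    add_met("phb", "PHB repeat unit", "C4H6O2", role = "exchangeable")
    add_rxn("PHAA", c(accoa = -2, aacoa = 1, coa = 1),
            enzyme = "PhaA, 3-ketothiolase")
    add_rxn("PHAB", c(aacoa = -1, nadph = -1, hbcoa = 1),
            enzyme = "PhaB, acetoacetyl-CoA reductase")
    add_rxn("PHAC", c(hbcoa = -1, phb = 1, coa = 1),
            enzyme = "PhaC1, PHA synthase")
    prod_id <- "phb"
  } else if (product %in% c("3hp", "pg")) {
    add_met("malcoa", "malonyl-CoA (acid-equivalent C3 unit)", "C3H4O4",
            role = "internal")
    add_rxn("ACC", c(accoa = -1, co2 = -1, atp = -1, malcoa = 1),
            enzyme = "ACC, acetyl-CoA carboxylase")
    if (product == "3hp") {
      add_met("hp3", "3-hydroxypropionate", "C3H6O3", role = "exchangeable")
      add_rxn("MCR", c(malcoa = -1, nadph = -2, hp3 = 1, coa = 1),
              enzyme = "MCR, malonyl-CoA reductase")
      prod_id <- "hp3"
    } else {
      add_met("pg", "phloroglucinol", "C6H6O3", role = "exchangeable")
      add_rxn("PHLD", c(malcoa = -3, pg = 1, co2 = 3, coa = 3),
              enzyme = "PhlD, type III polyketide synthase")
      prod_id <- "pg"
    }
  } else {
    prod_id <- NULL
  }
  if (needs_nadph && policy$nadph_pooling == "free")
    add_rxn("THD", c(nadh = -1, nadph = 1),
            enzyme = "transhydrogenase (pooled NAD(P)H)",
            reversible = TRUE, kind = "energetic")

  # -- exchanges
  add_rxn(paste0("EX_", sub_id), stats::setNames(1, sub_id),
          enzyme = "substrate uptake", kind = "exchange")
  add_rxn("EX_co2", c(co2 = -1), enzyme = "CO2 exchange",
          reversible = TRUE, kind = "exchange")
  add_rxn("EX_atp", c(atp = -1), enzyme = "net ATP drain",
          reversible = product == "none", kind = "exchange")
  if (product == "accoa") {
    # export of the acetyl moiety, releasing the CoA carrier
    add_rxn("EX_accoa", c(accoa = -1, coa = 1),
            enzyme = "acetyl-CoA (acetyl moiety) drain", kind = "exchange")
    prod_ex <- "EX_accoa"
  } else if (product == "none") {
    prod_ex <- "EX_atp"
  } else {
    add_rxn(paste0("EX_", prod_id), stats::setNames(-1, prod_id),
            enzyme = "product export", kind = "exchange")
    prod_ex <- paste0("EX_", prod_id)
  }

  flags <- list()
  if (substrate == "ethanol") flags$ethanol <- ethanol_route
  if (acetate_node) flags$acetate <- acetate_route
  metabolic_network(mets, rxns,
                    substrate_exchange = paste0("EX_", sub_id),
                    product_exchange = prod_ex,
                    route_flags = flags)
}

# species consumed by the product exchange that carries carbon (or NULL for
# the ATP-drain objective)
.product_species <- function(net) {
  r <- net$reactions[[net$product_exchange]]
  cons <- r$species[r$coef_n < 0]
  carb <- cons[vapply(cons, function(id)
    .carbon_count(net$metabolites[[id]]$formula) > 0, TRUE)]
  if (length(carb) >= 1) carb[[1]] else NULL
}

.substrate_species <- function(net) {
  r <- net$reactions[[net$substrate_exchange]]
  prod <- r$species[r$coef_n > 0]
  if (length(prod) != 1)
    stop("substrate exchange must import exactly one species", call. = FALSE)
  prod
}
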