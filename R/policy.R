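#' Cofactor and energy accounting policy
#'
#' Houses the energetic conventions used by the yield and ATP calculations:
#' P/O ratios for the three respiratory entry points, whether substrate-level
#' GTP (from the lumped TCA cycle) counts as ATP, whether the NADH and NADPH
#' pools interconvert freely (1:1, transhydrogenase-style) or are kept
#' strictly separate, and a non-growth maintenance ATP demand.
#'
#' The defaults — P/O(NADH) = 2.5, P/O(FADH2) = 1.5, cytochrome-c-level
#' pairs = 1.0, GTP counted as ATP, free NAD(P)H pooling, zero maintenance —
#' are the standard textbook aerobic E. coli values; they jointly reproduce
#' the classical 32 mol ATP per mol glucose for complete oxidation.
#'
#' @param po_nadh mol ATP per mol NAD(P)H oxidized (default 2.5).
#' @param po_fadh2 mol ATP per mol FADH2 oxidized (default 1.5).
#' @param po_cytc mol ATP per electron pair delivered at cytochrome-c level
#'   (default 1.0; used by the quinoprotein ExaABC ethanol route).
#' @param gtp_as_atp logical; count TCA substrate-level GTP as ATP
#'   (default `TRUE`).
#' @param nadph_pooling `"free"` (NADH and NADPH interconvert 1:1; default)
#'   or `"strict"` (no interconversion).
#' @param maintenance_atp non-negative ATP demand per unit substrate uptake
#'   (default 0; the theoretical yields in the source comparisons assume no
#'   maintenance burden).
#' @return an object of class `cofactor_policy`.
#' @examples
#' cofactor_policy()                  # defaults
#' cofactor_policy(po_nadh = 2)       # more conservative respiration
#' @export
cofactor_policy <- function(po_nadh = 2.5, po_fadh2 = 1.5, po_cytc = 1.0,
                            gtp_as_atp = TRUE,
                            nadph_pooling = c("free", "strict"),
                            maintenance_atp = 0) {
  nadph_pooling <- match.arg(nadph_pooling)
  stopifnot(is.numeric(po_nadh), po_nadh >= 0,
            is.numeric(po_fadh2), po_fadh2 >= 0,
            is.numeric(po_cytc), po_cytc >= 0,
            is.logical(gtp_as_atp),
            is.numeric(maintenance_atp), maintenance_atp >= 0)
  structure(list(po_nadh = po_nadh, po_fadh2 = po_fadh2, po_cytc = po_cytc,
                 gtp_as_atp = isTRUE(gtp_as_atp),
                 nadph_pooling = nadph_pooling,
                 maintenance_atp = maintenance_atp),
            class = "cofactor_policy")
}

#' @export
print.cofactor_policy <- function(x, ...) {
  cat(sprintf(paste0("<cofactor_policy> P/O: NADH %.3g, FADH2 %.3g, cyt-c %.3g",
                     " | GTP=ATP: %s | NAD(P)H pooling: %s | maintenance: %.3g\n"),
              x$po_nadh, x$po_fadh2, x$po_cytc, x$gtp_as_atp,
              x$nadph_pooling, x$maintenance_atp))
  invisible(x)
}

#' Re-instantiate the energetic reactions of a network under a policy
#'
#' Rewrites the policy-dependent energetic reactions of a network in place:
#' oxidative-phosphorylation ATP coefficients (`OXPHOS_NADH`, `OXPHOS_FADH2`,
#' `OXPHOS_CYTC`), GTP-to-ATP equivalence (`GTP_ATP`), and the reversible
#' NADH/NADPH interconversion (`THD`), which is present only under free
#' pooling. Reactions are matched by id, so the rewrite also applies to user
#' networks that follow the builtin naming convention; other reactions are
#' untouched.
#'
#' @param net a `metabolic_network`.
#' @param policy a [cofactor_policy()].
#' @return the modified `metabolic_network`.
#' @export
apply_policy <- function(net, policy = cofactor_policy()) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(policy, "cofactor_policy"))
  rxns <- net$reactions
  set_energetic <- function(id, stoich, reversible = FALSE) {
    rxns[[id]] <<- reaction(id, stoich, enzyme = rxns[[id]]$enzyme,
                            reversible = reversible, kind = "energetic")
  }
  if ("OXPHOS_NADH" %in% names(rxns))
    set_energetic("OXPHOS_NADH",
                  if (policy$po_nadh > 0) c(nadh = -1, atp = policy$po_nadh)
                  else c(nadh = -1))
  if ("OXPHOS_FADH2" %in% names(rxns))
    set_energetic("OXPHOS_FADH2",
                  if (policy$po_fadh2 > 0) c(fadh2 = -1, atp = policy$po_fadh2)
                  else c(fadh2 = -1))
  if ("OXPHOS_CYTC" %in% names(rxns))
    set_energetic("OXPHOS_CYTC",
                  if (policy$po_cytc > 0) c(cytc = -1, atp = policy$po_cytc)
                  else c(cytc = -1))
  if ("GTP_ATP" %in% names(rxns))
    set_energetic("GTP_ATP",
                  if (policy$gtp_as_atp) c(gtp = -1, atp = 1) else c(gtp = -1))
  has_nadph <- "nadph" %in% names(net$metabolites)
  if (has_nadph) {
    if (policy$nadph_pooling == "free") {
      rxns[["THD"]] <- reaction("THD", c(nadh = -1, nadph = 1),
                                enzyme = "transhydrogenase (pooled NAD(P)H)",
                                reversible = TRUE, kind = "energetic")
    } else {
      rxns[["THD"]] <- NULL
    }
  }
  net$reactions <- rxns
  net
}
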