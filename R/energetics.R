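#' ATP yield from complete oxidation of a substrate
#'
#' Computes the net ATP generated when one mol (or one gram) of substrate is
#' oxidized completely to CO2 and H2O: a flux-balance LP on the substrate's
#' assimilation route plus lumped TCA and oxidative phosphorylation, with
#' the product pathway absent, net CO2 export constrained to equal the
#' substrate carbon ("oxidized completely" is a constraint, not an
#' objective) and the reversible net-ATP drain maximized. Under the default
#' policy (P/O 2.5 / 1.5, GTP counted as ATP) this gives the classical 32,
#' 15 and 8 mol ATP per mol glucose, ethanol (AdhE route) and acetate
#' (ACS route). Energy-negative regimes (for example acetate activation at
#' zero P/O) are reported as negative net ATP rather than clamped, so policy
#' sensitivity stays visible.
#'
#' @param substrate `"glucose"`, `"ethanol"` or `"acetate"`.
#' @param policy a [cofactor_policy()].
#' @param ethanol_route,acetate_route assimilation route selectors passed to
#'   [builtin_network()].
#' @return `atp_per_mol()`: net mol ATP per mol substrate; `atp_per_gram()`:
#'   net mol ATP per gram (per-mol value divided by the substrate's average
#'   formula weight, so `atp_per_gram * formula_weight == atp_per_mol`
#'   exactly).
#' @examples
#' atp_per_mol("ethanol")    # 15
#' atp_per_gram("ethanol")   # 0.326 mol ATP per g
#' @export
atp_per_mol <- function(substrate = c("glucose", "ethanol", "acetate"),
                        policy = cofactor_policy(),
                        ethanol_route = NULL, acetate_route = NULL) {
  substrate <- match.arg(substrate)
  net <- builtin_network(substrate, "none", ethanol_route = ethanol_route,
                         acetate_route = acetate_route, policy = policy)
  lp <- .assemble_lp(net, policy, uptake = 1, complete_oxidation = TRUE)
  sol <- .rlp_solve(lp$A, lp$b, lp$cc)
  if (sol$status != "optimal")
    stop("complete-oxidation LP is ", sol$status, " for ", substrate,
         call. = FALSE)
  .rat_to_num(sol$obj)
}

#' @rdname atp_per_mol
#' @export
atp_per_gram <- function(substrate = c("glucose", "ethanol", "acetate"),
                         policy = cofactor_policy(),
                         ethanol_route = NULL, acetate_route = NULL) {
  substrate <- match.arg(substrate)
  fw <- formula_weight(switch(substrate,
                              glucose = "C6H12O6",
                              ethanol = "C2H6O",
                              acetate = "C2H4O2"))
  atp_per_mol(substrate, policy, ethanol_route, acetate_route) / fw
}
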