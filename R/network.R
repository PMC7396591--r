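#' Metabolites, reactions and metabolic networks
#'
#' `metabolite()` declares a chemical species. CoA thioesters are represented
#' by their acid-equivalent formula (acetyl-CoA as C2H4O2, malonyl-CoA as
#' C3H4O4, ...), so the CoA moiety cancels out of all balances; carrier and
#' redox cofactors (CoA, NAD(P)H, FADH2, cytochrome-c electron pairs, ATP)
#' are carbon-free pseudo-species declared without a formula and with an
#' explicit `electrons` override (2 for a reduced redox pair, 0 otherwise).
#' Cofactor-role species are excluded from mass-yield numerators and
#' denominators.
#'
#' `reaction()` declares a signed-stoichiometry reaction (negative
#' coefficient = consumed). Coefficients may be numbers or exact-rational
#' strings such as `"2/3"`. `kind` distinguishes mass-balanced `"conversion"`
#' reactions from balance-exempt `"exchange"` and `"energetic"`
#' (e.g. oxidative phosphorylation) reactions.
#'
#' `metabolic_network()` assembles and validates a network: all stoichiometry
#' keys must reference declared metabolites, the substrate and product
#' exchanges must exist and be exchange-kind, and (by default) every
#' conversion reaction must pass exact carbon and electron balance.
#'
#' @param id short unique identifier string.
#' @param name human-readable name.
#' @param formula an `elemental_formula`, a formula string, or `NULL` for a
#'   carbon-free carrier/cofactor pseudo-species.
#' @param charge integer charge (affects the degree of reduction).
#' @param role one of `"internal"`, `"exchangeable"`, `"cofactor"`.
#' @param electrons transferable electrons carried per molecule; defaults to
#'   the degree of reduction of `formula` (must be given when `formula` is
#'   `NULL`).
#' @return `metabolite()` an object of class `metabolite`; `reaction()` an
#'   object of class `reaction`; `metabolic_network()` a validated
#'   `metabolic_network`.
#' @examples
#' m <- metabolite("etoh", "ethanol", "C2H6O", role = "exchangeable")
#' r <- reaction("EX_etoh", c(etoh = 1), kind = "exchange")
#' @export
metabolite <- function(id, name = id, formula = NULL, charge = 0L,
                       role = c("internal", "exchangeable", "cofactor"),
                       electrons = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1, nchar(id) > 0)
  if (!is.null(formula)) formula <- .as_formula(formula)
  if (is.null(formula) && role != "cofactor")
    stop("only cofactor-role species may omit a formula: ", id, call. = FALSE)
  if (is.null(electrons)) {
    electrons <- if (is.null(formula)) 0 else degree_of_reduction(formula, charge)
  }
  structure(list(id = id, name = name, formula = formula,
                 charge = as.integer(charge), role = role,
                 electrons = electrons),
            class = "metabolite")
}

#' @rdname metabolite
#' @param stoichiometry named numeric (or rational-string) vector mapping
#'   metabolite id to signed coefficient; negative = consumed.
#' @param enzyme free-text enzyme annotation (e.g. `"PDH"`, `"AdhE"`).
#' @param reversible logical; irreversible reactions carry non-negative flux.
#' @param kind `"conversion"`, `"exchange"` or `"energetic"`.
#' @export
reaction <- function(id, stoichiometry, enzyme = "", reversible = FALSE,
                     kind = c("conversion", "exchange", "energetic")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1, nchar(id) > 0)
  if (length(stoichiometry) == 0 || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector", call. = FALSE)
  r <- .parse_rat(stoichiometry)
  keep <- r$n != 0
  if (kind == "conversion" && sum(keep) < 2)
    stop("conversion reaction needs >= 2 nonzero coefficients: ", id,
         call. = FALSE)
  structure(list(id = id, enzyme = enzyme,
                 species = names(stoichiometry)[keep],
                 coef_n = r$n[keep], coef_d = r$d[keep],
                 reversible = isTRUE(reversible), kind = kind),
            class = "reaction")
}

.rxn_coefs <- function(r) stats::setNames(r$coef_n / r$coef_d, r$species)

#' @rdname metabolite
#' @param metabolites list of `metabolite` objects.
#' @param reactions list of `reaction` objects.
#' @param substrate_exchange,product_exchange reaction ids of the substrate
#'   uptake and product export exchanges.
#' @param route_flags named list recording which alternative assimilation
#'   routes are enabled (informational; see [builtin_network()]).
#' @param validate check carbon/electron balance of all conversion reactions
#'   (default `TRUE`).
#' @export
metabolic_network <- function(metabolites, reactions, substrate_exchange,
                              product_exchange, route_flags = list(),
                              validate = TRUE) {
  stopifnot(all(vapply(metabolites, inherits, TRUE, "metabolite")),
            all(vapply(reactions, inherits, TRUE, "reaction")))
  mids <- vapply(metabolites, `[[`, "", "id")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(mids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rids)) stop("duplicate reaction ids", call. = FALSE)
  names(metabolites) <- mids
  names(reactions) <- rids
  for (r in reactions) {
    unknown <- setdiff(r$species, mids)
    if (length(unknown) > 0)
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (ex in c(substrate_exchange, product_exchange)) {
    if (!ex %in% rids) stop("exchange reaction not found: ", ex, call. = FALSE)
    if (reactions[[ex]]$kind != "exchange")
      stop("declared exchange is not exchange-kind: ", ex, call. = FALSE)
  }
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        substrate_exchange = substrate_exchange,
                        product_exchange = product_exchange,
                        route_flags = route_flags),
                   class = "metabolic_network")
  if (validate) {
    rep <- validate_network(net)
    bad <- rep$reaction[!rep$pass]
    if (length(bad) > 0)
      stop("unbalanced conversion reaction(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions\n",
              length(x$metabolites), length(x$reactions)))
  cat("  substrate exchange:", x$substrate_exchange,
      "| product exchange:", x$product_exchange, "\n")
  if (length(x$route_flags) > 0)
    cat("  routes:", paste(names(x$route_flags), unlist(x$route_flags),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Exact balance checking of reactions
#'
#' Checks a reaction for exact (rational-arithmetic, zero-tolerance) carbon
#' and electron (degree-of-reduction) balance. Under the acid-equivalent
#' cofactor convention hydrogen and oxygen flow through implicit water and
#' protons, so carbon is the element balanced; redox bookkeeping is enforced
#' through the electron balance, with reduced cofactor pairs (NAD(P)H, FADH2,
#' cytochrome-c pairs) each carrying 2 transferable electrons. Exchange and
#' energetic reactions are exempt and always pass.
#'
#' @param r a `reaction` or a reaction id present in `net`.
#' @param net a `metabolic_network` supplying metabolite identities.
#' @return a `balance_report`: list with `reaction`, `element_imbalance`
#'   (named numeric, currently `C`), `electron_imbalance`, and `pass` (true
#'   iff every imbalance entry is exactly zero).
#' @examples
#' net <- builtin_network("glucose", "phb")
#' check_balance("PDH", net)$pass
#' @export
check_balance <- function(r, net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.character(r)) {
    if (!r %in% names(net$reactions)) stop("unknown reaction id: ", r, call. = FALSE)
    r <- net$reactions[[r]]
  }
  unknown <- setdiff(r$species, names(net$metabolites))
  if (length(unknown) > 0)
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (r$kind != "conversion") {
    return(structure(list(reaction = r$id, exempt = TRUE,
                          element_imbalance = c(C = 0),
                          electron_imbalance = 0, pass = TRUE),
                     class = "balance_report"))
  }
  cn <- 0; cd <- 1   # carbon
  en <- 0; ed <- 1   # electrons
  for (k in seq_along(r$species)) {
    met <- net$metabolites[[r$species[k]]]
    carbon <- .carbon_count(met$formula)
    if (carbon != 0) {
      t <- .rat_mul(r$coef_n[k], r$coef_d[k], carbon, 1)
      s <- .rat_add(cn, cd, t$n, t$d); cn <- s$n; cd <- s$d
    }
    gam <- .as_rat(met$electrons)
    if (gam$n != 0) {
      t <- .rat_mul(r$coef_n[k], r$coef_d[k], gam$n, gam$d)
      s <- .rat_add(en, ed, t$n, t$d); en <- s$n; ed <- s$d
    }
  }
  structure(list(reaction = r$id, exempt = FALSE,
                 element_imbalance = c(C = cn / cd),
                 electron_imbalance = en / ed,
                 pass = cn == 0 && en == 0),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  status <- if (x$pass) "PASS" else "FAIL"
  if (isTRUE(x$exempt)) status <- "PASS (exempt)"
  cat(sprintf("<balance> %-14s %s  C: %+g  e-: %+g\n", x$reaction, status,
              x$element_imbalance[["C"]], x$electron_imbalance))
  invisible(x)
}

#' @rdname check_balance
#' @return `validate_network()`: a data.frame with one row per reaction and
#'   columns `reaction`, `kind`, `C_imbalance`, `e_imbalance`, `pass`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  reports <- lapply(net$reactions, check_balance, net = net)
  data.frame(
    reaction = vapply(reports, `[[`, "", "reaction"),
    kind = vapply(net$reactions, `[[`, "", "kind"),
    C_imbalance = vapply(reports, function(x) x$element_imbalance[["C"]], 0),
    e_imbalance = vapply(reports, `[[`, 0, "electron_imbalance"),
    pass = vapply(reports, `[[`, TRUE, "pass"),
    row.names = NULL)
}

#' Stoichiometric matrix of a network
#'
#' Returns the dense stoichiometric matrix S with one row per metabolite and
#' one column per reaction; entry (i, j) is the signed coefficient of
#' metabolite i in reaction j. Row and column names are the metabolite and
#' reaction ids.
#'
#' @param net a `metabolic_network`.
#' @return a numeric matrix with dimnames `(metabolite ids, reaction ids)`.
#' @examples
#' S <- stoichiometric_matrix(builtin_network("ethanol", "phb"))
#' dim(S)
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- names(net$metabolites)
  rids <- names(net$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in net$reactions) S[r$species, r$id] <- r$coef_n / r$coef_d
  S
}

# exact rational stoichiometric matrix (internal)
.stoich_rat <- function(net) {
  mids <- names(net$metabolites)
  rids <- names(net$reactions)
  Sn <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  Sd <- matrix(1, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in net$reactions) {
    Sn[r$species, r$id] <- r$coef_n
    Sd[r$species, r$id] <- r$coef_d
  }
  list(n = Sn, d = Sd)
}
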