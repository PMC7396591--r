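# ---- LP assembly ------------------------------------------------------------
# Builds max c'v s.t. S v = 0 (all species), uptake row, optional complete-
# oxidation row, v >= 0 with reversible reactions split into +/- columns and
# the maintenance demand applied as a lower-bound shift on the ATP drain.
.assemble_lp <- function(net, policy, uptake = 1, complete_oxidation = FALSE) {
  net <- apply_policy(net, policy)
  S <- .stoich_rat(net)
  rids <- names(net$reactions)
  rev <- vapply(net$reactions, `[[`, TRUE, "reversible")

  col_rxn <- unlist(lapply(seq_along(rids), function(j)
    if (rev[j]) c(rids[j], rids[j]) else rids[j]))
  col_sign <- unlist(lapply(seq_along(rids), function(j)
    if (rev[j]) c(1, -1) else 1))
  ncols <- length(col_rxn)
  jmap <- match(col_rxn, rids)

  An <- S$n[, jmap, drop = FALSE] * rep(col_sign, each = nrow(S$n))
  Ad <- S$d[, jmap, drop = FALSE]

  upt <- .as_rat(uptake)
  sub_cols <- which(col_rxn == net$substrate_exchange)
  urow_n <- numeric(ncols); urow_d <- rep(1, ncols)
  urow_n[sub_cols] <- col_sign[sub_cols]
  An <- rbind(An, urow_n); Ad <- rbind(Ad, urow_d)
  bn <- c(numeric(nrow(S$n)), upt$n)
  bd <- c(rep(1, nrow(S$n)), upt$d)

  if (complete_oxidation) {
    co2_cols <- which(col_rxn == "EX_co2")
    if (length(co2_cols) == 0) stop("network lacks EX_co2", call. = FALSE)
    sub_sp <- .substrate_species(net)
    csub <- .carbon_count(net$metabolites[[sub_sp]]$formula)
    crow_n <- numeric(ncols); crow_d <- rep(1, ncols)
    crow_n[co2_cols] <- col_sign[co2_cols]
    cox <- .rat_mul(csub, 1, upt$n, upt$d)
    An <- rbind(An, crow_n); Ad <- rbind(Ad, crow_d)
    bn <- c(bn, cox$n); bd <- c(bd, cox$d)
  }

  # maintenance ATP as lower bound on an irreversible EX_atp
  shift <- stats::setNames(numeric(0), character(0))
  if (policy$maintenance_atp > 0 && "EX_atp" %in% rids &&
      !net$reactions[["EX_atp"]]$reversible &&
      net$product_exchange != "EX_atp") {
    mcol <- which(col_rxn == "EX_atp")[1]
    mnt <- .rat_mul(.as_rat(policy$maintenance_atp)$n,
                    .as_rat(policy$maintenance_atp)$d, upt$n, upt$d)
    for (i in seq_along(bn)) {
      if (An[i, mcol] == 0) next
      t <- .rat_mul(An[i, mcol], Ad[i, mcol], mnt$n, mnt$d)
      s <- .rat_sub(bn[i], bd[i], t$n, t$d)
      bn[i] <- s$n; bd[i] <- s$d
    }
    shift <- stats::setNames(.rat_to_num(mnt), "EX_atp")
  }

  cn <- numeric(ncols); cd <- rep(1, ncols)
  pcols <- which(col_rxn == net$product_exchange)
  cn[pcols] <- col_sign[pcols]

  list(net = net, A = list(n = An, d = Ad), b = list(n = bn, d = bd),
       cc = list(n = cn, d = cd), col_rxn = col_rxn, col_sign = col_sign,
       shift = shift)
}

# recombine split columns into one exact flux value per reaction
.recombine_flux <- function(lp, x) {
  rids <- names(lp$net$reactions)
  vn <- stats::setNames(numeric(length(rids)), rids)
  vd <- stats::setNames(rep(1, length(rids)), rids)
  for (k in seq_along(lp$col_rxn)) {
    if (x$n[k] == 0) next
    t <- .rat_mul(lp$col_sign[k], 1, x$n[k], x$d[k])
    s <- .rat_add(vn[lp$col_rxn[k]], vd[lp$col_rxn[k]], t$n, t$d)
    vn[lp$col_rxn[k]] <- s$n; vd[lp$col_rxn[k]] <- s$d
  }
  for (id in names(lp$shift)) {
    s <- .rat_add(vn[id], vd[id], .as_rat(lp$shift[[id]])$n,
                  .as_rat(lp$shift[[id]])$d)
    vn[id] <- s$n; vd[id] <- s$d
  }
  list(n = vn, d = vd)
}

#' Maximum theoretical yield by linear programming
#'
#' Solves the flux-balance linear program that defines the theoretical yield:
#' maximize product-exchange flux subject to exact steady state on every
#' species (internal and cofactor; exchanged species are balanced by their
#' exchange reactions), substrate uptake fixed to `uptake`, irreversible
#' fluxes non-negative, redox converted to ATP only through the
#' policy-defined oxidative-phosphorylation reactions, and net ATP
#' production at least the policy maintenance demand. The LP is solved with
#' an exact-rational simplex, so the returned yields carry no solver
#' tolerance; among alternate optima the parsimonious (minimum-total-flux)
#' solution is reported, which affects the flux vector display but never the
#' yield. There is no biomass demand: the result is a product-only
#' stoichiometric limit.
#'
#' @param net a `metabolic_network` (typically from [builtin_network()]).
#' @param policy a [cofactor_policy()].
#' @param uptake substrate uptake the solution is scaled to (mol; default 1).
#'   Yields are reported per mol/g substrate and are invariant to `uptake`.
#' @return an object of class `yield_result` with fields `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `flux` (named numeric,
#'   exact), `mol_yield`, `mass_yield` (using average formula weights of the
#'   carbon product and substrate; `NA` for the ATP objective),
#'   `carbon_recovery_pct`, `net_stoichiometry` (net production of every
#'   exchangeable and cofactor species by the conversion reactions, i.e. the
#'   deduced overall pathway stoichiometry before respiration), and
#'   `co2_net` (net CO2 released per unit uptake; negative = net fixation).
#' @examples
#' res <- max_yield(builtin_network("ethanol", "phb"))
#' res$mol_yield   # 0.5 mol PHB monomer per mol ethanol
#' res$mass_yield  # ~0.934 g/g
#' @export
max_yield <- function(net, policy = cofactor_policy(), uptake = 1) {
  stopifnot(inherits(net, "metabolic_network"), uptake > 0)
  lp <- .assemble_lp(net, policy, uptake = uptake)
  sol <- .rlp_solve_parsimonious(lp$A, lp$b, lp$cc)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, flux = NULL, mol_yield = NA_real_,
                          mass_yield = NA_real_, carbon_recovery_pct = NA_real_,
                          net_stoichiometry = NULL, co2_net = NA_real_,
                          substrate = .substrate_species(lp$net),
                          product = .product_species(lp$net), policy = policy),
                     class = "yield_result"))
  }
  v <- .recombine_flux(lp, sol$x)
  net2 <- lp$net
  flux <- v$n / v$d

  sub_sp <- .substrate_species(net2)
  prod_sp <- .product_species(net2)
  upt <- .as_rat(uptake)
  my <- .rat_div(sol$obj$n, sol$obj$d, upt$n, upt$d)
  mol_yield <- unname(.rat_to_num(my))
  mass_yield <- if (is.null(prod_sp)) NA_real_ else
    mol_yield * formula_weight(net2$metabolites[[prod_sp]]$formula) /
      formula_weight(net2$metabolites[[sub_sp]]$formula)

  # net production by conversion reactions over exchangeable/cofactor species
  roles <- vapply(net2$metabolites, `[[`, "", "role")
  disp <- union(names(roles)[roles %in% c("exchangeable", "cofactor")],
                prod_sp)
  nn <- stats::setNames(numeric(length(disp)), disp)
  nd <- stats::setNames(rep(1, length(disp)), disp)
  for (r in net2$reactions) {
    if (r$kind != "conversion" || v$n[[r$id]] == 0) next
    for (k in seq_along(r$species)) {
      sp <- r$species[k]
      if (!sp %in% disp) next
      t <- .rat_mul(r$coef_n[k], r$coef_d[k], v$n[[r$id]], v$d[[r$id]])
      s <- .rat_add(nn[sp], nd[sp], t$n, t$d)
      nn[sp] <- s$n; nd[sp] <- s$d
    }
  }
  co2 <- if ("EX_co2" %in% names(flux)) flux[["EX_co2"]] / uptake else 0

  cs <- .carbon_count(net2$metabolites[[sub_sp]]$formula)
  cp <- if (is.null(prod_sp)) 0 else
    .carbon_count(net2$metabolites[[prod_sp]]$formula)
  crec <- if (cs > 0 && !is.null(prod_sp)) 100 * mol_yield * cp / cs else NA_real_

  structure(list(status = "optimal", flux = flux,
                 flux_n = v$n, flux_d = v$d,
                 mol_yield = mol_yield, mol_yield_n = my$n, mol_yield_d = my$d,
                 mass_yield = mass_yield, carbon_recovery_pct = crec,
                 net_stoichiometry = nn / nd, net_n = nn, net_d = nd,
                 co2_net = co2, substrate = sub_sp, product = prod_sp,
                 policy = policy, uptake = uptake),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat("<yield_result>", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  substrate: %s | product: %s\n", x$substrate,
                if (is.null(x$product)) "ATP" else x$product))
    cat(sprintf("  mol yield: %s mol/mol | mass yield: %s g/g | C recovery: %s%%\n",
                signif(x$mol_yield, 3),
                if (is.na(x$mass_yield)) "NA" else signif(x$mass_yield, 3),
                if (is.na(x$carbon_recovery_pct)) "NA"
                else signif(x$carbon_recovery_pct, 3)))
    cat(sprintf("  net CO2 per substrate: %s\n", signif(x$co2_net, 3)))
  }
  invisible(x)
}

#' Carbon recovery of an optimal yield solution
#'
#' Percentage of organic substrate carbon recovered in the product:
#' `100 * mol_yield * C_product / C_substrate`. Net CO2 fixation (negative
#' `co2_net`) can push recovery above 100%; in that case the returned value
#' carries attribute `co2_fixed = TRUE`.
#'
#' @param res an optimal `yield_result`.
#' @param net the network it was computed on.
#' @return numeric percentage.
#' @examples
#' net <- builtin_network("ethanol", "accoa")
#' carbon_recovery(max_yield(net), net)   # 100
#' @export
carbon_recovery <- function(res, net) {
  stopifnot(inherits(res, "yield_result"), inherits(net, "metabolic_network"))
  if (res$status != "optimal") stop("yield result is not optimal", call. = FALSE)
  sub_sp <- res$substrate
  cs <- .carbon_count(net$metabolites[[sub_sp]]$formula)
  if (cs == 0) stop("substrate carries no carbon", call. = FALSE)
  if (is.null(res$product)) stop("no carbon product to recover", call. = FALSE)
  cp <- .carbon_count(net$metabolites[[res$product]]$formula)
  out <- 100 * res$mol_yield * cp / cs
  if (!is.na(res$co2_net) && res$co2_net < 0) attr(out, "co2_fixed") <- TRUE
  out
}

#' Net overall stoichiometry of an optimal solution
#'
#' Renders the deduced overall pathway equation: the flux-weighted net
#' coefficients of the conversion reactions over exchanged species and
#' cofactors, scaled to the smallest exact integer coefficients. Under free
#' NAD(P)H pooling the NADH and NADPH entries are reported as a single
#' pooled NAD(P)H term. The equation is exactly carbon-conserving for every
#' optimal solution (each conversion reaction is carbon-balanced).
#'
#' @param res an optimal `yield_result`.
#' @param net the network it was computed on.
#' @return a list of class `overall_stoichiometry` with `coefficients`
#'   (named numeric, net production per unit uptake), `equation` (canonical
#'   string with integer coefficients), and `carbon_balance` (exact net
#'   carbon; always 0 at an optimum).
#' @examples
#' net <- builtin_network("ethanol", "phb")
#' overall_stoichiometry(max_yield(net), net)
#' @export
overall_stoichiometry <- function(res, net) {
  stopifnot(inherits(res, "yield_result"), inherits(net, "metabolic_network"))
  if (res$status != "optimal") stop("yield result is not optimal", call. = FALSE)
  nn <- res$net_n; nd <- res$net_d
  pooled <- res$policy$nadph_pooling == "free" &&
    all(c("nadh", "nadph") %in% names(nn) | !"nadph" %in% names(nn))
  if (res$policy$nadph_pooling == "free" && "nadph" %in% names(nn)) {
    s <- .rat_add(nn[["nadh"]], nd[["nadh"]], nn[["nadph"]], nd[["nadph"]])
    nn[["nadh"]] <- s$n; nd[["nadh"]] <- s$d
    keep <- names(nn) != "nadph"
    nn <- nn[keep]; nd <- nd[keep]
  }
  keep <- nn != 0
  nn <- nn[keep]; nd <- nd[keep]

  # exact carbon balance of the net equation
  cb_n <- 0; cb_d <- 1
  for (sp in names(nn)) {
    cc <- .carbon_count(net$metabolites[[sp]]$formula)
    if (cc == 0) next
    t <- .rat_mul(nn[[sp]], nd[[sp]], cc, 1)
    s <- .rat_add(cb_n, cb_d, t$n, t$d); cb_n <- s$n; cb_d <- s$d
  }

  # scale to smallest integers: multiply by lcm(denoms)/gcd(numerators)
  if (length(nn) > 0) {
    lcm <- 1
    for (d in nd) lcm <- lcm * d / .rat_gcd(lcm, d)
    ints <- nn * (lcm / nd)
    g <- 0
    for (v in ints) g <- .rat_gcd(g, v)
    if (g == 0) g <- 1
    ints <- ints / g
  } else ints <- numeric(0)

  label <- function(sp) {
    if (sp == "nadh" && res$policy$nadph_pooling == "free" &&
        "nadph" %in% names(net$metabolites)) return("NAD(P)H")
    net$metabolites[[sp]]$name
  }
  fmt <- function(idx, sgn) {
    if (length(idx) == 0) return("(nothing)")
    paste(vapply(idx, function(i) {
      k <- sgn * ints[i]
      paste0(if (k == 1) "" else paste0(k, " "), label(names(ints)[i]))
    }, ""), collapse = " + ")
  }
  lhs <- which(ints < 0)
  rhs <- which(ints > 0)
  eqn <- paste(fmt(lhs, -1), "->", fmt(rhs, 1))

  structure(list(coefficients = nn / nd, integer_coefficients = ints,
                 equation = eqn, carbon_balance = cb_n / cb_d),
            class = "overall_stoichiometry")
}

#' @export
print.overall_stoichiometry <- function(x, ...) {
  cat("<overall_stoichiometry>", x$equation, "\n")
  invisible(x)
}

#' Exact maximum yield by basic-solution enumeration (test oracle)
#'
#' Independent brute-force oracle for [max_yield()]: enumerates the basic
#' solutions (vertices) of the same flux polytope by exact rational
#' elimination over all column subsets of the steady-state system and
#' returns the exact maximum objective over feasible vertices. A fast
#' floating-point pre-pass filters candidate bases; every candidate within
#' rounding distance of the float optimum is then confirmed in exact
#' arithmetic, so the returned value is exact. Because the objective is
#' bounded on these carbon-conserving networks, the optimum is attained at a
#' vertex and enumeration is exhaustive. Intended for networks of up to ~25
#' reactions (an explicit guard rejects larger enumerations).
#'
#' @inheritParams max_yield
#' @param max_bases guard on the number of column subsets enumerated.
#' @return exact maximum mol yield (numeric), or `NA` with a warning if no
#'   feasible basic solution exists.
#' @examples
#' net <- builtin_network("ethanol", "phb")
#' brute_force_max_yield(net) == max_yield(net)$mol_yield
#' @export
brute_force_max_yield <- function(net, policy = cofactor_policy(), uptake = 1,
                                  max_bases = 2e5) {
  stopifnot(inherits(net, "metabolic_network"))
  lp <- .assemble_lp(net, policy, uptake = uptake)
  red <- .rat_rref(lp$A, lp$b)
  if (!red$consistent) {
    warning("constraint system inconsistent: no feasible solution")
    return(NA_real_)
  }
  An <- red$A$n; Ad <- red$A$d
  bn <- red$b$n; bd <- red$b$d
  r <- nrow(An); n <- ncol(An)
  if (n > 28) stop("enumeration guard: too many reactions (", n, " columns)",
                   call. = FALSE)
  if (choose(n, r) > max_bases)
    stop("enumeration guard: ", choose(n, r), " bases exceed max_bases",
         call. = FALSE)

  Af <- An / Ad
  bf <- bn / bd
  cf <- lp$cc$n / lp$cc$d
  subsets <- utils::combn(n, r)
  cand <- list()
  best_float <- -Inf
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    M <- Af[, idx, drop = FALSE]
    x <- tryCatch(solve(M, bf), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x)) || min(x) < -1e-6) next
    obj <- sum(cf[idx] * x)
    if (obj > best_float + 1e-9) best_float <- obj
    cand[[length(cand) + 1]] <- list(idx = idx, obj = obj)
  }
  if (length(cand) == 0) {
    warning("no feasible basic solution found")
    return(NA_real_)
  }
  objs <- vapply(cand, `[[`, 0, "obj")
  check <- cand[objs >= best_float - 1e-6]
  best <- NULL
  for (cd in check) {
    sol <- .rat_solve_square(An[, cd$idx, drop = FALSE],
                             Ad[, cd$idx, drop = FALSE], bn, bd)
    if (is.null(sol) || any(sol$n < 0)) next
    on <- 0; od <- 1
    for (k in seq_len(r)) {
      j <- cd$idx[k]
      if (lp$cc$n[j] == 0 || sol$n[k] == 0) next
      t <- .rat_mul(lp$cc$n[j], lp$cc$d[j], sol$n[k], sol$d[k])
      s2 <- .rat_add(on, od, t$n, t$d); on <- s2$n; od <- s2$d
    }
    if (is.null(best) || .rat_lt(best$n, best$d, on, od))
      best <- list(n = on, d = od)
  }
  if (is.null(best)) {
    warning("float pre-pass found no exactly feasible vertex")
    return(NA_real_)
  }
  upt <- .as_rat(uptake)
  unname(.rat_to_num(.rat_div(best$n, best$d, upt$n, upt$d)))
}

# ---- exact linear algebra helpers (for the oracle) --------------------------

# reduced row echelon form of [A | b]; returns independent rows only and a
# consistency flag
.rat_rref <- function(A, b) {
  An <- cbind(A$n, b$n); Ad <- cbind(A$d, b$d)
  m <- nrow(An); ncols <- ncol(An); nvar <- ncols - 1L
  piv_row <- 0L
  for (j in seq_len(nvar)) {
    if (piv_row == m) break
    rows <- which(An[, j] != 0)
    rows <- rows[rows > piv_row]
    if (length(rows) == 0) next
    piv_row <- piv_row + 1L
    if (rows[1] != piv_row) {
      tmp <- An[piv_row, ]; An[piv_row, ] <- An[rows[1], ]; An[rows[1], ] <- tmp
      tmp <- Ad[piv_row, ]; Ad[piv_row, ] <- Ad[rows[1], ]; Ad[rows[1], ] <- tmp
    }
    sc <- .rat_div(An[piv_row, ], Ad[piv_row, ],
                   rep(An[piv_row, j], ncols), rep(Ad[piv_row, j], ncols))
    An[piv_row, ] <- sc$n; Ad[piv_row, ] <- sc$d
    for (i in seq_len(m)) {
      if (i == piv_row || An[i, j] == 0) next
      t <- .rat_mul(rep(An[i, j], ncols), rep(Ad[i, j], ncols),
                    An[piv_row, ], Ad[piv_row, ])
      u <- .rat_sub(An[i, ], Ad[i, ], t$n, t$d)
      An[i, ] <- u$n; Ad[i, ] <- u$d
    }
  }
  zero_rows <- apply(An[, seq_len(nvar), drop = FALSE] != 0, 1, sum) == 0
  consistent <- all(An[zero_rows, ncols] == 0)
  keep <- which(!zero_rows)
  list(A = list(n = An[keep, seq_len(nvar), drop = FALSE],
                d = Ad[keep, seq_len(nvar), drop = FALSE]),
       b = list(n = An[keep, ncols], d = Ad[keep, ncols]),
       consistent = consistent)
}

# exact solve of square rational system; NULL if singular
.rat_solve_square <- function(An, Ad, bn, bd) {
  r <- nrow(An)
  Mn <- cbind(An, bn); Md <- cbind(Ad, bd)
  ncols <- r + 1L
  for (j in seq_len(r)) {
    rows <- which(Mn[, j] != 0)
    rows <- rows[rows >= j]
    if (length(rows) == 0) return(NULL)
    if (rows[1] != j) {
      tmp <- Mn[j, ]; Mn[j, ] <- Mn[rows[1], ]; Mn[rows[1], ] <- tmp
      tmp <- Md[j, ]; Md[j, ] <- Md[rows[1], ]; Md[rows[1], ] <- tmp
    }
    sc <- .rat_div(Mn[j, ], Md[j, ], rep(Mn[j, j], ncols), rep(Md[j, j], ncols))
    Mn[j, ] <- sc$n; Md[j, ] <- sc$d
    for (i in seq_len(r)) {
      if (i == j || Mn[i, j] == 0) next
      t <- .rat_mul(rep(Mn[i, j], ncols), rep(Md[i, j], ncols), Mn[j, ], Md[j, ])
      u <- .rat_sub(Mn[i, ], Md[i, ], t$n, t$d)
      Mn[i, ] <- u$n; Md[i, ] <- u$d
    }
  }
  list(n = Mn[, ncols], d = Md[, ncols])
}
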