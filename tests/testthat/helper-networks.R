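# Shared fixtures: toy and randomized networks built in code.

# minimal 2A -> B network: mol yield 1/2 by construction
toy_dimer_network <- function() {
  mets <- list(
    metabolite("A", formula = "CH2", role = "exchangeable"),
    metabolite("B", formula = "C2H4", role = "exchangeable"))
  rxns <- list(
    reaction("DIM", c(A = -2, B = 1), enzyme = "dimerase"),
    reaction("EX_A", c(A = 1), kind = "exchange"),
    reaction("EX_B", c(B = -1), kind = "exchange"))
  metabolic_network(mets, rxns, "EX_A", "EX_B")
}

# identity network: substrate exported unchanged
identity_network <- function() {
  mets <- list(metabolite("glc", formula = "C6H12O6", role = "exchangeable"))
  rxns <- list(reaction("EX_in", c(glc = 1), kind = "exchange"),
               reaction("EX_out", c(glc = -1), kind = "exchange"))
  metabolic_network(mets, rxns, "EX_in", "EX_out")
}

# Random small conservative network for the LP-vs-enumeration property.
# Species carry (CH2)_n formulas so any carbon-balanced reaction is also
# electron-balanced; a linear chain substrate -> ... -> product is decorated
# with random cross-links, a waste branch, reversibility, non-integer
# coefficients, and ATP side terms (non-negative on the main chain so the
# LP stays feasible at fixed uptake).
random_small_network <- function(seed) {
  set.seed(seed)
  n_int <- sample(1:3, 1)
  ids <- c("S", paste0("I", seq_len(n_int)), "P")
  carbons <- sample(1:4, length(ids), replace = TRUE)
  mets <- c(
    lapply(seq_along(ids), function(i)
      metabolite(ids[i], formula = sprintf("C%dH%d", carbons[i], 2 * carbons[i]),
                 role = if (ids[i] %in% c("S", "P")) "exchangeable"
                        else "internal")),
    list(metabolite("W", formula = "CH2", role = "exchangeable"),
         metabolite("atp", role = "cofactor", electrons = 0)))
  names(carbons) <- ids
  carbons <- c(carbons, W = 1)

  balanced <- function(from, to) {
    g <- .rat_gcd_test(carbons[from], carbons[to])
    stats::setNames(c(-(carbons[to] / g), carbons[from] / g), c(from, to))
  }
  rxns <- list()
  chain <- c("S", paste0("I", seq_len(n_int)), "P")
  for (k in seq_len(length(chain) - 1)) {
    st <- balanced(chain[k], chain[k + 1])
    atp_coef <- sample(0:2, 1)                 # chain never consumes ATP
    if (atp_coef > 0) st <- c(st, atp = atp_coef)
    scale <- sample(c(1, 1, 0.5), 1)           # occasional rational coefs
    rxns[[length(rxns) + 1]] <-
      reaction(paste0("R", k), st * scale,
               reversible = stats::runif(1) < 0.3)
  }
  # waste branch and a random cross-link (may consume ATP)
  rxns[[length(rxns) + 1]] <- reaction("RW", balanced(chain[2], "W"))
  from <- sample(chain[-length(chain)], 1)
  to <- sample(setdiff(chain[-1], from), 1)
  stx <- balanced(from, to)
  atp_coef <- sample(-1:1, 1)
  if (atp_coef != 0) stx <- c(stx, atp = atp_coef)
  rxns[[length(rxns) + 1]] <- reaction("RX", stx,
                                       reversible = stats::runif(1) < 0.3)
  rxns <- c(rxns, list(
    reaction("EX_S", c(S = 1), kind = "exchange"),
    reaction("EX_P", c(P = -1), kind = "exchange"),
    reaction("EX_W", c(W = -1), kind = "exchange"),
    reaction("EX_atp", c(atp = -1), kind = "exchange")))
  metabolic_network(mets, rxns, "EX_S", "EX_P")
}

.rat_gcd_test <- function(a, b) {
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

# every builtin substrate/product/route combination with a carbon product
all_builtin_networks <- function() {
  combos <- list(
    list("glucose", NULL, NULL), list("ethanol", "adhE", NULL),
    list("ethanol", "exaABC", "acs"), list("ethanol", "exaABC", "pta_ackA"),
    list("acetate", NULL, "acs"), list("acetate", NULL, "pta_ackA"))
  out <- list()
  for (cmb in combos) {
    for (pr in c("phb", "3hp", "pg")) {
      key <- paste(cmb[[1]], pr, cmb[[2]] %||% "", cmb[[3]] %||% "", sep = ":")
      out[[key]] <- builtin_network(cmb[[1]], pr, ethanol_route = cmb[[2]],
                                    acetate_route = cmb[[3]])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
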