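# Exact-rational two-phase simplex with Bland's rule.
#
# Solves   max c'x   s.t.  A x = b,  x >= 0
# with every tableau entry an exact rational, so there is no feasibility or
# optimality tolerance: the returned vertex and objective are exact. Bland's
# smallest-index pivoting rule guarantees termination on the degenerate
# LPs that stoichiometric models routinely produce. Problem sizes here are
# ~10 rows by ~25 columns, where exact pivoting costs microseconds.

# A is given as list(n=,d=) matrices; b, c as list(n=,d=) vectors.
.rlp_solve <- function(A, b, cc) {
  m <- nrow(A$n)
  n <- ncol(A$n)
  stopifnot(length(b$n) == m, length(cc$n) == n)

  # force b >= 0
  neg <- b$n < 0
  if (any(neg)) {
    A$n[neg, ] <- -A$n[neg, ]
    b$n[neg] <- -b$n[neg]
  }

  # tableau: columns 1..n real, n+1..n+m artificial, rhs kept separately
  Tn <- cbind(A$n, diag(m), b$n)
  Td <- cbind(A$d, matrix(1, m, m), b$d)
  basis <- n + seq_len(m)
  rhs_col <- n + m + 1L

  reduced_costs <- function(cost_n, cost_d, cols) {
    # rc_j = sum_i cB_i * T[i,j] - c_j, vectorized over columns
    rn <- -cost_n[cols]
    rd <- cost_d[cols]
    for (i in seq_len(m)) {
      cb <- basis[i]
      if (cost_n[cb] == 0) next
      term <- .rat_mul(rep(cost_n[cb], length(cols)), rep(cost_d[cb], length(cols)),
                       Tn[i, cols], Td[i, cols])
      r <- .rat_add(rn, rd, term$n, term$d)
      rn <- r$n; rd <- r$d
    }
    list(n = rn, d = rd)
  }

  pivot <- function(r, j) {
    # scale pivot row
    pn <- Tn[r, j]; pd <- Td[r, j]
    row <- .rat_div(Tn[r, ], Td[r, ], rep(pn, rhs_col), rep(pd, rhs_col))
    Tn[r, ] <<- row$n; Td[r, ] <<- row$d
    for (i in seq_len(m)) {
      if (i == r || Tn[i, j] == 0) next
      f <- list(n = Tn[i, j], d = Td[i, j])
      term <- .rat_mul(rep(f$n, rhs_col), rep(f$d, rhs_col), Tn[r, ], Td[r, ])
      upd <- .rat_sub(Tn[i, ], Td[i, ], term$n, term$d)
      Tn[i, ] <<- upd$n; Td[i, ] <<- upd$d
    }
    basis[r] <<- j
  }

  run_phase <- function(cost_n, cost_d, cols) {
    repeat {
      rc <- reduced_costs(cost_n, cost_d, cols)
      ent_idx <- which(rc$n < 0)
      if (length(ent_idx) == 0) return("optimal")
      j <- cols[min(ent_idx)]                      # Bland: smallest index
      pos <- which(Tn[, j] > 0)
      if (length(pos) == 0) return("unbounded")
      # ratio test: min rhs_i / T_ij, ties -> smallest basis index
      best <- NULL
      for (i in pos) {
        ratio <- .rat_div(Tn[i, rhs_col], Td[i, rhs_col], Tn[i, j], Td[i, j])
        if (is.null(best) || .rat_lt(ratio$n, ratio$d, best$ratio$n, best$ratio$d) ||
            (.rat_eq(ratio$n, ratio$d, best$ratio$n, best$ratio$d) &&
             basis[i] < basis[best$i])) {
          best <- list(i = i, ratio = ratio)
        }
      }
      pivot(best$i, j)
    }
  }

  # ---- phase 1: maximize -sum(artificials) ----
  cost1_n <- c(numeric(n), rep(-1, m))
  cost1_d <- rep(1, n + m)
  st <- run_phase(cost1_n, cost1_d, seq_len(n + m))
  # phase-1 objective value = sum of basic artificial rhs (negated)
  art_basic <- which(basis > n)
  infeas <- FALSE
  for (i in art_basic) if (Tn[i, rhs_col] != 0) infeas <- TRUE
  if (infeas) return(list(status = "infeasible"))

  # drive remaining zero-level artificials out of the basis
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    j <- which(Tn[i, seq_len(n)] != 0)
    if (length(j) > 0) pivot(i, j[1]) else drop_rows <- c(drop_rows, i)
  }
  if (length(drop_rows) > 0) {
    keep <- setdiff(seq_len(m), drop_rows)
    Tn <- Tn[keep, , drop = FALSE]
    Td <- Td[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- length(keep)
    # rebind closures' view of m via environment
  }

  # ---- phase 2: real objective, artificial columns barred ----
  cost2_n <- c(-cc$n, rep(0, ncol(Tn) - 1L - n))
  cost2_d <- c(cc$d, rep(1, ncol(Tn) - 1L - n))
  # we maximize c'x ; reduced-cost machinery above maximizes with cost vector,
  # using rc_j = cB'T_j - c_j, entering when rc_j < 0.
  cost2_n <- -cost2_n  # undo: store actual costs (artificials cost 0)
  st <- run_phase(cost2_n, cost2_d, seq_len(n))
  if (st == "unbounded") return(list(status = "unbounded"))

  xn <- numeric(n); xd <- rep(1, n)
  for (i in seq_len(m)) {
    if (basis[i] <= n) {
      xn[basis[i]] <- Tn[i, rhs_col]
      xd[basis[i]] <- Td[i, rhs_col]
    }
  }
  # objective value c'x
  on <- 0; od <- 1
  for (j in which(cc$n != 0 & xn != 0)) {
    term <- .rat_mul(cc$n[j], cc$d[j], xn[j], xd[j])
    o <- .rat_add(on, od, term$n, term$d)
    on <- o$n; od <- o$d
  }
  list(status = "optimal", x = list(n = xn, d = xd), obj = list(n = on, d = od))
}

# Parsimonious second stage: among optima of (A, b, c), return the solution
# minimizing sum(x) (total flux through the split, non-negative variables).
# Keeps the optimal objective as an exact extra equality row.
.rlp_solve_parsimonious <- function(A, b, cc) {
  first <- .rlp_solve(A, b, cc)
  if (first$status != "optimal") return(first)
  A2 <- list(n = rbind(A$n, cc$n), d = rbind(A$d, cc$d))
  b2 <- list(n = c(b$n, first$obj$n), d = c(b$d, first$obj$d))
  n <- ncol(A$n)
  c2 <- list(n = rep(-1, n), d = rep(1, n))
  second <- .rlp_solve(A2, b2, c2)
  if (second$status != "optimal") return(first)  # defensive; cannot happen
  list(status = "optimal", x = second$x, obj = first$obj)
}
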