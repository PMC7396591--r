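# Exact rational arithmetic on parallel numerator/denominator vectors.
# All denominators are kept positive and fractions fully reduced; numerators
# and denominators are stored as doubles but always hold exact integers, with
# an overflow guard at 2^52. This is ample for the small curated networks the
# package solves (coefficients are small rationals such as 5/2 or 1/3).

.rat_gcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(b > 0.5)) {
    nz <- b > 0.5
    r <- a
    r[nz] <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b <- r
    b[!nz] <- 0
  }
  a
}

.rat_check <- function(n, d) {
  if (any(abs(n) >= 2^52) || any(abs(d) >= 2^52))
    stop("exact rational arithmetic overflow", call. = FALSE)
  invisible(NULL)
}

# normalize: d > 0, gcd(n, d) = 1
.rat_norm <- function(n, d) {
  if (any(d == 0)) stop("zero denominator", call. = FALSE)
  s <- sign(d)
  n <- n * s
  d <- d * s
  g <- .rat_gcd(n, d)
  g[g == 0] <- 1
  n <- n / g
  d <- d / g
  .rat_check(n, d)
  list(n = n, d = d)
}

.rat_add <- function(n1, d1, n2, d2) {
  g <- .rat_gcd(d1, d2)
  g[g == 0] <- 1
  t1 <- d2 / g
  t2 <- d1 / g
  .rat_norm(n1 * t1 + n2 * t2, d1 * t1)
}

.rat_sub <- function(n1, d1, n2, d2) .rat_add(n1, d1, -n2, d2)

.rat_mul <- function(n1, d1, n2, d2) {
  # cross-cancel before multiplying to limit magnitude growth
  g1 <- .rat_gcd(n1, d2); g1[g1 == 0] <- 1
  g2 <- .rat_gcd(n2, d1); g2[g2 == 0] <- 1
  .rat_norm((n1 / g1) * (n2 / g2), (d1 / g2) * (d2 / g1))
}

.rat_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("rational division by zero", call. = FALSE)
  .rat_mul(n1, d1, d2, n2)
}

# a/b < c/d with b, d > 0
.rat_lt <- function(n1, d1, n2, d2) n1 * d2 < n2 * d1
.rat_eq <- function(n1, d1, n2, d2) n1 * d2 == n2 * d1

# Convert numerics to exact rationals by continued fractions. Inputs are
# expected to be "nice" (small-denominator) values such as stoichiometric
# coefficients or P/O ratios; anything not representable with denominator
# <= max_den to within 1e-9 relative error is rejected.
.as_rat <- function(x, max_den = 1e6) {
  n <- numeric(length(x))
  d <- numeric(length(x))
  for (k in seq_along(x)) {
    v <- x[k]
    if (!is.finite(v)) stop("non-finite coefficient", call. = FALSE)
    if (v == round(v) && abs(v) < 2^52) {
      n[k] <- round(v); d[k] <- 1
      next
    }
    # continued-fraction convergents
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    z <- abs(v)
    repeat {
      a <- floor(z)
      p2 <- a * p1 + p0
      q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      frac <- z - a
      if (frac < 1e-12) break
      z <- 1 / frac
    }
    if (q1 == 0 || abs(abs(v) - p1 / q1) > 1e-9 * max(1, abs(v)))
      stop(sprintf("coefficient %g is not a small rational", v), call. = FALSE)
    n[k] <- sign(v) * p1
    d[k] <- q1
  }
  .rat_norm(n, d)
}

# Parse "p/q" strings (or plain numbers) into exact rationals.
.parse_rat <- function(x) {
  if (is.numeric(x)) return(.as_rat(x))
  x <- as.character(x)
  n <- numeric(length(x)); d <- numeric(length(x))
  for (k in seq_along(x)) {
    s <- trimws(x[k])
    if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      n[k] <- as.numeric(parts[1]); d[k] <- as.numeric(parts[2])
    } else {
      r <- .as_rat(as.numeric(s))
      n[k] <- r$n; d[k] <- r$d
    }
  }
  .rat_norm(n, d)
}

.rat_to_num <- function(r) r$n / r$d
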