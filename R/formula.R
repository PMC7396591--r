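#' Elemental formulas, formula weights, and degrees of reduction
#'
#' `parse_formula()` parses a Hill-style chemical formula over the supported
#' elements (C, H, N, O, P, S) into an `elemental_formula` object — a named
#' integer vector of element counts. `formula_weight()` returns the average
#' formula weight in g/mol using a pinned table of IUPAC 2021 conventional
#' atomic weights. `degree_of_reduction()` returns the number of transferable
#' electrons per molecule under the standard CO2 / H2O / NH3 / H3PO4 / H2SO4
#' reference states:
#' \deqn{\gamma = 4C + H - 2O - 3N + 5P + 6S - charge}
#' so that CO2, H2O and NH3 all have \eqn{\gamma = 0} and, e.g., ethanol has
#' \eqn{\gamma = 12}.
#'
#' @param text a chemical formula string such as `"C4H6O2"`. An element symbol
#'   may appear once, optionally followed by a positive integer count.
#' @param f an `elemental_formula` (or a string, which is parsed first).
#' @param charge integer net charge of the species (electrons carried by the
#'   ion are added back, e.g. acetate C2H3O2 with charge -1 has
#'   \eqn{\gamma = 8}).
#' @return `parse_formula()`: an `elemental_formula`; `formula_weight()`:
#'   numeric g/mol; `degree_of_reduction()`: numeric electrons per molecule.
#' @examples
#' f <- parse_formula("C4H6O2")   # the PHB repeat unit
#' formula_weight(f)              # 86.09 g/mol
#' degree_of_reduction("C2H6O")   # ethanol: 12 electrons
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0)
    stop("formula must be a single non-empty string", call. = FALSE)
  text <- trimws(text)
  if (nchar(text) == 0) stop("formula must be a single non-empty string", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", text, call. = FALSE)
  counts <- stats::setNames(integer(0), character(0))
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(.atomic_weights))
      stop("unsupported element symbol: ", sym, call. = FALSE)
    k <- if (nchar(num) == 0) 1L else as.integer(num)
    if (is.na(k) || k <= 0L) stop("invalid element count in: ", tok, call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
  }
  new_elemental_formula(counts)
}

# pinned IUPAC 2021 conventional atomic weights, g/mol
.atomic_weights <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

# electrons contributed per atom under CO2/H2O/NH3/H3PO4/H2SO4 reference
.gamma_per_atom <- c(C = 4, H = 1, N = -3, O = -2, P = 5, S = 6)

new_elemental_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    stop("formula must contain at least one element", call. = FALSE)
  # canonical Hill order: C, H, then remaining alphabetical
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  structure(as.integer(counts[ord]), names = ord, class = "elemental_formula")
}

.as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stop("expected an elemental_formula or a formula string", call. = FALSE)
}

#' @rdname parse_formula
#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' @rdname parse_formula
#' @export
formula_weight <- function(f) {
  f <- .as_formula(f)
  sum(.atomic_weights[names(f)] * as.numeric(f))
}

#' @rdname parse_formula
#' @export
degree_of_reduction <- function(f, charge = 0) {
  f <- .as_formula(f)
  sum(.gamma_per_atom[names(f)] * as.numeric(f)) - charge
}

.carbon_count <- function(f) {
  if (is.null(f)) return(0L)
  f <- .as_formula(f)
  if ("C" %in% names(f)) as.integer(f[["C"]]) else 0L
}
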