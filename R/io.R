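#' Read and write network model files (JSON)
#'
#' The model file is JSON with top-level keys `metabolites` (objects with
#' `id`, `name`, `formula`, `charge`, `role`, and optional `electrons` for
#' carrier/cofactor pseudo-species without a formula), `reactions` (objects
#' with `id`, `enzyme`, `stoichiometry` mapping metabolite id to a number or
#' an exact-rational string such as `"2/3"`, `reversible`, `kind`),
#' `substrate_exchange`, `product_exchange` and `route_flags`. Coefficients
#' are written back as rational strings when they are not integers, so a
#' write/read round trip is exact.
#'
#' @param path path to a JSON model file.
#' @param validate check balance of conversion reactions on read
#'   (default `TRUE`).
#' @return `read_network_json()`: a `metabolic_network`.
#' @examples
#' net <- builtin_network("ethanol", "phb")
#' f <- tempfile(fileext = ".json")
#' write_network_json(net, f)
#' net2 <- read_network_json(f)
#' identical(stoichiometric_matrix(net), stoichiometric_matrix(net2))
#' @export
read_network_json <- function(path, validate = TRUE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions", "substrate_exchange",
                "product_exchange"))
    if (is.null(obj[[key]])) stop("model file lacks key: ", key, call. = FALSE)
  mets <- lapply(obj$metabolites, function(m)
    metabolite(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               formula = if (is.null(m$formula) || identical(m$formula, ""))
                 NULL else m$formula,
               charge = if (is.null(m$charge)) 0L else m$charge,
               role = if (is.null(m$role)) "internal" else m$role,
               electrons = m$electrons))
  rxns <- lapply(obj$reactions, function(r) {
    st <- unlist(lapply(r$stoichiometry, as.character))
    reaction(id = r$id, stoichiometry = st,
             enzyme = if (is.null(r$enzyme)) "" else r$enzyme,
             reversible = isTRUE(r$reversible),
             kind = if (is.null(r$kind)) "conversion" else r$kind)
  })
  metabolic_network(mets, rxns,
                    substrate_exchange = obj$substrate_exchange,
                    product_exchange = obj$product_exchange,
                    route_flags = if (is.null(obj$route_flags)) list()
                                  else obj$route_flags,
                    validate = validate)
}

#' @rdname read_network_json
#' @param net a `metabolic_network`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  mets <- lapply(net$metabolites, function(m) {
    out <- list(id = m$id, name = m$name,
                formula = if (is.null(m$formula)) NULL else format(m$formula),
                charge = m$charge, role = m$role, electrons = m$electrons)
    out[!vapply(out, is.null, TRUE)]
  })
  rxns <- lapply(net$reactions, function(r) {
    st <- as.list(ifelse(r$coef_d == 1, as.character(r$coef_n),
                         paste0(r$coef_n, "/", r$coef_d)))
    names(st) <- r$species
    list(id = r$id, enzyme = r$enzyme, stoichiometry = st,
         reversible = r$reversible, kind = r$kind)
  })
  jsonlite::write_json(
    list(metabolites = unname(mets), reactions = unname(rxns),
         substrate_exchange = net$substrate_exchange,
         product_exchange = net$product_exchange,
         route_flags = net$route_flags),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
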