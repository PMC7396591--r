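#' Fermentation time-course container and CSV reader
#'
#' A `fermentation_timecourse` is a validated data.frame of shake-flask or
#' fed-batch records: column `time_h` (strictly increasing), one or more
#' substrate concentration columns named `<substrate>_g_per_L`, and optional
#' `od600`, `cdw_g_per_L`, `product_g_per_L` and `fed_g_per_L` (cumulative
#' fed substrate, g/L-equivalent against broth volume; feeds are accounted
#' under a constant-volume approximation). All concentrations must be
#' non-negative.
#'
#' @param df a data.frame with the columns above.
#' @param path CSV file (comma-separated, dot decimal, header required).
#' @return a `fermentation_timecourse` (data.frame subclass).
#' @examples
#' ts <- fermentation_timecourse(data.frame(
#'   time_h = c(0, 54), ethanol_g_per_L = c(10, 0.32),
#'   product_g_per_L = c(0, 3.12)))
#' substrate_consumed(ts, "ethanol")
#' @export
fermentation_timecourse <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"time_h" %in% names(df))
    stop("missing required column: time_h", call. = FALSE)
  conc_cols <- grep("_g_per_L$", names(df), value = TRUE)
  if (length(setdiff(conc_cols, "fed_g_per_L")) == 0)
    stop("need at least one concentration column (<name>_g_per_L)",
         call. = FALSE)
  if (nrow(df) < 2) stop("need at least 2 records", call. = FALSE)
  if (any(diff(df$time_h) <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  num_cols <- c(conc_cols, intersect("od600", names(df)))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) stop("column ", cl, " is not numeric", call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in column ", cl, call. = FALSE)
  }
  class(df) <- c("fermentation_timecourse", "data.frame")
  df
}

#' @rdname fermentation_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fermentation_timecourse(df)
}

#' @rdname fermentation_timecourse
#' @param ts a `fermentation_timecourse`.
#' @export
write_timecourse <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.tc_value <- function(ts, col, t) {
  i <- which(abs(ts$time_h - t) < 1e-9)
  if (length(i) != 1)
    stop("time ", t, " h is not a sampled time point", call. = FALSE)
  ts[[col]][i]
}

#' Substrate consumed over an interval
#'
#' Consumption between two sampled time points:
#' `C(t0) - C(t1) + (fed(t1) - fed(t0))` using the cumulative `fed_g_per_L`
#' column when present (fed-batch bookkeeping). An apparently negative
#' consumption (evaporation or measurement noise) is clamped to 0 with a
#' warning. Both `t0` and `t1` must be sampled times; no extrapolation or
#' interpolation is performed, which makes consumption exactly additive over
#' adjacent intervals.
#'
#' @param ts a `fermentation_timecourse`.
#' @param name substrate name; the column used is `<name>_g_per_L`.
#' @param t0,t1 interval bounds in hours (default: first and last sample).
#' @return consumption in g/L (g/L-equivalent for fed-batch).
#' @examples
#' ts <- fermentation_timecourse(data.frame(
#'   time_h = c(0, 115), ethanol_g_per_L = c(1, 0),
#'   fed_g_per_L = c(0, 129.5)))
#' substrate_consumed(ts, "ethanol")   # 130.5
#' @export
substrate_consumed <- function(ts, name, t0 = min(ts$time_h),
                               t1 = max(ts$time_h)) {
  stopifnot(inherits(ts, "fermentation_timecourse"))
  col <- paste0(name, "_g_per_L")
  if (!col %in% names(ts))
    stop("unknown substrate: ", name, " (no column ", col, ")", call. = FALSE)
  if (!(t0 < t1)) stop("need t0 < t1", call. = FALSE)
  if (t0 < min(ts$time_h) - 1e-9 || t1 > max(ts$time_h) + 1e-9)
    stop("interval outside the sampled range (no extrapolation)", call. = FALSE)
  consumed <- .tc_value(ts, col, t0) - .tc_value(ts, col, t1)
  if ("fed_g_per_L" %in% names(ts))
    consumed <- consumed + (.tc_value(ts, "fed_g_per_L", t1) -
                              .tc_value(ts, "fed_g_per_L", t0))
  if (consumed < 0) {
    warning("apparent negative consumption (", signif(consumed, 3),
            " g/L) clamped to 0")
    consumed <- 0
  }
  consumed
}

#' Yield, content, and percent-of-theoretical arithmetic
#'
#' Scalar bookkeeping on measured (or simulated) fermentations:
#' `product_yield()` is product formed over substrate consumed (g/g, full
#' precision; display conventions round to 2-3 significant figures);
#' `phb_content()` is the polymer titer as a percentage of cell dry weight;
#' `percent_of_theoretical()` relates a measured yield to the stoichiometric
#' limit from [max_yield()] (displayed rounded to an integer percent).
#'
#' @param product_formed product formed, g/L.
#' @param substrate_consumed substrate consumed, g/L (> 0).
#' @return numeric at full precision (g/g or percent).
#' @examples
#' product_yield(3.12, 9.68)                  # 0.322... -> displays 0.32
#' percent_of_theoretical(0.32, 0.935)        # 34.2... -> displays 34
#' @export
product_yield <- function(product_formed, substrate_consumed) {
  if (!is.numeric(substrate_consumed) || any(substrate_consumed <= 0))
    stop("substrate_consumed must be > 0", call. = FALSE)
  if (any(product_formed < 0))
    stop("product_formed must be >= 0", call. = FALSE)
  product_formed / substrate_consumed
}

#' @rdname product_yield
#' @param product product titer, g/L.
#' @param cdw cell dry weight, g/L (> 0).
#' @export
phb_content <- function(product, cdw) {
  if (!is.numeric(cdw) || any(cdw <= 0)) stop("cdw must be > 0", call. = FALSE)
  100 * product / cdw
}

#' @rdname product_yield
#' @param measured measured yield, g/g.
#' @param theoretical theoretical yield, g/g (> 0).
#' @export
percent_of_theoretical <- function(measured, theoretical) {
  if (!is.numeric(theoretical) || any(theoretical <= 0))
    stop("theoretical yield must be > 0", call. = FALSE)
  100 * measured / theoretical
}

#' Summary of a fermentation time course
#'
#' Convenience wrapper reporting consumption, titer, yield, polymer content
#' (when CDW is recorded) and percent of a theoretical yield over the full
#' sampled interval.
#'
#' @param ts a `fermentation_timecourse`.
#' @param substrate substrate name (column `<substrate>_g_per_L`).
#' @param theoretical optional theoretical yield (g/g) for
#'   [percent_of_theoretical()].
#' @return a one-row data.frame with columns `consumed_g_per_L`,
#'   `product_g_per_L`, `yield_g_per_g`, `content_pct_cdw`,
#'   `pct_of_theoretical`.
#' @export
fermentation_summary <- function(ts, substrate, theoretical = NULL) {
  stopifnot(inherits(ts, "fermentation_timecourse"))
  consumed <- substrate_consumed(ts, substrate)
  titer <- if ("product_g_per_L" %in% names(ts))
    ts$product_g_per_L[nrow(ts)] - ts$product_g_per_L[1] else NA_real_
  yld <- if (!is.na(titer) && consumed > 0) product_yield(titer, consumed)
         else NA_real_
  content <- if ("cdw_g_per_L" %in% names(ts) && !is.na(titer) &&
                 ts$cdw_g_per_L[nrow(ts)] > 0)
    phb_content(ts$product_g_per_L[nrow(ts)], ts$cdw_g_per_L[nrow(ts)])
  else NA_real_
  pct <- if (!is.null(theoretical) && !is.na(yld))
    percent_of_theoretical(yld, theoretical) else NA_real_
  data.frame(consumed_g_per_L = consumed, product_g_per_L = titer,
             yield_g_per_g = yld, content_pct_cdw = content,
             pct_of_theoretical = pct)
}
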