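#' Targeted metabolite panel container and CSV reader
#'
#' A `metabolite_panel` holds long-format relative-quantification records:
#' one row per (metabolite, strain, stage, replicate) with a non-negative
#' `intensity` in arbitrary (pre-normalized) units. Undetectable
#' measurements are recorded as `NA` (the CSV reader also accepts the token
#' `"ND"` or an empty field). The panel operates on whatever normalized
#' intensities are supplied; no normalization of its own is applied.
#'
#' @param df data.frame with columns `metabolite`, `strain`, `stage`,
#'   `replicate`, `intensity`.
#' @param path CSV file in the long format above.
#' @return a `metabolite_panel` (data.frame subclass).
#' @examples
#' pan <- metabolite_panel(data.frame(
#'   metabolite = "lactate", strain = c("A", "A", "B", "B"),
#'   stage = "D1", replicate = c(1, 2, 1, 2),
#'   intensity = c(10, 12, 1, 1.2)))
#' fold_change(pan, "lactate", c("A", "D1"), c("B", "D1"))$ratio
#' @export
metabolite_panel <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("metabolite", "strain", "stage", "replicate", "intensity")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.character(df$intensity)) {
    v <- trimws(df$intensity)
    v[v %in% c("", "ND", "nd", "NA")] <- NA
    df$intensity <- as.numeric(v)
  }
  if (any(df$intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  class(df) <- c("metabolite_panel", "data.frame")
  df
}

#' @rdname metabolite_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(intensity = "character"))
  metabolite_panel(df)
}

#' @rdname metabolite_panel
#' @param panel a `metabolite_panel`.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$intensity <- ifelse(is.na(df$intensity), "ND",
                         format(df$intensity, digits = 15, trim = TRUE,
                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-cell summary: mean, SEM, replicate count
#'
#' Summarizes one (metabolite, strain, stage) cell of a panel: arithmetic
#' mean and standard error of the mean (sample standard deviation over
#' `sqrt(n)`) over detected replicates. A cell is flagged undetectable only
#' when all of its replicates are undetectable; partially detected cells are
#' summarized over the detected replicates (undetectable values are treated
#' as missing, not as zero, since no limit of detection is modeled).
#'
#' @param panel a `metabolite_panel`.
#' @param metabolite,strain,stage cell coordinates.
#' @return list with `mean`, `sem`, `n` (detected replicates),
#'   `undetectable`.
#' @examples
#' pan <- metabolite_panel(data.frame(
#'   metabolite = "pyruvate", strain = "A", stage = "D1",
#'   replicate = 1:7, intensity = 1:7))
#' summarize_cell(pan, "pyruvate", "A", "D1")   # mean 4, SEM 0.816
#' @export
summarize_cell <- function(panel, metabolite, strain, stage) {
  stopifnot(inherits(panel, "metabolite_panel"))
  sel <- panel$metabolite == metabolite & panel$strain == strain &
    panel$stage == stage
  if (!any(sel))
    stop("no such cell: ", metabolite, " / ", strain, " / ", stage,
         call. = FALSE)
  v <- panel$intensity[sel]
  det <- v[!is.na(v)]
  if (length(det) == 0)
    return(list(mean = NA_real_, sem = NA_real_, n = 0L, undetectable = TRUE))
  list(mean = mean(det),
       sem = if (length(det) > 1) stats::sd(det) / sqrt(length(det)) else 0,
       n = length(det), undetectable = FALSE)
}

#' Fold change between two panel cells
#'
#' Ratio of cell means (numerator over denominator) with a confidence
#' interval by first-order error propagation on the log-ratio:
#' `SE_log = sqrt((SEM_num/mean_num)^2 + (SEM_den/mean_den)^2)`,
#' `CI = ratio * exp(-+ z * SE_log)`. The ratio is computed on cell means
#' (not replicate-wise ratios), matching mean-plus-SEM presentation and
#' unpaired replicates. When the denominator cell is undetectable (or its
#' mean is zero) the result is flagged undefined with no ratio.
#'
#' @param panel a `metabolite_panel`.
#' @param metabolite metabolite name.
#' @param numerator,denominator length-2 character vectors `c(strain, stage)`.
#' @param conf confidence level for the propagated interval (default 0.95).
#' @return a `fold_change_result`: list with `metabolite`, `numerator`,
#'   `denominator`, `ratio`, `ci_lower`, `ci_upper`, `se_log`, `undefined`.
#' @export
fold_change <- function(panel, metabolite, numerator, denominator,
                        conf = 0.95) {
  stopifnot(inherits(panel, "metabolite_panel"),
            length(numerator) == 2, length(denominator) == 2)
  num <- summarize_cell(panel, metabolite, numerator[1], numerator[2])
  den <- summarize_cell(panel, metabolite, denominator[1], denominator[2])
  base <- list(metabolite = metabolite,
               numerator = paste(numerator, collapse = ":"),
               denominator = paste(denominator, collapse = ":"))
  if (den$undetectable || isTRUE(den$mean == 0) || num$undetectable) {
    return(structure(c(base, list(ratio = NA_real_, ci_lower = NA_real_,
                                  ci_upper = NA_real_, se_log = NA_real_,
                                  undefined = TRUE)),
                     class = "fold_change_result"))
  }
  ratio <- num$mean / den$mean
  se_log <- sqrt((num$sem / num$mean)^2 + (den$sem / den$mean)^2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(c(base, list(ratio = ratio,
                         ci_lower = ratio * exp(-z * se_log),
                         ci_upper = ratio * exp(z * se_log),
                         se_log = se_log, undefined = FALSE)),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<fold_change> %s %s / %s: undefined (undetectable)\n",
                x$metabolite, x$numerator, x$denominator))
  } else {
    cat(sprintf("<fold_change> %s %s / %s: %.3g [%.3g, %.3g]\n",
                x$metabolite, x$numerator, x$denominator,
                x$ratio, x$ci_lower, x$ci_upper))
  }
  invisible(x)
}

#' Stage-wise fold-change table between two strains
#'
#' Batch [fold_change()] over every metabolite measured in both strains at a
#' given stage, in deterministic alphabetical metabolite order.
#'
#' @param panel a `metabolite_panel`.
#' @param numerator_strain,denominator_strain strain labels.
#' @param stage stage label (e.g. `"D1"`).
#' @return data.frame with one row per shared metabolite and columns
#'   `metabolite`, `ratio`, `ci_lower`, `ci_upper`, `undefined`.
#' @export
stage_report <- function(panel, numerator_strain, denominator_strain, stage) {
  stopifnot(inherits(panel, "metabolite_panel"))
  in_num <- unique(panel$metabolite[panel$strain == numerator_strain &
                                      panel$stage == stage])
  in_den <- unique(panel$metabolite[panel$strain == denominator_strain &
                                      panel$stage == stage])
  shared <- sort(intersect(in_num, in_den))
  if (length(shared) == 0)
    stop("no shared metabolites between strains at stage ", stage,
         call. = FALSE)
  rows <- lapply(shared, function(m) {
    fc <- fold_change(panel, m, c(numerator_strain, stage),
                      c(denominator_strain, stage))
    data.frame(metabolite = m, ratio = fc$ratio, ci_lower = fc$ci_lower,
               ci_upper = fc$ci_upper, undefined = fc$undefined)
  })
  do.call(rbind, rows)
}
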