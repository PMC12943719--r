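# Activity table, SAR metrics and the active/low-active class comparison.
#
# IC50 values are stored in nM throughout; pIC50 converts to molar
# internally. Cells not measured (compounds that did not pass the 100 nM
# potency screen) are absent values ("nd" in the TSV), never zeros.

ASSAY_COLUMNS <- c("pde4b1_nM", "pde4a4_nM", "pde4d3_nM", "harbs_nM",
                   "tnfa_hwb_nM", "tnfa_hpbmc_nM", "caco2_nM")

#' Load an activity table
#'
#' Reads the tab-separated activity schema
#' `compound_id  series  pde4b1_nM  pde4a4_nM  pde4d3_nM  harbs_nM
#' tnfa_hwb_nM  tnfa_hpbmc_nM  caco2_nM  mned_mgkg`. Cells `nd`/`NA`/
#' empty become `NA`; any present value must be a positive number.
#'
#' @param path TSV path. The packaged transcription of the study's
#'   printed tables ships as `system.file("extdata", "pde4_activity.tsv",
#'   package = "dockhb")` and is used when `path` is `NULL`.
#' @return data.frame, one row per compound.
#' @export
load_activity_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pde4_activity.tsv", package = "dockhb")
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) return(raw)
  need <- c("compound_id", "series", ASSAY_COLUMNS, "mned_mgkg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("activity table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(raw$compound_id))
    stop("duplicate compound_id in activity table")
  for (col in c(ASSAY_COLUMNS, "mned_mgkg")) {
    v <- trimws(raw[[col]])
    v[v %in% c("", "nd", "ND", "NA", "-")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num <= 0))
    if (length(bad))
      stop("non-positive or non-numeric value '", v[bad[1]], "' in column ",
           col, " at row ", bad[1] + 1L, " (", raw$compound_id[bad[1]], ")")
    raw[[col]] <- num
  }
  raw
}

#' pIC50 transform
#'
#' @param ic50_nM IC50 in nanomolar; must be positive.
#' @return `-log10(IC50 in molar)`.
#' @export
pic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0))
    stop("pic50 requires positive IC50 values (nM)")
  -log10(ic50_nM * 1e-9)
}

#' Most (or least) potent compound of a series in one assay
#'
#' @param records activity data.frame from [load_activity_table()].
#' @param series series label (e.g. `"3"`).
#' @param assay assay column name (default `"pde4b1_nM"`).
#' @param which `"min"` (most potent) or `"max"`.
#' @return list with `compound_id` and `value` (nM).
#' @export
series_extreme <- function(records, series, assay = "pde4b1_nM",
                           which = c("min", "max")) {
  which <- match.arg(which)
  sel <- records$series == series & !is.na(records[[assay]])
  if (!any(sel))
    stop("no record in series '", series, "' with assay ", assay)
  v <- records[[assay]][sel]
  id <- records$compound_id[sel]
  k <- if (which == "min") which.min(v) else which.max(v)
  list(compound_id = id[k], value = v[k])
}

#' Potency filter
#'
#' Keeps records with assay value present and `<= threshold` (inclusive,
#' matching the study's "IC50 <= 100 nM" advancement rule).
#'
#' @param records activity data.frame.
#' @param assay assay column (default `"pde4b1_nM"`).
#' @param threshold_nM inclusive cutoff (default 100).
#' @return subset data.frame.
#' @export
filter_potent <- function(records, assay = "pde4b1_nM",
                          threshold_nM = 100) {
  records[!is.na(records[[assay]]) & records[[assay]] <= threshold_nM, ,
          drop = FALSE]
}

#' Selectivity ratio between two assays of one compound
#'
#' @param record single-row activity data.frame (or list).
#' @param assay_num,assay_den assay column names; the ratio is
#'   `IC50(num) / IC50(den)`.
#' @return dimensionless ratio.
#' @export
selectivity_ratio <- function(record, assay_num, assay_den) {
  a <- record[[assay_num]]
  b <- record[[assay_den]]
  if (is.na(a) || is.na(b))
    stop("selectivity_ratio: missing value for ", assay_num, " or ",
         assay_den)
  a / b
}

#' Maximal-not-emetic-dose fold versus a reference compound
#'
#' @param record,reference_record single-row activity data.frames with
#'   `mned_mgkg` present.
#' @return `mned(record) / mned(reference)`.
#' @export
mned_fold <- function(record, reference_record) {
  a <- record[["mned_mgkg"]]
  b <- reference_record[["mned_mgkg"]]
  if (is.na(a) || is.na(b)) stop("mned_fold: missing MNED value")
  a / b
}

#' Modeling class definition (active vs low-active)
#'
#' The eight active (A) and eight very-low-active (I) ligands selected
#' for the docking/minimization comparison, with the PDE4B1 IC50 ranges
#' used as a fallback when a compound is in neither list.
#'
#' @param active_members,inactive_members compound id vectors.
#' @param active_range,inactive_range numeric length-2 PDE4B1 IC50
#'   windows in nM.
#' @return list of class `dockhb_classdef`.
#' @export
class_definition <- function(
    active_members = c("Roflumilast", "2c", "2e", "2f", "2n", "2p",
                       "3a", "3k"),
    inactive_members = c("Rolipram", "2i", "2h", "2o", "4f", "5d",
                         "7", "10a"),
    active_range = c(0.69, 19.54),
    inactive_range = c(520, 6700)) {
  both <- intersect(active_members, inactive_members)
  if (length(both))
    stop("definition error: compound(s) in both classes: ",
         paste(both, collapse = ", "))
  stopifnot(active_range[2] < inactive_range[1])
  structure(list(active_members = active_members,
                 inactive_members = inactive_members,
                 active_range = active_range,
                 inactive_range = inactive_range),
            class = "dockhb_classdef")
}

#' Assign the modeling class of compounds
#'
#' Membership lists are authoritative: the study enumerates its eight
#' active and eight low-active ligands explicitly, and several potent
#' compounds inside the active IC50 window were simply not selected for
#' modeling. With `use_ranges = TRUE` a compound in neither list is
#' classed by its PDE4B1 IC50 falling inside the active or inactive
#' window; anything else is `unassigned`.
#'
#' @param records activity data.frame (vectorised over rows).
#' @param definition a [class_definition()].
#' @param use_ranges apply the IC50-window fallback to unlisted
#'   compounds (default `FALSE`).
#' @return character vector of `"A"`, `"I"`, `"unassigned"`.
#' @export
assign_modeling_class <- function(records, definition = class_definition(),
                                  use_ranges = FALSE) {
  out <- rep("unassigned", nrow(records))
  if (use_ranges) {
    ic <- records$pde4b1_nM
    inside <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]
    out[inside(ic, definition$active_range)] <- "A"
    out[inside(ic, definition$inactive_range)] <- "I"
  }
  out[records$compound_id %in% definition$active_members] <- "A"
  out[records$compound_id %in% definition$inactive_members] <- "I"
  out
}

#' Compare a metric between the active and low-active classes
#'
#' Two-sided Welch two-sample t-test by default; a Wilcoxon rank-sum
#' alternative is available since the distributional form of pooled
#' bond distances is not guaranteed.
#'
#' @param values_A,values_I numeric vectors (at least 2 values each).
#' @param alpha significance level (default 0.05).
#' @param metric_name label carried into the result.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return list of class `dockhb_comparison` with `metric_name`,
#'   `mean_A`, `mean_I`, `n_A`, `n_I`, `statistic`, `p_value`,
#'   `significant`, `alpha`, `method`.
#' @export
compare_classes <- function(values_A, values_I, alpha = 0.05,
                            metric_name = "metric",
                            method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  values_A <- values_A[is.finite(values_A)]
  values_I <- values_I[is.finite(values_I)]
  if (length(values_A) < 2L || length(values_I) < 2L)
    stop("compare_classes requires at least 2 values per class")
  if (method == "welch") {
    # t.test errors when both samples are constant; identical constant
    # samples are a well-defined no-difference case
    if (stats::sd(values_A) == 0 && stats::sd(values_I) == 0 &&
        mean(values_A) == mean(values_I)) {
      stat <- 0; p <- 1
    } else {
      ht <- stats::t.test(values_A, values_I, var.equal = FALSE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    ht <- stats::wilcox.test(values_A, values_I, exact = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(
    metric_name = metric_name,
    mean_A = mean(values_A), mean_I = mean(values_I),
    n_A = length(values_A), n_I = length(values_I),
    statistic = stat, p_value = p,
    significant = p < alpha, alpha = alpha, method = method
  ), class = "dockhb_comparison")
}

#' @export
print.dockhb_comparison <- function(x, ...) {
  cat("<dockhb_comparison> ", x$metric_name, ": mean A ",
      format(x$mean_A, digits = 4), " vs mean I ",
      format(x$mean_I, digits = 4), " (n=", x$n_A, "/", x$n_I, "), ",
      x$method, " p = ", format.pval(x$p_value, digits = 3),
      if (x$significant) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Flatten comparison results to the report table
#'
#' @param comparisons list of `dockhb_comparison` objects.
#' @return data.frame `metric`, `mean_A`, `mean_I`, `n_A`, `n_I`,
#'   `statistic`, `p_value`.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) data.frame(
    metric = x$metric_name, mean_A = x$mean_A, mean_I = x$mean_I,
    n_A = x$n_A, n_I = x$n_I, statistic = x$statistic,
    p_value = x$p_value, stringsAsFactors = FALSE
  )))
}
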