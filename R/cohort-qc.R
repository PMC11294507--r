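#' Flag per-group IQR outliers in a cohort of diaphragm indices
#'
#' Within each group (e.g. GOLD stage), values lying more than 1.5 times
#' the interquartile range beyond the quartiles are flagged:
#' below Q1 - 1.5 IQR or above Q3 + 1.5 IQR. Quartiles use linear
#' interpolation between order statistics (the [stats::quantile()] type-7
#' default). Groups with fewer than 4 records are skipped with a warning.
#'
#' @param records data frame with columns `subject_id`, `group` and a
#'   value column (default `diaphragm_index`).
#' @param value_col name of the value column.
#' @return Data frame with columns `subject_id`, `group`, the value column,
#'   `lower`, `upper` and `is_outlier`, one row per record in a
#'   sufficiently large group.
#' @export
flag_outliers <- function(records, value_col = "diaphragm_index") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    dct_error("records must be a non-empty data frame",
              "diaphragmct_parameter_error")
  stopifnot(all(c("subject_id", "group", value_col) %in% names(records)))
  out <- list()
  for (g in unique(records$group)) {
    sub <- records[records$group == g, , drop = FALSE]
    if (nrow(sub) < 4L) {
      warning("group '", g, "' has fewer than 4 records; skipped")
      next
    }
    v <- sub[[value_col]]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    out[[length(out) + 1L]] <- data.frame(
      subject_id = sub$subject_id, group = g, value = v,
      lower = lo, upper = hi, is_outlier = v < lo | v > hi,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    dct_error("no group had at least 4 records", "diaphragmct_parameter_error")
  res <- do.call(rbind, out)
  names(res)[names(res) == "value"] <- value_col
  rownames(res) <- NULL
  res
}

#' Per-group summaries of a cohort
#'
#' Mean, sample SD (n - 1 denominator) and range per group, mirroring the
#' "mean +/- SD (range)" reporting convention; SD is `NA` for single-record
#' groups. Groups are ordered by label.
#'
#' @inheritParams flag_outliers
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_groups <- function(records, value_col = "diaphragm_index") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    dct_error("records must be a non-empty data frame",
              "diaphragmct_parameter_error")
  stopifnot(all(c("group", value_col) %in% names(records)))
  groups <- sort(unique(records$group))
  res <- do.call(rbind, lapply(groups, function(g) {
    v <- records[[value_col]][records$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Tabulate visually assigned segmentation-defect labels
#'
#' Defect vocabulary used when segmentations are visually inspected:
#' `none`, `minor` (absence of less than half of one or both hemidiaphragm
#' domes and/or a small spurious inclusion) and `major` (absence of more
#' than half, and/or a significant spurious inclusion). Inspection itself
#' is manual; this helper only tabulates rates from a label column.
#'
#' @param labels character vector of labels in `c("none", "minor", "major")`.
#' @return Data frame with `label`, `n` and `percent`.
#' @export
tabulate_defects <- function(labels) {
  if (!all(labels %in% c("none", "minor", "major")))
    dct_error("defect labels must be 'none', 'minor' or 'major'",
              "diaphragmct_parameter_error")
  lv <- factor(labels, levels = c("none", "minor", "major"))
  tab <- table(lv)
  data.frame(label = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(labels),
             stringsAsFactors = FALSE)
}
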