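#' Neutralise per-parameter extraction outliers
#'
#' For each feature column independently, z-scores are computed once from the
#' raw column mean and standard deviation; values with |z| above the threshold
#' are replaced by the raw column median. A single pass: z-scores are not
#' recomputed after replacement, and the median is that of the raw column
#' including the outliers. Zero-variance columns are skipped with a warning
#' (z is undefined there). The default threshold of 3.29 corresponds to the
#' two-sided 0.001 tail of the standard normal.
#'
#' @param table feature table (data.frame with `call_id`, `original_label`
#'   and numeric feature columns).
#' @param z_threshold absolute z-score above which a value is an outlier.
#' @param columns feature columns to screen; defaults to all of
#'   [feature_columns()] (MDS coordinates included).
#' @return list with `table` (cleaned feature table) and `report`, a list with
#'   `n_values_replaced`, `n_calls_affected`, `z_threshold` and
#'   `per_parameter` (named replacement counts).
#' @export
replace_outliers <- function(table, z_threshold = 3.29,
                             columns = feature_columns(table)) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  if (nrow(table) < 3L) stop("need at least 3 calls to screen outliers")
  affected <- rep(FALSE, nrow(table))
  per_param <- stats::setNames(integer(length(columns)), columns)
  for (col in columns) {
    x <- table[[col]]
    if (!is.numeric(x)) stop("column '", col, "' is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("column '", col, "' has zero variance; no replacements")
      next
    }
    z <- (x - mean(x)) / s
    out <- abs(z) > z_threshold
    if (any(out)) {
      table[[col]][out] <- stats::median(x)
      per_param[col] <- sum(out)
      affected <- affected | out
    }
  }
  list(table = table,
       report = list(n_values_replaced = sum(per_param),
                     n_calls_affected = sum(affected),
                     z_threshold = z_threshold,
                     per_parameter = as.list(per_param)))
}
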