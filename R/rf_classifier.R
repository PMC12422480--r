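#' Random-forest configuration
#'
#' Defaults follow common repertoire-classification practice: 1000 trees and
#' mtry = floor(sqrt(p)) features tried at each split (5 for the default
#' 31-feature table), with per-call weights proportional to the inverse of the
#' class's relative frequency so rare call types are adequately oversampled.
#'
#' @param n_trees number of trees.
#' @param mtry features tried per split; `NULL` means floor(sqrt(p)).
#' @param weighting `"case"` (default) applies the inverse-frequency weights as
#'   per-observation bootstrap sampling weights; `"class"` instead applies them
#'   as class weights in the splitting rule; `"none"` fits an unweighted
#'   forest (baseline for assessing the weighting).
#' @param seed integer seed; fixes bootstrap draws, split sampling and
#'   importance permutations.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000L, mtry = NULL,
                      weighting = c("case", "class", "none"), seed = 1L) {
  weighting <- match.arg(weighting)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 weighting = weighting, seed = as.integer(seed)),
            class = "rf_config")
}

# normalised inverse-frequency weights: mean 1 over calls, so a class of size
# n_c gets per-call weight N / (k * n_c)
inverse_frequency_weights <- function(labels) {
  n_c <- table(labels)
  w <- as.numeric(length(labels) / (length(n_c) * n_c[as.character(labels)]))
  w
}

#' Fit the class-weighted random forest and collect out-of-bag predictions
#'
#' Wraps [ranger::ranger()] with inverse-class-frequency case weights driving
#' the bootstrap, permutation (mean-decrease-accuracy) importance, and a fixed
#' seed. Out-of-bag votes are aggregated explicitly from the in-bag counts so
#' the tie-break is deterministic: the class with the larger total weight wins,
#' then lexicographic label order.
#'
#' @param table feature table (columns `call_id`, `original_label`, features).
#' @param cfg an [rf_config()].
#' @return object of class `weighted_rf`: list with `model` (the ranger fit),
#'   `oob_predictions` (factor, one per call), `labels` (factor of original
#'   labels), `case_weights`, `feature_names`, `cfg`.
#' @export
fit_weighted_forest <- function(table, cfg = rf_config()) {
  feats <- feature_columns(table)
  x <- as.matrix(table[feats])
  if (anyNA(x)) stop("feature table contains missing values; clean it first")
  labels <- if (is.factor(table$original_label)) table$original_label
            else factor(table$original_label)
  sizes <- table(labels)
  if (any(sizes == 0L)) stop("empty class: ", paste(names(sizes)[sizes == 0L], collapse = ", "))
  if (any(sizes == 1L))
    warning("class(es) with a single call: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "),
            " (OOB prediction still defined)")
  p <- length(feats)
  mtry <- if (is.null(cfg$mtry)) floor(sqrt(p)) else cfg$mtry
  if (mtry > p) stop("mtry (", mtry, ") exceeds feature count (", p, ")")
  w <- inverse_frequency_weights(labels)

  args <- list(x = x, y = labels, num.trees = cfg$n_trees, mtry = mtry,
               importance = "permutation", keep.inbag = TRUE,
               seed = cfg$seed, num.threads = 1L, verbose = FALSE)
  if (cfg$weighting == "case") {
    args$case.weights <- w
  } else if (cfg$weighting == "class") {
    cw <- as.numeric(length(labels) / (nlevels(labels) * table(labels)))
    args$class.weights <- cw
  }
  model <- do.call(ranger::ranger, args)

  votes <- stats::predict(model, data = x, predict.all = TRUE,
                          num.threads = 1L)$predictions
  inbag <- matrix(unlist(model$inbag.counts), nrow = nrow(x))
  lev <- model$forest$levels
  class_weight <- stats::setNames(as.numeric(length(labels) /
                                    (nlevels(labels) * sizes)), names(sizes))
  oob <- character(nrow(x))
  never_oob <- 0L
  for (i in seq_len(nrow(x))) {
    out_trees <- inbag[i, ] == 0L
    vi <- votes[i, if (any(out_trees)) out_trees else TRUE]
    if (!any(out_trees)) never_oob <- never_oob + 1L
    tab <- tabulate(vi, nbins = length(lev))
    top <- which(tab == max(tab))
    if (length(top) > 1L) {                 # tie-break: weight, then label order
      cw_top <- class_weight[lev[top]]
      top <- top[cw_top == max(cw_top)]
      top <- top[order(lev[top])][1]
    }
    oob[i] <- lev[top]
  }
  if (never_oob > 0L)
    warning(never_oob, " call(s) were in-bag in every tree; ",
            "all-tree majority used for them")
  structure(list(model = model,
                 oob_predictions = factor(oob, levels = levels(labels)),
                 labels = labels, case_weights = w,
                 feature_names = feats, mtry = mtry, cfg = cfg),
            class = "weighted_rf")
}

#' @export
print.weighted_rf <- function(x, ...) {
  acc <- mean(x$oob_predictions == x$labels)
  cat(sprintf("<weighted_rf> %d trees, mtry %d, %d calls, %d classes; OOB accuracy %.3f\n",
              x$cfg$n_trees, x$mtry, length(x$labels), nlevels(x$labels), acc))
  invisible(x)
}

#' Build the out-of-bag confusion matrix
#'
#' Rows are original labels, columns the out-of-bag predictions; the per-row
#' classification error is 1 - diagonal/rowsum.
#'
#' @param predictions factor or character of predicted labels (e.g.
#'   `fit$oob_predictions`), one per call.
#' @param labels factor or character of original labels, same length.
#' @return object of class `confusion_matrix`: list with `labels`, `counts`
#'   (k x k integer matrix), `row_errors`, `trace`, `total`.
#' @export
oob_confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions (", length(predictions), ") and labels (",
         length(labels), ") differ in length")
  lev <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  extra <- setdiff(unique(as.character(predictions)), lev)
  if (length(extra))
    stop("predicted label(s) not in the label set: ", paste(extra, collapse = ", "))
  counts <- table(factor(labels, levels = lev),
                  factor(predictions, levels = lev))
  as_confusion_matrix(unclass(counts))
}

#' Construct a confusion matrix object from a square count matrix
#'
#' @param counts square numeric matrix, rows = original label, columns =
#'   predicted label, with identical row and column name order.
#' @param total optional stated grand total overriding `sum(counts)` (used
#'   when reproducing published tables whose cells do not add up to the stated
#'   sample size).
#' @return object of class `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, total = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- colnames(counts) <- paste0("class", seq_len(nrow(counts)))
  if (!identical(rownames(counts), colnames(counts)))
    stop("row and column labels must match (same order)")
  rs <- rowSums(counts)
  structure(list(labels = rownames(counts),
                 counts = counts,
                 row_errors = ifelse(rs > 0, 1 - diag(counts) / rs, NA_real_),
                 trace = sum(diag(counts)),
                 total = if (is.null(total)) sum(counts) else total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d calls, agreement %.1f%%\n",
              length(x$labels), x$total, 100 * x$trace / x$total))
  m <- cbind(x$counts, classification_error = round(x$row_errors, 3))
  print(m)
  invisible(x)
}

#' Exact binomial test of classification agreement against chance
#'
#' Tests the number of correctly classified calls (the confusion-matrix trace)
#' against the chance level 1/k, where k is the number of call types, using
#' the exact two-tailed binomial test (minimum-likelihood two-sided method).
#'
#' @param cm a `confusion_matrix`.
#' @return list with `n_agree`, `n_total`, `chance_level` (= 1/k), `p_value`,
#'   `two_tailed = TRUE`.
#' @export
chance_test <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- length(cm$labels)
  if (k == 0L) stop("empty confusion matrix")
  ht <- stats::binom.test(cm$trace, cm$total, p = 1 / k,
                          alternative = "two.sided")
  list(n_agree = cm$trace, n_total = cm$total, chance_level = 1 / k,
       p_value = ht$p.value, two_tailed = TRUE)
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' @param fit a `weighted_rf` from [fit_weighted_forest()].
#' @return named numeric vector, sorted decreasing.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "weighted_rf"))
  sort(fit$model$variable.importance, decreasing = TRUE)
}

#' Write / read a confusion matrix as CSV
#'
#' Dialect: first column holds the row labels, then one column per predicted
#' label, and a final `classification_error` column; counts are integers.
#'
#' @param cm a `confusion_matrix`.
#' @param path CSV path.
#' @return `path` invisibly / a `confusion_matrix`.
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(call_type = cm$labels, cm$counts,
                   classification_error = round(cm$row_errors, 3),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion
#' @param total optional stated grand total (see [as_confusion_matrix()]).
#' @export
read_confusion <- function(path, total = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  counts <- as.matrix(df[, setdiff(names(df)[-1], "classification_error"),
                         drop = FALSE])
  rownames(counts) <- labels
  if (!identical(labels, colnames(counts)))
    stop("confusion CSV row and column labels disagree")
  as_confusion_matrix(counts, total = total)
}

#' The published 15-type confusion matrix over the putative repertoire
#'
#' The printed out-of-bag confusion matrix of the wild-bonobo study this
#' package's pipeline reproduces (15 putative call types, 1506 tabulated calls
#' of a stated 1509), shipped as plain CSV. Useful for exercising
#' [resolve_repertoire()] without audio.
#'
#' @param total stated grand total; defaults to the published 1509.
#' @return a `confusion_matrix`.
#' @export
published_confusion <- function(total = 1509L) {
  read_confusion(system.file("extdata", "table1_confusion.csv",
                             package = "vocrep", mustWork = TRUE),
                 total = total)
}
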