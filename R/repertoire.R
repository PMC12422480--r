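#' Resolve a putative repertoire from its confusion matrix
#'
#' Applies the plurality criterion: a call type is retained (deemed
#' acoustically discriminable) iff the diagonal count is the strict maximum of
#' its row — the classifier assigned a plurality of its calls to their own
#' label. Otherwise the type is relabelled as the call type it was most often
#' classified as. All decisions are read off the single input matrix; there is
#' no retraining after a merge (an optional fixed-point mode is available via
#' `iterate`, off by default).
#'
#' Edge rules: a tie that includes the diagonal retains the row
#' (conservative); a tie among off-diagonal maxima targets the
#' lexicographically first label; a cycle among non-retained types is merged
#' into the cycle member with the largest row sum; a target that is itself
#' merged is followed transitively to a retained type. All such events are
#' recorded in the mapping's notes.
#'
#' @param cm a `confusion_matrix`.
#' @param iterate if `TRUE`, the rule is reapplied on the merged matrix until
#'   a fixed point (not the default procedure).
#' @return object of class `repertoire_mapping`: data.frame with columns
#'   `original`, `target`, `retained`, `note`.
#' @export
resolve_repertoire <- function(cm, iterate = FALSE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  mapping <- resolve_once(cm)
  if (iterate) {
    repeat {
      merged <- merge_confusion(cm, mapping)
      nxt <- resolve_once(merged)
      if (all(nxt$retained)) break
      # compose: originals follow their target's onward mapping
      idx <- match(mapping$target, nxt$original)
      mapping$target <- nxt$target[idx]
      mapping$retained <- mapping$retained & nxt$retained[idx]
      cm <- merged
    }
  }
  mapping
}

resolve_once <- function(cm) {
  counts <- cm$counts
  labels <- cm$labels
  k <- length(labels)
  retained <- logical(k)
  target <- integer(k)
  note <- character(k)
  for (i in seq_len(k)) {
    row <- counts[i, ]
    m <- max(row)
    if (row[i] == m) {
      retained[i] <- TRUE
      target[i] <- i
      if (sum(row == m) > 1L)
        note[i] <- "tie for row maximum includes own label; retained"
    } else {
      cand <- which(row == m)
      if (length(cand) > 1L) {
        cand <- cand[order(labels[cand])][1]
        note[i] <- "tie among off-diagonal maxima; lexicographically first target"
      }
      target[i] <- cand
    }
  }

  # break cycles among non-retained types: the member with the largest row sum
  # (lexicographic label on ties) becomes the retained representative
  repeat {
    cycle <- find_cycle(target, retained)
    if (is.null(cycle)) break
    rs <- rowSums(counts)[cycle]
    win <- cycle[rs == max(rs)]
    win <- win[order(labels[win])][1]
    retained[win] <- TRUE
    target[win] <- win
    note[win] <- paste0("cycle among {",
                        paste(labels[cycle], collapse = ", "),
                        "}; retained as largest row sum")
  }

  # follow chains to a retained type
  final <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    hops <- 0L
    while (!retained[j]) {
      j <- target[j]
      hops <- hops + 1L
      if (hops > k) stop("internal error: unresolved mapping chain")  # nocov
    }
    final[i] <- j
    if (hops > 1L)
      note[i] <- paste0(note[i], if (nzchar(note[i])) "; ",
                        "chain followed through ", hops, " merges")
  }

  structure(data.frame(original = labels, target = labels[final],
                       retained = retained, note = note,
                       stringsAsFactors = FALSE),
            class = c("repertoire_mapping", "data.frame"))
}

# first cycle reachable among non-retained nodes, or NULL
find_cycle <- function(target, retained) {
  k <- length(target)
  for (s in which(!retained)) {
    path <- integer(0)
    j <- s
    while (!retained[j]) {
      pos <- match(j, path)
      if (!is.na(pos)) return(path[pos:length(path)])
      path <- c(path, j)
      j <- target[j]
    }
  }
  NULL
}

# collapse a confusion matrix along a mapping (for the iterate mode)
merge_confusion <- function(cm, mapping) {
  tgt <- mapping$target[match(cm$labels, mapping$original)]
  lev <- sort(unique(tgt))
  g <- factor(tgt, levels = lev)
  counts <- rowsum(t(rowsum(cm$counts, g)), g)
  counts <- counts[lev, lev, drop = FALSE]
  as_confusion_matrix(counts, total = cm$total)
}

#' @export
print.repertoire_mapping <- function(x, ...) {
  cat(sprintf("<repertoire_mapping> %d original -> %d retained call types\n",
              nrow(x), sum(x$retained)))
  merged <- x[!x$retained, , drop = FALSE]
  if (nrow(merged))
    cat(paste0("  ", merged$original, " -> ", merged$target, collapse = "\n"), "\n")
  invisible(x)
}

#' Relabel a feature table along a repertoire mapping
#'
#' @param table feature table with an `original_label` column.
#' @param mapping a `repertoire_mapping`.
#' @return the table with `original_label` rewritten to the mapped (retained)
#'   labels; feature values and row count untouched.
#' @export
apply_mapping <- function(table, mapping) {
  stopifnot(inherits(mapping, "repertoire_mapping"))
  unknown <- setdiff(unique(table$original_label), mapping$original)
  if (length(unknown))
    stop("label(s) missing from mapping: ", paste(unknown, collapse = ", "))
  table$original_label <-
    mapping$target[match(table$original_label, mapping$original)]
  table
}

#' Summarise a resolution: agreement, errors, retained types, merges
#'
#' @param cm the `confusion_matrix` the mapping was derived from.
#' @param mapping the corresponding `repertoire_mapping`.
#' @return list with `trace`, `total`, `agreement_pct`, `error_pct`,
#'   `chance_level_pct`, `p_value` (exact two-tailed binomial against 1/k),
#'   `row_errors`, `n_retained`, `retained`, `merges` (named character vector,
#'   original -> target).
#' @export
summarize_repertoire <- function(cm, mapping) {
  stopifnot(inherits(cm, "confusion_matrix"),
            inherits(mapping, "repertoire_mapping"))
  if (!setequal(cm$labels, mapping$original))
    stop("mapping and confusion matrix carry different label sets")
  ct <- chance_test(cm)
  merged <- mapping[!mapping$retained, , drop = FALSE]
  list(trace = cm$trace, total = cm$total,
       agreement_pct = 100 * cm$trace / cm$total,
       error_pct = 100 * (1 - cm$trace / cm$total),
       chance_level_pct = 100 / length(cm$labels),
       p_value = ct$p_value,
       row_errors = stats::setNames(cm$row_errors, cm$labels),
       n_retained = sum(mapping$retained),
       retained = mapping$original[mapping$retained],
       merges = stats::setNames(merged$target, merged$original))
}

#' Write / read a repertoire mapping as JSON
#'
#' One object per original call type: `{target, retained, note}`.
#'
#' @param mapping a `repertoire_mapping`.
#' @param path JSON path.
#' @return `path` invisibly / a `repertoire_mapping`.
#' @export
write_mapping <- function(mapping, path) {
  obj <- lapply(seq_len(nrow(mapping)), function(i)
    list(target = mapping$target[i], retained = mapping$retained[i],
         note = mapping$note[i]))
  names(obj) <- mapping$original
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(data.frame(original = names(obj),
                       target = vapply(obj, `[[`, character(1), "target"),
                       retained = vapply(obj, `[[`, logical(1), "retained"),
                       note = vapply(obj, `[[`, character(1), "note"),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("repertoire_mapping", "data.frame"))
}
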