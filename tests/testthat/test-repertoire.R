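cm_from <- function(m, labels = LETTERS[seq_len(nrow(m))], total = NULL) {
  dimnames(m) <- list(labels, labels)
  as_confusion_matrix(m, total = total)
}

test_that("an identity-patterned matrix retains every call type", {
  cm <- cm_from(diag(c(5, 9, 4)))
  map <- resolve_repertoire(cm)
  expect_true(all(map$retained))
  expect_identical(map$target, map$original)
})

test_that("a merged type is relabelled to its modal prediction", {
  m <- rbind(c(2, 6, 1),
             c(0, 9, 0),
             c(1, 0, 8))
  map <- resolve_repertoire(cm_from(m))
  expect_identical(map$retained, c(FALSE, TRUE, TRUE))
  expect_identical(map$target, c("B", "B", "C"))
})

test_that("chains are followed transitively to a retained type", {
  # A's plurality goes to B, B's plurality goes to C, C retained
  m <- rbind(c(1, 5, 0),
             c(0, 2, 6),
             c(0, 0, 9))
  map <- resolve_repertoire(cm_from(m))
  expect_identical(map$target, c("C", "C", "C"))
  expect_identical(sum(map$retained), 1L)
  expect_match(map$note[1], "chain")
})

test_that("cycles merge into the member with the largest row sum", {
  # A and B each point at the other; C separate
  m <- rbind(c(1, 5, 0),
             c(6, 2, 0),
             c(0, 0, 9))
  map <- resolve_repertoire(cm_from(m))
  expect_identical(map$original[map$retained], c("B", "C"))   # rowsum B=8 > A=6
  expect_identical(map$target, c("B", "B", "C"))
  expect_match(map$note[2], "cycle")
})

test_that("ties involving the diagonal retain the type; off-diagonal ties pick the first label", {
  m <- rbind(c(5, 5, 0),
             c(0, 9, 0),
             c(0, 0, 9))
  map <- resolve_repertoire(cm_from(m))
  expect_true(map$retained[1])
  expect_match(map$note[1], "tie")
  m2 <- rbind(c(1, 4, 4),
              c(0, 9, 0),
              c(0, 0, 9))
  map2 <- resolve_repertoire(cm_from(m2))
  expect_false(map2$retained[1])
  expect_identical(map2$target[1], "B")
  expect_match(map2$note[1], "tie")
})

test_that("resolution always terminates with a nonempty, self-consistent retained set", {
  # exhaustive over all 3x3 count matrices with entries in {0,1,2}
  grid <- as.matrix(expand.grid(rep(list(0:2), 9)))
  empty_retained <- unresolved <- crooked_self <- 0L
  for (r in seq_len(nrow(grid))) {
    m <- matrix(as.numeric(grid[r, ]), 3, 3)
    if (sum(m) == 0) next
    map <- resolve_repertoire(cm_from(m))
    if (sum(map$retained) < 1L) empty_retained <- empty_retained + 1L
    # every target is retained; retained types map to themselves
    if (!all(map$target %in% map$original[map$retained]))
      unresolved <- unresolved + 1L
    if (!identical(map$target[map$retained], map$original[map$retained]))
      crooked_self <- crooked_self + 1L
  }
  expect_identical(empty_retained, 0L)
  expect_identical(unresolved, 0L)
  expect_identical(crooked_self, 0L)
})

test_that("apply_mapping rewrites labels, conserves rows, and rejects unknowns", {
  tab <- demo_features()
  ident <- resolve_repertoire(cm_from(diag(c(1, 1, 1)),
                                      labels = c("grunt", "hoot", "whistle")))
  expect_identical(apply_mapping(tab, ident), tab)
  m <- rbind(c(2, 6, 1), c(0, 9, 0), c(1, 0, 8))
  map <- resolve_repertoire(cm_from(m, labels = c("grunt", "hoot", "whistle")))
  out <- apply_mapping(tab, map)
  expect_identical(nrow(out), nrow(tab))
  expect_setequal(unique(out$original_label), c("hoot", "whistle"))
  expect_identical(sum(out$original_label == "hoot"),
                   sum(tab$original_label %in% c("grunt", "hoot")))
  expect_identical(out[feature_columns(out)], tab[feature_columns(tab)])
  bad <- map[map$original != "grunt", ]
  class(bad) <- class(map)
  expect_error(apply_mapping(tab, bad), "grunt")
})

test_that("summaries report agreement, chance and merges coherently", {
  cm <- cm_from(diag(c(5, 9, 4)))
  s <- summarize_repertoire(cm, resolve_repertoire(cm))
  expect_equal(s$agreement_pct, 100)
  expect_equal(s$error_pct, 0)
  expect_identical(s$n_retained, 3L)
  expect_length(s$merges, 0L)
  m <- rbind(c(2, 6, 1), c(0, 9, 0), c(1, 0, 8))
  cm2 <- cm_from(m)
  s2 <- summarize_repertoire(cm2, resolve_repertoire(cm2))
  expect_equal(s2$trace, 19)
  expect_equal(s2$agreement_pct, 100 * 19 / 27, tolerance = 1e-12)
  expect_identical(unname(s2$merges), "B")
  expect_identical(names(s2$merges), "A")
})

test_that("mapping and confusion CSV/JSON round trips are faithful", {
  m <- rbind(c(2, 6, 1), c(0, 9, 0), c(1, 0, 8))
  cm <- cm_from(m)
  map <- resolve_repertoire(cm)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_mapping(map, p1)
  expect_identical(read_mapping(p1), map)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_confusion(cm, p2)
  back <- read_confusion(p2)
  expect_equal(unname(back$counts), unname(m))
  expect_identical(back$labels, c("A", "B", "C"))
})

test_that("the optional fixed-point mode reaches a stable repertoire", {
  # after merging A into B, B's own row still wins: same answer as single pass
  m <- rbind(c(2, 6, 1), c(0, 9, 0), c(1, 0, 8))
  expect_identical(resolve_repertoire(cm_from(m), iterate = TRUE)$target,
                   resolve_repertoire(cm_from(m))$target)
})
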