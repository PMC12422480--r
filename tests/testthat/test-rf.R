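test_that("inverse-frequency weights have mean one and a 10x rare:common ratio at 10:100", {
  labels <- factor(c(rep("rare", 10), rep("common", 100)))
  w <- vocrep:::inverse_frequency_weights(labels)
  expect_equal(mean(w), 1, tolerance = 1e-12)
  expect_equal(unique(w[labels == "rare"]) / unique(w[labels == "common"]),
               10, tolerance = 1e-12)
})

test_that("two perfectly separated classes reach OOB accuracy >= 0.95 across seeds", {
  arch <- list(call_archetype("whistle", 2200, 2500, "arch", 0.45, 0.06, 0.98, 1),
               call_archetype("grunt", 260, 240, "fall", 0.25, 0.04, 0.5, 6,
                              noise_band = c(200, 1500)))
  ds <- generate_dataset(synthetic_spec(arch, c(50L, 50L), seed = 19L))
  tab <- build_feature_table(ds$recordings)
  for (s in 1:5) {
    fit <- fit_weighted_forest(tab, rf_config(n_trees = 500L, seed = s))
    expect_gte(mean(fit$oob_predictions == fit$labels), 0.95)
  }
})

test_that("fits are reproducible and confusion counts are conserved", {
  tab <- demo_clean()$table
  f1 <- fit_weighted_forest(tab, rf_config(n_trees = 300L, seed = 42L))
  f2 <- fit_weighted_forest(tab, rf_config(n_trees = 300L, seed = 42L))
  expect_identical(as.character(f1$oob_predictions),
                   as.character(f2$oob_predictions))
  cm <- oob_confusion(f1$oob_predictions, f1$labels)
  expect_identical(cm$counts, oob_confusion(f2$oob_predictions, f2$labels)$counts)
  expect_identical(sum(cm$counts), nrow(tab))
  expect_identical(cm$trace + sum(cm$counts) - sum(diag(cm$counts)), nrow(tab))
  expect_equal(unname(cm$row_errors),
               unname(1 - diag(cm$counts) / rowSums(cm$counts)))
  expect_identical(f1$mtry, 5)   # floor(sqrt(31))
})

test_that("weighted rare-class recall is no worse than unweighted on a separable 10:100 problem", {
  arch <- list(call_archetype("whistle", 2200, 2500, "arch", 0.45, 0.06, 0.98, 1),
               call_archetype("grunt", 260, 240, "fall", 0.25, 0.04, 0.5, 6,
                              noise_band = c(200, 1500)))
  ds <- generate_dataset(synthetic_spec(arch, c(10L, 100L), seed = 21L))
  tab <- build_feature_table(ds$recordings)
  recall <- function(wt, s) {
    fit <- suppressWarnings(
      fit_weighted_forest(tab, rf_config(n_trees = 500L, weighting = wt, seed = s)))
    mean(fit$oob_predictions[fit$labels == "whistle"] == "whistle")
  }
  weighted <- vapply(1:10, function(s) recall("case", s), numeric(1))
  unweighted <- vapply(1:10, function(s) recall("none", s), numeric(1))
  expect_gte(mean(weighted), mean(unweighted))
})

test_that("permuted labels drive OOB accuracy to chance", {
  tab <- demo_clean()$table
  k <- length(unique(tab$original_label))
  correct <- 0L
  total <- 0L
  for (s in 1:5) {
    t2 <- tab
    t2$original_label <- vocrep:::with_seed(400L + s, sample(t2$original_label))
    fit <- fit_weighted_forest(t2, rf_config(n_trees = 300L, seed = s))
    correct <- correct + sum(fit$oob_predictions == fit$labels)
    total <- total + length(fit$labels)
  }
  band <- qbinom(c(0.005, 0.995), total, 1 / k) / total
  expect_gte(correct / total, band[1])
  expect_lte(correct / total, band[2])
})

test_that("the chance test is exact two-tailed binomial, matching enumeration", {
  # k = 2, 10/10 correct: p = 2 * (1/2)^10
  cm <- as_confusion_matrix(diag(c(6, 4)))
  ct <- chance_test(cm)
  expect_equal(ct$chance_level, 0.5)
  expect_equal(ct$p_value, 2 * (1 / 2)^10, tolerance = 1e-12)
  expect_equal(ct$p_value, enum_binom_two_tailed(10, 10, 1 / 2), tolerance = 1e-12)
  # enumeration oracle across all outcomes of a small 3-class problem
  for (x in 0:12) {
    m <- matrix(0, 3, 3)
    diag(m) <- c(x, 0, 0)
    m[1, 2] <- 12 - x
    ctx <- chance_test(as_confusion_matrix(m))
    expect_equal(ctx$p_value, enum_binom_two_tailed(x, 12, 1 / 3),
                 tolerance = 1e-9)
  }
  # agreement at expectation is unremarkable
  m <- matrix(4, 3, 3)                      # trace 12 of 36 = 1/3 exactly
  expect_gt(chance_test(as_confusion_matrix(m))$p_value, 0.5)
})

test_that("label bookkeeping errors are caught", {
  expect_error(oob_confusion(c("a", "b"), c("a", "b", "a")), "differ in length")
  expect_error(oob_confusion(c("a", "z"), c("a", "b")), "not in the label set")
  labels <- factor(c("a", "a", "b", "b", "b"), levels = c("a", "b", "c"))
  tab <- data.frame(call_id = sprintf("c%d", 1:5), original_label = labels,
                    f1 = rnorm(5), f2 = rnorm(5))
  expect_error(fit_weighted_forest(tab, rf_config(n_trees = 50L)), "empty class")
  tab$original_label <- factor(c("a", "a", "a", "a", "b"))
  expect_warning(fit_weighted_forest(tab, rf_config(n_trees = 50L)),
                 "single call")
})

test_that("permutation importance finds the informative feature and zeroes the constant one", {
  set.seed(3)
  n <- 60
  tab <- data.frame(call_id = sprintf("c%02d", 1:n),
                    original_label = rep(c("a", "b"), each = n / 2),
                    sep = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    flat = rep(1.5, n))
  fit <- fit_weighted_forest(tab, rf_config(n_trees = 300L, mtry = 2L, seed = 1L))
  imp <- variable_importance(fit)
  expect_identical(names(imp)[1], "sep")
  expect_lt(abs(imp[["flat"]]), 1e-9)
})
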