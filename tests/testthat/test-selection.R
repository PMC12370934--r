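# selection layer: Type II ANOVA, Tukey-Kramer groupings, regression tree,
# RPI and model-set extraction

# synthetic BIC tables built directly (no fitting) so effects are controlled
fake_table <- function(models, cats, n_per_cell, model_eff, cat_eff,
                       sd = 1, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(model = models, feed_category = cats,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  rows$sample_id <- paste0(rows$feed_category, "_", rows$rep)
  rows$bic <- 40 + model_eff[rows$model] + cat_eff[rows$feed_category] +
    rnorm(nrow(rows), 0, sd)
  rows[, c("sample_id", "feed_category", "model", "bic")]
}

test_that("two_way_anova reproduces the full-design degrees of freedom", {
  models <- gp_models(names_only = TRUE)
  cats <- gp_feed_categories()
  tab <- fake_table(models, cats, 3,
                    setNames(seq_along(models), models),
                    setNames(1:6, cats), seed = 2)
  an <- two_way_anova(tab)
  expect_identical(an$df[1:3], c(20L, 5L, 100L))
  # balanced design: the decomposition is exact
  tot <- sum((tab$bic - mean(tab$bic))^2)
  expect_equal(sum(an$ss), tot)
  expect_lt(an$p[1], 0.01)
})

test_that("two_way_anova matches a hand-computed 2x2 oracle", {
  # cells: A1B1 {1,3}, A1B2 {5,7}, A2B1 {2,4}, A2B2 {10,12}
  tab <- data.frame(
    sample_id = as.character(1:8),
    feed_category = rep(c("B1", "B2"), each = 2, times = 2),
    model = rep(c("A1", "A2"), each = 4),
    bic = c(1, 3, 5, 7, 2, 4, 10, 12))
  an <- two_way_anova(tab)
  # balanced, so Type II equals the textbook sums of squares
  expect_equal(an$ss[an$source == "model"], 18)
  expect_equal(an$ss[an$source == "feed_category"], 72)
  expect_equal(an$ss[an$source == "model:feed_category"], 8)
  expect_equal(an$ss[an$source == "residual"], 8)
  expect_identical(an$df, c(1L, 1L, 1L, 4L))
})

test_that("constant response gives zero factor SS and p = 1", {
  tab <- fake_table(c("A", "B"), c("X", "Y"), 3,
                    c(A = 0, B = 0), c(X = 0, Y = 0), sd = 0)
  an <- two_way_anova(tab)
  expect_true(all(an$ss[1:3] == 0))
  expect_true(all(an$p[1:3] == 1))
})

test_that("empty cells raise an explicit design error", {
  tab <- fake_table(c("A", "B"), c("X", "Y"), 2,
                    c(A = 0, B = 1), c(X = 0, Y = 1))
  tab <- tab[!(tab$model == "A" & tab$feed_category == "Y"), ]
  expect_error(two_way_anova(tab), "empty")
})

test_that("tukey_groups letters behave on constructed separations", {
  # two statistically identical models share a letter
  tab <- fake_table(c("A", "B"), "X", 10, c(A = 0, B = 0), c(X = 0),
                    sd = 1, seed = 4)
  g <- tukey_groups(tab)[["X"]]
  expect_true(any(strsplit(g$letters[1], "")[[1]] %in%
                  strsplit(g$letters[2], "")[[1]]))

  # one model shifted far beyond the critical difference sits alone
  tab2 <- fake_table(c("A", "B", "C"), "X", 10,
                     c(A = 0, B = 0.5, C = 40), c(X = 0), sd = 1, seed = 5)
  g2 <- tukey_groups(tab2)[["X"]]
  lc <- g2$letters[g2$model == "C"]
  others <- g2$letters[g2$model != "C"]
  expect_false(any(strsplit(lc, "")[[1]] %in%
                   unlist(strsplit(others, ""))))
  expect_true(all(nchar(g2$letters) >= 1))
})

test_that("true best model lands in the best group (Monte Carlo)", {
  models <- c("M1", "M2", "M3", "M4", "M5")
  eff <- c(M1 = 0, M2 = 6, M3 = 7, M4 = 8, M5 = 12)
  hits <- vapply(1:20, function(s) {
    tab <- fake_table(models, "X", 50, eff, c(X = 0), sd = 4, seed = 100 + s)
    g <- tukey_groups(tab)[["X"]]
    best <- attr(g, "best_letters")
    any(strsplit(g$letters[g$model == "M1"], "")[[1]] %in% best)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("regression tree recovers a separable construction", {
  tab <- fake_table(c("A", "B", "C", "D"), c("X", "Y"), 20,
                    c(A = -15, B = -15, C = 25, D = 25),
                    c(X = 0, Y = 0), sd = 0.5, seed = 6)
  tr <- fit_tree(tab, seed = 2, control = list(max_depth = 3, min_leaf = 5))
  expect_identical(tr$tree$split_var, "model")
  expect_setequal(tr$tree$left_levels, c("A", "B"))
  expect_gt(tr$valid_r2, 0.98)
  expect_equal(sum(tr$contribution), 100)
  expect_identical(sum(tr$leaf_report$count), tr$n_train)
})

test_that("tree on constant response makes zero splits", {
  tab <- fake_table(c("A", "B"), c("X", "Y"), 10,
                    c(A = 0, B = 0), c(X = 0, Y = 0), sd = 0)
  tr <- fit_tree(tab, seed = 1, control = list(max_depth = 5, min_leaf = 5))
  expect_identical(tr$n_splits, 0L)
  expect_length(tr$contribution, 0)
  expect_identical(nrow(tr$leaf_report), 1L)
  expect_error(fit_tree(tab, split_fraction = 1.2), "split_fraction")
})

test_that("dominant model effect yields the larger contribution share", {
  models <- paste0("M", 1:6)
  cats <- paste0("C", 1:3)
  tab <- fake_table(models, cats, 15,
                    setNames(c(0, 4, 8, 12, 16, 20), models),
                    setNames(c(0, 3, 6), cats), sd = 1, seed = 7)
  tr <- fit_tree(tab, seed = 3)
  expect_gt(tr$contribution[["model"]], tr$contribution[["feed_category"]])
  expect_equal(sum(tr$contribution), 100)
  # leaf means are exact means of their members; training R2 is sane
  expect_gte(tr$train_r2, 0)
  pred <- predict(tr, tab)
  expect_true(all(pred %in% tr$leaf_report$mean_bic))
})

test_that("compute_rpi reproduces published arithmetic and its invariance", {
  expect_equal(round(compute_rpi(29.6, 58.0, 40.1), 1), 70.8)
  expect_equal(round(compute_rpi(22.6, 55.0, 34.4), 1), 94.2)
  expect_identical(compute_rpi(30, 30, 40), 0)
  expect_equal(compute_rpi(29.6, 58.0, 40.1),
               compute_rpi(296, 580, 401))
  expect_error(compute_rpi(10, 20, 0), "positive")
  expect_error(compute_rpi(10, 20, -5), "positive")
})

test_that("select_model_sets extracts disjoint top/lower sets and RPI", {
  tab <- fake_table(c("Good1", "Good2", "Mid", "Bad"), c("X", "Y"), 25,
                    c(Good1 = 0, Good2 = 0.4, Mid = 12, Bad = 25),
                    c(X = 0, Y = 2), sd = 1.5, seed = 8)
  g <- tukey_groups(tab)
  sets <- select_model_sets(g, tab)
  expect_identical(nrow(sets), 2L)
  for (i in 1:2) {
    top <- strsplit(sets$top_models[i], ";")[[1]]
    lower <- strsplit(sets$lower_models[i], ";")[[1]]
    expect_true(all(c("Good1", "Good2") %in% top))
    expect_identical(lower, "Bad")
    expect_length(intersect(top, lower), 0)
  }
  expect_equal(sets$rpi,
               100 * (sets$bic_lower - sets$bic_top) / sets$bic_all)

  # all models exactly equal: top = lower = all, RPI = 0
  tab0 <- fake_table(c("A", "B"), "X", 30, c(A = 0, B = 0), c(X = 0),
                     sd = 0, seed = 9)
  s0 <- select_model_sets(tukey_groups(tab0), tab0)
  expect_identical(s0$top_models, s0$lower_models)
  expect_equal(s0$rpi, 0, tolerance = 1e-12)
})

test_that("bic_table keeps only converged rows by default", {
  fits <- data.frame(sample_id = c("a", "b"), feed_category = "X",
                     model = "M", bic = c(10, NA),
                     converged = c(TRUE, FALSE))
  expect_identical(nrow(bic_table(fits)), 1L)
  expect_identical(nrow(bic_table(fits, keep_failures = TRUE)), 2L)
})
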