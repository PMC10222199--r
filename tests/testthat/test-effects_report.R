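# build an encoding + partition where each group is one class, so group
# presence patterns can be dictated directly
effects_fixture <- function(pres, y) {
  ind <- matrix(as.integer(pres), nrow(pres), ncol(pres),
                dimnames = list(paste0("s", seq_len(nrow(pres))),
                                paste0("c", seq_len(ncol(pres)))))
  # append an always-present residual class
  ind <- cbind(ind, r = 1L)
  enc <- class_encoding(ind)
  glabs <- c(LETTERS[seq_len(ncol(pres))], "Z")
  part <- functional_partition(
    stats::setNames(glabs, colnames(ind)), glabs)
  list(encoding = enc, partition = part, y = y)
}

test_that("group effects are percentages of the median property", {
  # 20 samples, median 10; samples with G present average 13.9 -> +39%
  pres <- matrix(FALSE, 20, 2)
  pres[1:10, 1] <- TRUE           # G = A
  pres[c(1:5, 11:15), 2] <- TRUE  # second factor for contrast
  y <- numeric(20)
  y[1:10] <- 13.9                 # mean given A present
  y[11:20] <- seq(2, 10.1, length.out = 10)
  y[20] <- 10 + (10 - median(y[-20]))  # nudge so overall median lands at 10
  med <- 10
  y <- y + (med - median(y))      # exact median 10
  fx <- effects_fixture(pres, y)
  eff <- group_anova_effects(fx$encoding, fx$y, fx$partition)
  expect_equal(eff$median_property, 10)
  expect_equal(eff$main$effect_pct[eff$main$group == "A"],
               100 * (mean(y[pres[, 1]]) - 10) / 10)
  expect_true(all(eff$main$p_value >= 0 & eff$main$p_value <= 1, na.rm = TRUE))
})

test_that("a group with no presence contrast is dropped with a warning", {
  pres <- matrix(c(rep(TRUE, 12), rbinom(12, 1, 0.5) == 1), 12, 2)
  y <- rnorm(12, 10)
  fx <- effects_fixture(pres, y)
  expect_warning(eff <- group_anova_effects(fx$encoding, fx$y, fx$partition),
                 "no contrast")
  expect_false("A" %in% eff$main$group)
})

test_that("the interaction effect is the double difference on the median scale", {
  set.seed(71)
  pres <- matrix(rbinom(80 * 2, 1, 0.5) == 1, 80, 2)
  y <- rnorm(80, 10) + 3 * (pres[, 1] & pres[, 2])
  fx <- effects_fixture(pres, y)
  eff <- group_anova_effects(fx$encoding, fx$y, fx$partition)
  med <- median(y)
  expected <- 100 * (mean(y[pres[, 1] & pres[, 2]]) -
                       mean(y[pres[, 1] & !pres[, 2]]) -
                       mean(y[!pres[, 1] & pres[, 2]]) +
                       mean(y[!pres[, 1] & !pres[, 2]])) / abs(med)
  expect_equal(eff$interactions$effect_pct[1], expected, tolerance = 1e-10)
})

test_that("sequential ANOVA components add back to the total sum of squares", {
  set.seed(72)
  pres <- matrix(rbinom(60 * 3, 1, 0.5) == 1, 60, 3)
  y <- rnorm(60, 5) + pres[, 1] * 2 - pres[, 3]
  fx <- effects_fixture(pres, y)
  eff <- group_anova_effects(fx$encoding, fx$y, fx$partition)
  ss <- eff$anova[["Sum Sq"]]
  expect_equal(sum(ss), sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("an effect of a group whose mean equals the median is exactly zero", {
  set.seed(73)
  pres <- matrix(c(rep(c(TRUE, FALSE), each = 10),
                   rbinom(20, 1, 0.5) == 1), 20, 2)
  y <- c(rep(5, 10), 1, 2, 3, 4, 6, 7, 8, 9, 10, 11)
  # mean(y | A present) = 5 and median(y) = 5
  fx <- effects_fixture(pres, y)
  eff <- group_anova_effects(fx$encoding, fx$y, fx$partition)
  expect_identical(eff$main$effect_pct[eff$main$group == "A"], 0)
})

test_that("key-family comparison categorises and totals correctly", {
  st <- simulate_study(seed = 10)
  X <- unclass(st$table) / rowSums(unclass(st$table))
  lm_tr <- backward_select_linear(X, st$y)
  tree <- fit_tree(st$encoding, st$y, max_groups = 5)
  fc_tr <- backward_select_families(st$encoding, st$y, tree)
  eff <- group_anova_effects(st$encoding, st$y, tree$partition)
  cmp <- compare_key_families(lm_tr, fc_tr, eff)
  expect_identical(nrow(cmp$table), 20L)
  expect_equal(sum(cmp$percentages), 100)
  with(cmp$table, {
    expect_true(all(category %in% c("both", "linear_only",
                                    "clustering_only", "neither")))
    expect_true(all(linear_sign[category %in% c("both", "linear_only")]
                    %in% c("+", "-")))
    expect_true(all(linear_sign[category %in% c("clustering_only",
                                                "neither")] == ""))
    expect_true(all(nzchar(group[category %in% c("both",
                                                 "clustering_only")])))
  })
  # category assignment is consistent with the kept sets
  both <- cmp$table$family[cmp$table$category == "both"]
  expect_true(all(both %in% lm_tr$final$kept_families))
  expect_true(all(both %in% fc_tr$final$kept_families))
})

test_that("mismatched family universes are rejected with the difference listed", {
  st <- simulate_study(seed = 10)
  X <- unclass(st$table) / rowSums(unclass(st$table))
  lm_tr <- backward_select_linear(X[, -1], st$y)
  tree <- fit_tree(st$encoding, st$y, max_groups = 5)
  fc_tr <- backward_select_families(st$encoding, st$y, tree)
  expect_error(compare_key_families(lm_tr, fc_tr), "fam01")
})

test_that("Kruskal-Wallis abundance check matches hand-computed values", {
  tab <- abundance_table(matrix(
    c(1L, 2L, 3L, 10L, 20L, 30L), nrow = 1,
    dimnames = list("s1", paste0("f", 1:6))))
  res <- median_abundance_check(tab, paste0("f", 1:3), paste0("f", 4:6))
  expect_equal(round(res$statistic, 3), 3.857)
  expect_equal(res$p_value, 1 - pchisq(3.857143, 1), tolerance = 1e-4)
  # identical abundance lists: H = 0, p = 1
  tab2 <- abundance_table(matrix(
    c(1L, 2L, 3L, 1L, 2L, 3L), nrow = 1,
    dimnames = list("s1", paste0("g", 1:6))))
  res2 <- median_abundance_check(tab2, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_error(median_abundance_check(tab, character(0), "f1"), "non-empty")
})

test_that("random key sets almost never look abundance-biased", {
  tab <- random_table(30, 20, seed = 50)
  set.seed(51)
  sig <- 0
  for (i in 1:100) {
    key <- sample(colnames(tab), 8)
    res <- median_abundance_check(tab, key, setdiff(colnames(tab), key))
    if (res$p_value < 0.001) sig <- sig + 1
  }
  expect_lte(sig, 1)
})
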