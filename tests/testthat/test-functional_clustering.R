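test_that("assembly motifs are the OR of member-class presences", {
  part <- functional_partition(c(c1 = "A", c2 = "A", c3 = "B"), c("A", "B"))
  expect_identical(motif_of_sample(c(c1 = 0, c2 = 1, c3 = 0), part), "A")
  expect_identical(motif_of_sample(c(c1 = 0, c2 = 0, c3 = 0), part),
                   character(0))
  expect_identical(motif_of_sample(c(c1 = 1, c2 = 1, c3 = 1), part),
                   c("A", "B"))
  ind <- rbind(s1 = c(c1 = 0, c2 = 1, c3 = 0),
               s2 = c(c1 = 0, c2 = 0, c3 = 0),
               s3 = c(c1 = 1, c2 = 0, c3 = 1))
  expect_identical(unname(motif_of_sample(ind, part)),
                   c("A", "(none)", "A+B"))
})

test_that("the motif-mean worked example reproduces its arithmetic", {
  w <- worked_example()
  fit <- fit_motif_means(w$encoding, w$y, w$partition)
  expect_equal(fit$fitted, c(3, 3, 10), ignore_attr = TRUE)
  expect_equal(fit$tss, 34 + 2 / 3, tolerance = 1e-12)
  expect_equal(fit$rss, 2, tolerance = 1e-12)
  expect_equal(round(fit$r2, 4), 0.9423)
  # independent direct formula
  expect_equal(fit$r2, 1 - 2 / (34 + 2 / 3), tolerance = 1e-10)
})

test_that("motif-mean fits hit the degenerate limits", {
  # every sample its own motif: interpolation, R2 = 1
  ind <- diag(3); colnames(ind) <- paste0("c", 1:3)
  rownames(ind) <- paste0("s", 1:3)
  enc <- class_encoding(ind)
  part <- functional_partition(stats::setNames(LETTERS[1:3], paste0("c", 1:3)),
                               LETTERS[1:3])
  expect_equal(fit_motif_means(enc, c(1, 4, 9), part)$r2, 1)
  # all samples one motif: R2 = 0 with a warning
  ind1 <- matrix(1L, 3, 2, dimnames = list(paste0("s", 1:3), c("c1", "c2")))
  enc1 <- class_encoding(ind1)
  part1 <- functional_partition(c(c1 = "A", c2 = "A"), "A")
  expect_warning(f0 <- fit_motif_means(enc1, c(1, 2, 6), part1),
                 "single assembly motif")
  expect_equal(f0$r2, 0)
  expect_error(fit_motif_means(enc1, c(2, 2, 2), part1), "constant")
})

test_that("per-motif residuals of the mean fit sum to zero", {
  enc <- random_encoding(40, 6, seed = 13)
  y <- rnorm(40)
  part <- functional_partition(
    stats::setNames(c("A", "A", "B", "B", "C", "C"), colnames(enc$indicators)),
    c("A", "B", "C"))
  fit <- fit_motif_means(enc, y, part)
  res <- tapply(y - fit$fitted, fit$motifs, sum)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("a two-group planted truth is recovered exactly at zero noise", {
  set.seed(61)
  ind <- matrix(rbinom(60 * 6, 1, 0.45), 60, 6,
                dimnames = list(paste0("s", 1:60), paste0("c", 1:6)))
  enc <- class_encoding(ind)
  planted <- stats::setNames(rep(c("A", "B"), each = 3), paste0("c", 1:6))
  truth <- synthetic_truth(planted, group_effects = c(A = 2, B = -1),
                           baseline = 5, noise_sd = 0, seed = 61)
  y <- plant_partition_property(enc, truth)
  tr <- fit_tree(enc, y, max_groups = 3)
  expect_equal(tr$levels[[2]]$r2, 1, tolerance = 1e-12)
  lvl2 <- tr$levels[[2]]$assignment
  expect_identical(adjusted_rand_index(lvl2, planted[paste0("c", 1:6)]), 1)
})

test_that("level R2 is non-decreasing and the search deterministic", {
  enc <- random_encoding(35, 9, seed = 17)
  y <- rnorm(35)
  tr1 <- fit_tree(enc, y, max_groups = 4)
  tr2 <- fit_tree(enc, y, max_groups = 4)
  r2s <- vapply(tr1$levels, `[[`, 0, "r2")
  expect_true(all(diff(r2s) >= -1e-12))
  expect_identical(tr1$partition$assignment, tr2$partition$assignment)
  expect_error(fit_tree(enc, y, max_groups = 10), "exceeds the number")
})

test_that("the exhaustive oracle enumerates set partitions and bounds the greedy", {
  ind <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1), 3, 3,
                dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
  enc <- class_encoding(ind)
  orc <- exhaustive_oracle(enc, c(1, 2, 5), 2)
  # S(3,1) + S(3,2) = 1 + 3 partitions into at most two groups
  expect_identical(orc$n_examined, 4L)
  orc1 <- exhaustive_oracle(enc, c(1, 2, 5), 1)
  expect_identical(orc1$n_examined, 1L)
  expect_lte(orc1$r2, orc$r2)

  for (s in 1:15) {
    enc_r <- random_encoding(25, 7, seed = 100 + s)
    y <- rnorm(25)
    orc_r <- exhaustive_oracle(enc_r, y, 3)
    tr <- fit_tree(enc_r, y, max_groups = 3)
    expect_lte(tr$levels[[3]]$r2, orc_r$r2 + 1e-9)
  }
  expect_error(exhaustive_oracle(random_encoding(10, 30, seed = 1),
                                 rnorm(10), 6), "guard")
})

test_that("groups are ordered by explanatory contribution, residual last", {
  st <- simulate_study(seed = 8)
  tr <- fit_tree(st$encoding, st$y, max_groups = 5)
  part <- tr$partition
  contrib <- part$contributions
  non_resid <- head(part$group_order, -1)
  expect_identical(names(contrib), part$group_order)
  expect_true(all(diff(contrib[non_resid]) <= 1e-12))
  expect_true(is.na(contrib[residual_group(part)]))
  # the residual group is the catch-all mass
  expect_identical(residual_group(part),
                   names(which.max(table(part$assignment))))
  # the dominant planted group (largest |effect|) is labelled A
  dominant <- names(which.max(abs(st$truth$group_effects)))
  planted_in_A <- names(st$truth$planted_partition)[
    st$truth$planted_partition == dominant]
  expect_true(all(part$assignment[planted_in_A] == "A"))
})

test_that("motif structure is invariant under class input order", {
  enc <- random_encoding(30, 8, seed = 23)
  y <- rnorm(30)
  tr1 <- fit_tree(enc, y, max_groups = 3)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  enc2 <- class_encoding(enc$indicators[, perm])
  tr2 <- fit_tree(enc2, y, max_groups = 3)
  m1 <- motif_of_sample(enc$indicators, tr1$partition)
  m2 <- motif_of_sample(enc2$indicators, tr2$partition)
  # same partition of samples into motifs, up to group relabelling
  expect_identical(adjusted_rand_index(m1, m2), 1)
})

test_that("family selection removes only motif-preserving residual families", {
  st <- simulate_study(seed = 4)
  tr <- fit_tree(st$encoding, st$y, max_groups = 5)
  sel <- backward_select_families(st$encoding, st$y, tr)
  resid <- residual_group(tr$partition)
  # every removed family had all classes in the residual group
  for (fam in sel$steps$removed) {
    cls <- st$encoding$classes$label[st$encoding$classes$family == fam]
    expect_true(all(tr$partition$assignment[cls] == resid))
  }
  # planted families all kept (their key classes sit in non-residual groups)
  planted_fams <- unique(sub("\\|.*$", "", names(st$truth$planted_partition)))
  expect_true(all(planted_fams %in% sel$final$kept_families))
  # motifs unchanged by the whole reduction
  kept_enc <- subset_families(st$encoding, sel$final$kept_families)
  expect_identical(sel$final$r2,
                   fit_motif_means(kept_enc, st$y,
                                   sel$final$partition)$r2)
  # AICc improved and df bookkeeping follows the family-count convention
  expect_lt(sel$final$aicc, aicc(sel$final$rss, sel$final$n, 20))
  expect_identical(sel$final$reported_df,
                   20L - length(sel$final$kept_families))
})

test_that("families with a class in a non-residual group are never candidates", {
  st <- simulate_study(seed = 6)
  tr <- fit_tree(st$encoding, st$y, max_groups = 5)
  sel <- backward_select_families(st$encoding, st$y, tr)
  resid <- residual_group(tr$partition)
  non_resid_fams <- unique(st$encoding$classes$family[
    tr$partition$assignment[st$encoding$classes$label] != resid])
  expect_length(intersect(sel$steps$removed, non_resid_fams), 0)
})

test_that("selection is a no-op when no family is wholly residual", {
  w <- worked_example()
  sel <- backward_select_families(w$encoding, w$y, w$partition)
  expect_identical(nrow(sel$steps), 0L)
  expect_identical(sort(sel$final$kept_families), c("c1", "c2"))
})
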