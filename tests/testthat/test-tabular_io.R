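test_that("abundance tables round-trip through TSV and CSV exactly", {
  tab <- abundance_table(matrix(c(3L, 1L, 0L, 5L), 2, 2,
                                dimnames = list(c("s1", "s2"),
                                                c("famA", "famB"))))
  for (dialect in c("tsv", "csv")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_abundance_table(tab, path, dialect)
    back <- read_abundance_table(path, dialect)
    expect_identical(unclass(back)[, ], unclass(tab)[, ])
  }
})

test_that("parsing is orientation-safe", {
  tab <- random_table(6, 4, seed = 1)
  p1 <- tempfile(); p2 <- tempfile()
  write_abundance_table(tab, p1)
  # transpose by hand: families in rows
  df <- data.frame(family = colnames(tab), t(unclass(tab)),
                   check.names = FALSE)
  utils::write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(unclass(read_abundance_table(p2,
                                                orientation = "families_rows"))[, ],
                   unclass(read_abundance_table(p1))[, ])
})

test_that("invalid counts are rejected with the offending cell named", {
  m <- matrix(c(1, -1, 2, 3), 2, 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(abundance_table(m), "s2.*f1|f1.*s2")
  m2 <- matrix(c(1, 1.5, 2, 3), 2, 2,
               dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(abundance_table(m2), "non-integer")
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s1"), c("f1", "f2")))
  expect_error(abundance_table(m3), "duplicate sample")
  m4 <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("f1", "f1")))
  expect_error(abundance_table(m4), "duplicate family")
})

test_that("non-numeric cells are reported with their position", {
  path <- tempfile()
  writeLines(c("sample\tf1\tf2", "s1\t3\tx", "s2\t1\t5"), path)
  expect_error(read_abundance_table(path), "s1.*f2|f2.*s1")
})

test_that("a 57 x 60 table records n = 57 samples and p = 60 families", {
  tab <- simulate_abundance_table(57, 60, c(0.3, 1), 3000, seed = 2)
  expect_identical(dim(tab), c(57L, 60L))
})

test_that("property tables read, align by identifier, and error on missing samples", {
  path <- tempfile()
  utils::write.table(data.frame(sample = c("s2", "s1"), pe7 = c(4, 2)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  pv <- read_property_table(path, reference_ids = c("s1", "s2"))
  expect_equal(as.numeric(pv), c(2, 4))
  expect_identical(names(pv), c("s1", "s2"))
  expect_error(read_property_table(path, reference_ids = c("s1", "s2", "s3")),
               "s3")
})

test_that("a wide property table yields one vector per labelled column", {
  labs <- c("soil_7d", "soil_42d", "straw_7d", "straw_42d", "pe_7d", "pe_42d")
  df <- data.frame(sample = c("s1", "s2"), matrix(rnorm(12), 2, 6))
  names(df)[-1] <- labs
  path <- tempfile()
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pvs <- read_property_table(path)
  expect_named(pvs, labs)
  expect_s3_class(pvs$pe_7d, "property_vector")
})

test_that("non-finite property values are rejected", {
  expect_error(property_vector(c(1, NA), c("s1", "s2")), "non-finite.*s2")
})

test_that("write_results produces the expected file kinds and schema", {
  out <- tempfile()
  expect_identical(nrow(write_results(out)), 0L)

  tab <- random_table(12, 5, seed = 3)
  enc <- encode_all(tab)
  y <- property_vector(rnorm(12), rownames(tab))
  X <- unclass(tab) / rowSums(unclass(tab))
  trace <- backward_select_linear(X, y)
  tree <- fit_tree(enc, y, max_groups = 3)
  eff <- suppressWarnings(group_anova_effects(enc, y, tree$partition))
  man <- write_results(out, encoding = enc, trace = trace, partition = tree,
                       effects = eff, fits = list(lm = trace$final))
  expect_setequal(man$kind, c("class_encoding", "selection_trace",
                              "partition", "effects", "model_summary"))
  expect_true(all(file.exists(man$path)))
  summ <- jsonlite::read_json(man$path[man$kind == "model_summary"])
  expect_named(summ$lm, c("route", "r2", "f_ratio", "aicc", "k", "n",
                          "kept_families", "reported_df", "residual_df"),
               ignore.order = TRUE)
  # encoding round-trips exactly through its TSV
  back <- read_class_encoding(man$path[man$kind == "class_encoding"])
  expect_identical(back$indicators[, ], enc$indicators[, ])
  # byte-identical re-run
  out2 <- tempfile()
  man2 <- write_results(out2, encoding = enc, trace = trace, partition = tree,
                        effects = eff, fits = list(lm = trace$final))
  for (k in man$kind)
    expect_identical(readLines(man$path[man$kind == k]),
                     readLines(man2$path[man2$kind == k]))
})
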