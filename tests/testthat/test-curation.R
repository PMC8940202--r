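test_that("profiling reports exact missingness and majority-vote kinds", {
  tab <- data.frame(
    a = c(rep("1", 8), "", ""),
    b = c("1.2", "3.4", "oops", "", "", rep("7", 5)),
    c = rep("", 10),
    d = c(rep("x", 5), rep("y", 5)),
    check.names = FALSE)
  prof <- profile_cohort(tab)
  expect_equal(prof$missing_fraction[prof$column == "a"], 0.2)
  expect_equal(prof$missing_fraction[prof$column == "c"], 1.0)
  expect_equal(prof$observed_kind[prof$column == "b"], "numeric")
  expect_equal(prof$observed_kind[prof$column == "d"], "categorical")
  expect_equal(prof$observed_kind[prof$column == "c"], "unknown")
  expect_error(profile_cohort(data.frame(a = character(0))), "empty cohort")
  # majority vote on a 5-cell column: 2/3 of non-empty cells parse numeric
  p2 <- profile_cohort(data.frame(x = c("1.2", "3.4", "oops", "", "")))
  expect_equal(p2$observed_kind, "numeric")
  expect_equal(p2$missing_fraction, 0.4)
})

test_that("inconsistency findings follow the threshold rules", {
  # 10% unparseable cells in a numeric column -> inconsistent, cells listed
  tab <- data.frame(x = c(as.character(1:18), "bad", "worse"),
                    y = as.character(rep(c(0, 1), 10)),
                    check.names = FALSE)
  f <- detect_inconsistent(tab)
  expect_equal(f$column, "x")
  expect_equal(f$reason, "unparseable_values")
  expect_equal(f$cells[[1]], c(19L, 20L))
  # a clean 0/1 column is not inconsistent
  expect_false("y" %in% f$column)
  # declared vs observed kind
  f2 <- detect_inconsistent(tab, profile = profile_cohort(
    tab, declared = c(y = "numeric")))
  expect_true(any(f2$column == "y" & f2$reason == "declared_vs_observed"))
  # out-of-domain against a mapped reference term: 1 of 3 ages
  tab3 <- data.frame(patient_age = c("34", "51", "290"), check.names = FALSE)
  f3 <- detect_inconsistent(tab3, model = tiny_model(),
                            mapping = c(patient_age = "age"))
  expect_equal(f3$reason, "out_of_domain")
  expect_equal(f3$cells[[1]], 3L)
})

test_that("duplicate detection uses names and value agreement", {
  tab <- data.frame(`Anti-La` = as.character(rep(c(0, 1), 10)),
                    anti_la = as.character(rep(c(0, 1), 10)),
                    check.names = FALSE)
  d <- detect_duplicates(tab)
  expect_equal(d$second[d$status == "duplicate"], "anti_la")
  # two independent continuous columns never agree
  set.seed(1)
  tab2 <- data.frame(u = as.character(rnorm(100)), v = as.character(rnorm(100)))
  expect_equal(nrow(detect_duplicates(tab2)[
    detect_duplicates(tab2)$status == "duplicate", ]), 0)
  # identical values but disjoint missingness: indeterminate, not flagged
  tab3 <- data.frame(p = c("1", "2", "", ""), q = c("", "", "3", "4"))
  d3 <- detect_duplicates(tab3)
  expect_equal(d3$status, "indeterminate")
})

test_that("outlier fences use distinct-value quartiles with a 3xIQR fence", {
  tab <- data.frame(v = as.character(c(10:16, 1000)))
  out <- detect_outliers(tab)
  expect_equal(out$cells$row, 8L)
  expect_equal(out$cells$value, "1000")
  # a far-tail rule flags (almost) nothing on a clean normal sample
  set.seed(7)
  tab2 <- data.frame(z = as.character(round(rnorm(200), 6)))
  expect_lte(nrow(detect_outliers(tab2)$cells), 2)
  # constant columns collapse the fences onto the constant: inside
  tab3 <- data.frame(k = as.character(rep(5, 12)))
  expect_equal(nrow(detect_outliers(tab3)$cells), 0)
  # short features are skipped, not judged
  tab4 <- data.frame(s = as.character(c(1, 2, 3, 1000, "", "", "", "")))
  out4 <- detect_outliers(tab4)
  expect_equal(out4$skipped, "s")
})

test_that("imputation uses medians, modes and the lexicographic tie rule", {
  tab <- data.frame(num = c("1", "2", "", "4"),
                    bin = c("1", "1", "0", ""),
                    cat = c("a", "b", "", ""),
                    check.names = FALSE)
  imp <- impute_missing(tab)
  expect_equal(imp$table$num[3], "2")       # median of {1,2,4}
  expect_equal(imp$table$bin[4], "1")       # mode
  expect_equal(imp$table$cat[3:4], c("a", "a"))  # tie -> smallest
  expect_equal(sort(unique(imp$actions$column)), c("bin", "cat", "num"))
})

test_that("the curation pipeline drops, blanks and imputes in fixed order", {
  n <- 50
  set.seed(3)
  base <- as.character(round(rnorm(n, 10, 2), 3))
  tab <- data.frame(
    keep1 = base,
    keep2 = as.character(rep(c(0, 1), n / 2)),
    dupe = base,                                  # value-identical duplicate
    allmiss = rep("", n),                         # bad
    check.names = FALSE)
  tab$keep1[5] <- ""                               # 2% missing
  res <- curate(tab)
  expect_equal(res$report$n_duplicate, 1)
  expect_equal(res$report$n_bad, 1)
  expect_equal(names(res$table), c("keep1", "keep2"))
  expect_equal(sum(is_missing_cell(unlist(res$table))), 0)
  expect_equal(nrow(res$table), n)                 # rows conserved
  # a clean table is a fixpoint with an empty action log
  clean <- data.frame(a = as.character(1:20), b = as.character(rep(c(0, 1), 10)))
  res2 <- curate(clean)
  expect_identical(res2$table, cohortharmony:::as_cohort_table(clean))
  expect_equal(nrow(res2$report$actions), 0)
  # dropping everything is an error
  expect_error(curate(data.frame(x = rep("", 5))), "no usable features")
})

test_that("curation is idempotent and replayable on generated cohorts", {
  study <- generate_study(generator_config(
    n_cohorts = 2, n_rows = c(150, 150), seed = 9))
  for (nm in names(study$cohorts)) {
    raw <- study$cohorts[[nm]]
    res1 <- curate(raw)
    res2 <- curate(res1$table)
    expect_identical(res2$table, res1$table)
    expect_identical(apply_curation(raw, res1$report), res1$table)
    expect_equal(nrow(res1$table), nrow(raw))
    expect_equal(max(profile_cohort(res1$table)$missing_fraction), 0)
  }
})
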