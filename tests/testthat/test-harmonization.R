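test_that("lexical matching accepts greedily with injectivity and tie rules", {
  corpus <- build_corpus(tiny_model())
  m <- lexical_match(c("lymphadenopathy", "x1"), corpus)
  expect_equal(m$source_column, "lymphadenopathy")
  expect_equal(m$reference_term, "lymphadenopathy")
  expect_equal(m$score, 1)
  expect_equal(m$method, "lexical")
  # columns far from every synonym stay unmatched
  expect_equal(nrow(lexical_match("x1", corpus)), 0)
  # two columns tied at 1.0 for one term: lexicographically first wins
  m2 <- lexical_match(c("z gender", "a gender"), corpus, threshold = 0.5)
  row_g <- m2[m2$reference_term == "gender", ]
  expect_equal(row_g$source_column, "a gender")
  # injectivity: at most one column per term, one term per column
  study <- generate_study(generator_config(n_cohorts = 2, seed = 13))
  corpus2 <- build_corpus(study$model, builtin_synonyms())
  mm <- lexical_match(names(study$cohorts$cohort1), corpus2)
  expect_false(anyDuplicated(mm$source_column) > 0)
  expect_false(anyDuplicated(mm$reference_term) > 0)
})

test_that("semantic scores combine token, synonym and class-path evidence", {
  stub <- list("gender" = "sex")
  corpus <- build_corpus(tiny_model(), synonyms = stub)
  m <- semantic_match("sex", corpus)
  expect_equal(m$reference_term, "gender")
  expect_equal(m$method, "semantic")
  expect_gte(m$score, 0.8)  # token listed as a synonym scores 1, weighted 0.8
  # hand evaluation: "glandular swelling" vs "salivary gland swelling"
  # tokens: glandular -> best lexsim vs {salivary, gland, swelling} = 5/9;
  # swelling -> exact 1; base = (5/9 + 1)/2; no ancestor overlap
  corpus0 <- build_corpus(tiny_model())
  m2 <- semantic_match("glandular swelling", corpus0)
  expect_equal(m2$reference_term, "salivary gland swelling")
  expect_equal(m2$score, 0.8 * (5 / 9 + 1) / 2, tolerance = 1e-9)
  # garbage stays unmatched
  expect_equal(nrow(semantic_match("zzqq", corpus0)), 0)
})

test_that("value transforms standardize categories, binaries and units", {
  corpus <- build_corpus(tiny_model())
  tab <- data.frame(gender = c("Male", "Female", "Female"),
                    lymphadenopathy = c("yes", "no", "yes"),
                    C4 = c("0.12", "0.30", "0.25"),
                    check.names = FALSE)
  matches <- data.frame(source_column = c("gender", "lymphadenopathy", "C4"),
                        reference_term = c("gender", "lymphadenopathy", "C4"),
                        score = 1, method = "lexical", accepted = TRUE,
                        stringsAsFactors = FALSE)
  cfg <- harmonization_config(unit_conversions = list(
    C4 = list(scale = 100, offset = 0)))  # recorded in g/L -> mg/dL
  tr <- build_transforms(matches, tab, corpus, cfg)
  expect_equal(tr$gender$type, "recode")
  expect_equal(tr$gender$map$Male, "male")
  expect_equal(tr$lymphadenopathy$type, "binary")
  expect_equal(tr$lymphadenopathy$map$yes, "1")
  expect_equal(tr$C4$type, "affine")
  expect_equal(tr$C4$scale, 100)
  # unknown category falls back to the configured label with a warning
  tab2 <- data.frame(gender = c("qqq", "female"), check.names = FALSE)
  tr2 <- build_transforms(matches[1, ], tab2, corpus)
  expect_equal(tr2$gender$map$qqq, "unknown")
  expect_match(attr(tr2, "warnings"), "qqq")
})

test_that("harmonize produces the shared reference schema with coverage", {
  corpus <- build_corpus(tiny_model())
  leaves <- leaf_terms(tiny_model())
  # fixpoint: canonical columns give full coverage and identity transforms
  tab <- data.frame(gender = c("female", "male"), age = c("40", "60"),
                    C4 = c("20", "30"), lymphadenopathy = c("0", "1"),
                    `salivary gland swelling` = c("1", "0"),
                    check.names = FALSE)
  h <- harmonize(tab, corpus)
  expect_equal(h$coverage$coverage_pct, 100)
  expect_equal(h$coverage$n_standardized, 0)
  expect_equal(names(h$data), leaves)
  # already-harmonized data harmonizes to itself
  h2 <- harmonize(h$data, corpus)
  expect_equal(h2$coverage$coverage_pct, 100)
  expect_equal(h2$coverage$n_standardized, 0)
  # disjoint-vocabulary cohorts share the output schema
  tabA <- data.frame(gender = c("female", "male"), age = c("30", "50"),
                     check.names = FALSE)
  tabB <- data.frame(C4 = c("22", "31"), lymphadenopathy = c("0", "1"),
                     check.names = FALSE)
  hA <- harmonize(tabA, corpus); hB <- harmonize(tabB, corpus)
  expect_identical(names(hA$data), names(hB$data))
  # no alignment at all is an error
  expect_error(harmonize(data.frame(qx = c("1", "2")), corpus),
               "no alignment possible")
})

test_that("lowering the lexical threshold never decreases coverage", {
  study <- generate_study(generator_config(seed = 7))
  corpus <- build_corpus(study$model, builtin_synonyms())
  tab <- curate(study$cohorts$cohort1)$table
  cov <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(th)
    harmonize(tab, corpus,
              harmonization_config(lexical_threshold = th))$coverage$coverage_pct,
    numeric(1))
  expect_true(all(diff(cov) <= 1e-9))
})

test_that("planted column-to-term mappings are recovered under perturbation", {
  study <- generate_study(generator_config(
    n_cohorts = 2, n_rows = c(120, 120), seed = 21, edit_fraction = 0.15,
    missing_rates = c(0, 0), n_duplicate_cols = 0, n_bad_cols = 0,
    n_inconsistent_cols = 0))
  corpus <- build_corpus(study$model, builtin_synonyms())
  h <- harmonize(study$cohorts$cohort1, corpus)
  expect_gte(mapping_recovery(h$mapping, study$truth$cohorts$cohort1), 0.95)
  # accepted matches stay a partial bijection under perturbation
  expect_false(anyDuplicated(h$mapping$matches$source_column) > 0)
  expect_false(anyDuplicated(h$mapping$matches$reference_term) > 0)
})
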