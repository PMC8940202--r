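test_that("value domains enforce their invariants", {
  expect_error(value_domain("numeric", range = c(5, 1)), "low <= high")
  expect_error(value_domain("categorical", categories = c("a", "a")), "unique")
  expect_error(value_domain("categorical"), "non-empty")
  expect_equal(value_domain("binary")$categories, c("0", "1"))
})

test_that("a minimal hierarchy loads with one root and two leaves", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"demo","version":"1","terms":[
    {"name":"Demographics","description":"","parent":null,
     "domain":{"kind":"binary","unit":"","range":null,"categories":null}},
    {"name":"gender","description":"","parent":"Demographics",
     "domain":{"kind":"categorical","unit":"","range":null,
               "categories":["female","male"]}},
    {"name":"age","description":"","parent":"Demographics",
     "domain":{"kind":"numeric","unit":"years","range":[0,120],
               "categories":null}}]}', path)
  ont <- load_reference_model(path)
  expect_equal(ontology_roots(ont), "Demographics")
  expect_equal(leaf_terms(ont), c("gender", "age"))
})

test_that("clinical terms carry their value domains", {
  ont <- tiny_model()
  expect_equal(ont$terms[["lymphadenopathy"]]$domain$kind, "binary")
  expect_equal(ont$terms[["C4"]]$domain$kind, "numeric")
  expect_equal(ont$terms[["C4"]]$domain$unit, "mg/dL")
})

test_that("structural errors are detected and named", {
  expect_error(
    reference_ontology(list(
      reference_term("age", value_domain("numeric", range = c(0, 120)),
                     parent = "ghost"))),
    "undefined parent 'ghost'")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","version":"1","terms":[
    {"name":"a","description":"","parent":"b",
     "domain":{"kind":"binary"}},
    {"name":"b","description":"","parent":"a",
     "domain":{"kind":"binary"}}]}', path)
  expect_error(load_reference_model(path), "cyclic")
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","version":"1","terms":[
    {"name":"a","description":"","parent":null,"domain":{"unit":""}}]}', path2)
  expect_error(load_reference_model(path2), "kind.*term 'a'")
})

test_that("terminology extraction is deterministic depth-first", {
  ont <- tiny_model()
  tt <- extract_terminologies(ont)
  expect_equal(tt$name, c("Demographics", "gender", "age", "Laboratory", "C4",
                          "Symptoms", "lymphadenopathy",
                          "salivary gland swelling"))
  expect_equal(tt$class_path[[2]], c("Demographics", "gender"))
  expect_equal(extract_terminologies(
    reference_ontology(list(), name = "empty"))$name, character(0))
  # independent recursive traversal oracle on a generated ontology
  ont2 <- generate_reference(n_terms = 12, depth = 3, seed = 5)
  walk <- function(node) {
    kids <- names(ont2$terms)[vapply(ont2$terms, function(t)
      identical(t$parent, node), logical(1))]
    c(node, unlist(lapply(kids, walk)))
  }
  expected <- unlist(lapply(names(ont2$terms)[vapply(ont2$terms, function(t)
    is.null(t$parent), logical(1))], walk))
  expect_equal(extract_terminologies(ont2)$name, expected)
})

test_that("corpus entries cover every term with canonical synonyms and tokens", {
  corpus <- build_corpus(tiny_model())
  expect_equal(length(corpus$entries), length(tiny_model()$terms))
  expect_equal(corpus$entries[["gender"]]$synonyms, "gender")
  expect_equal(corpus$entries[["gender"]]$tokens, "gender")
  expect_equal(corpus$entries[["salivary gland swelling"]]$tokens,
               c("salivary", "gland", "swelling"))
  # property over random generated ontologies
  for (s in 1:4) {
    ont <- generate_reference(n_terms = sample(6:20, 1), depth = 3, seed = s)
    expect_equal(length(build_corpus(ont)$entries), length(ont$terms))
  }
})

test_that("synonym enrichment is stub-injectable, monotone, and fault-tolerant", {
  stub <- list("swelling" = "puffiness")
  ont <- tiny_model()
  corpus <- build_corpus(ont, synonyms = stub)
  entry <- corpus$entries[["salivary gland swelling"]]
  expect_true("puffiness" %in% entry$synonyms)
  expect_true("puffiness" %in% entry$enriched)
  # monotonicity: enriched synonyms are a superset of the offline ones
  offline <- build_corpus(ont)
  enriched <- build_corpus(ont, synonyms = builtin_synonyms())
  for (nm in names(offline$entries)) {
    expect_true(all(offline$entries[[nm]]$synonyms %in%
                      enriched$entries[[nm]]$synonyms))
  }
  # a failing source degrades to the offline corpus with warnings
  bad_source <- function(key) stop("backend unavailable")
  single <- reference_ontology(list(
    reference_term("gender", value_domain("binary"))), name = "one")
  expect_warning(build_corpus(single, synonyms = bad_source), "offline")
  c2 <- suppressWarnings(build_corpus(ont, synonyms = bad_source))
  for (nm in names(offline$entries))
    expect_equal(c2$entries[[nm]]$synonyms, offline$entries[[nm]]$synonyms)
})

test_that("model and corpus serializations round-trip byte-identically", {
  ont <- generate_reference(n_terms = 10, depth = 3, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_reference_model(ont, p1)
  save_reference_model(load_reference_model(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  corpus <- build_corpus(ont, synonyms = builtin_synonyms())
  c1 <- withr::local_tempfile(fileext = ".json")
  c2 <- withr::local_tempfile(fileext = ".json")
  save_corpus(corpus, c1)
  save_corpus(load_corpus(c1), c2)
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
})
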