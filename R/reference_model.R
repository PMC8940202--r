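#' Value domain of a reference term
#'
#' Describes the admissible values of a clinical parameter: its kind
#' (numeric / categorical / binary / date), an optional unit label, an
#' inclusive numeric range for numeric kinds, and the ordered canonical
#' category labels for categorical kinds.  Binary terms follow the
#' convention 0 = absent, 1 = present and always carry categories
#' `c("0", "1")`.
#'
#' @param kind One of `"numeric"`, `"categorical"`, `"binary"`, `"date"`.
#' @param unit Free-text unit label (numeric kinds), default `""`.
#' @param range Numeric `c(low, high)` inclusive bounds, numeric kind only.
#' @param categories Character vector of canonical category labels
#'   (categorical kind); ignored for binary, which is fixed to `0`/`1`.
#' @return An object of class `value_domain`.
#' @export
value_domain <- function(kind, unit = "", range = NULL, categories = NULL) {
  kind <- match.arg(kind, c("numeric", "categorical", "binary", "date"))
  if (kind == "numeric") {
    if (is.null(range) || length(range) != 2 || anyNA(range))
      stop("numeric domain requires range = c(low, high)")
    range <- as.numeric(range)
    if (range[1] > range[2]) stop("numeric domain requires low <= high")
    categories <- NULL
  } else if (kind == "binary") {
    categories <- c("0", "1")
    range <- NULL
  } else if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0)
      stop("categorical domain requires non-empty categories")
    categories <- as.character(categories)
    if (anyDuplicated(categories)) stop("categories must be unique")
    range <- NULL
  } else {
    range <- NULL
    categories <- NULL
  }
  structure(list(kind = kind, unit = as.character(unit)[1],
                 range = range, categories = categories),
            class = "value_domain")
}

#' A term of the disease reference model
#'
#' @param name Canonical term name (unique within a model).
#' @param domain A [value_domain()].
#' @param description Free-text description.
#' @param parent Canonical name of the parent class, or `NULL` for a root.
#' @return An object of class `reference_term`.
#' @export
reference_term <- function(name, domain, description = "", parent = NULL) {
  stopifnot(is.character(name), nzchar(name), inherits(domain, "value_domain"))
  structure(list(name = name, description = as.character(description)[1],
                 parent = if (is.null(parent)) NULL else as.character(parent)[1],
                 domain = domain),
            class = "reference_term")
}

#' Assemble a disease reference model (ontology form)
#'
#' Terms with parent links form a forest: root classes have no parent and
#' every term is reachable from exactly one root.  Parent links carry a
#' single relation label (default `"has_subclass"`), the ontology's object
#' property.
#'
#' @param terms List of [reference_term()] objects, in declaration order
#'   (the order drives the deterministic depth-first traversal).
#' @param name Model name.
#' @param version Model version string.
#' @param relation Label of the parent-to-child object property.
#' @return An object of class `reference_ontology`.
#' @export
reference_ontology <- function(terms, name = "reference", version = "1.0",
                               relation = "has_subclass") {
  nm <- vapply(terms, function(t) t$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate term names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(terms) <- nm
  ont <- structure(list(name = name, version = version,
                        relation = relation, terms = terms),
                   class = "reference_ontology")
  validate_ontology(ont)
  ont
}

validate_ontology <- function(ont) {
  nm <- names(ont$terms)
  for (t in ont$terms) {
    if (!is.null(t$parent)) {
      if (!t$parent %in% nm)
        stop("term '", t$name, "' names undefined parent '", t$parent, "'")
    }
  }
  # acyclicity: walk each term to a root
  for (start in nm) {
    seen <- character(0)
    cur <- start
    while (!is.null(ont$terms[[cur]]$parent)) {
      if (cur %in% seen)
        stop("cyclic parent links: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- ont$terms[[cur]]$parent
    }
  }
  invisible(ont)
}

#' @export
print.reference_ontology <- function(x, ...) {
  leaves <- leaf_terms(x)
  cat("Reference model '", x$name, "' v", x$version, ": ",
      length(x$terms), " terms (", length(ontology_roots(x)), " roots, ",
      length(leaves), " parameters)\n", sep = "")
  invisible(x)
}

#' Root classes of a reference model
#' @param ont A `reference_ontology`.
#' @return Character vector of root term names, in declaration order.
#' @export
ontology_roots <- function(ont) {
  nm <- names(ont$terms)
  nm[vapply(ont$terms, function(t) is.null(t$parent), logical(1))]
}

ontology_children <- function(ont, parent) {
  nm <- names(ont$terms)
  nm[vapply(ont$terms, function(t) !is.null(t$parent) && t$parent == parent,
            logical(1))]
}

#' Leaf terms (measurable parameters) of a reference model
#'
#' Terms with no children: the clinical parameters a data column can map
#' to, as opposed to grouping classes.
#' @param ont A `reference_ontology`.
#' @return Character vector of leaf term names in depth-first order.
#' @export
leaf_terms <- function(ont) {
  tt <- extract_terminologies(ont)
  tt$name[tt$is_leaf]
}

#' Class path of a term
#' @param ont A `reference_ontology`.
#' @param name Term name.
#' @return Character vector from the root down to (and including) the term.
#' @export
class_path <- function(ont, name) {
  if (!name %in% names(ont$terms)) stop("unknown term '", name, "'")
  path <- name
  cur <- name
  while (!is.null(ont$terms[[cur]]$parent)) {
    cur <- ont$terms[[cur]]$parent
    path <- c(cur, path)
  }
  path
}

#' Extract terminologies and range values from the ontology
#'
#' One row per term, in deterministic depth-first order (roots in
#' declaration order, children in declaration order), with the term's value
#' domain and its root-to-term class path — the semantic information the
#' downstream matching stages consume.
#'
#' @param ont A `reference_ontology`.
#' @return A data frame with columns `name`, `kind`, `is_leaf`, and
#'   list-columns `domain` and `class_path`.
#' @export
extract_terminologies <- function(ont) {
  out_names <- character(0)
  walk <- function(name) {
    out_names <<- c(out_names, name)
    for (ch in ontology_children(ont, name)) walk(ch)
  }
  for (r in ontology_roots(ont)) walk(r)
  has_child <- vapply(out_names,
                      function(n) length(ontology_children(ont, n)) > 0,
                      logical(1))
  data.frame(
    name = out_names,
    kind = vapply(out_names, function(n) ont$terms[[n]]$domain$kind, character(1)),
    is_leaf = !has_child,
    domain = I(lapply(out_names, function(n) ont$terms[[n]]$domain)),
    class_path = I(lapply(out_names, function(n) class_path(ont, n))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

domain_to_list <- function(d) {
  list(kind = d$kind, unit = d$unit,
       range = if (is.null(d$range)) NULL else as.numeric(d$range),
       categories = if (is.null(d$categories)) NULL else as.list(d$categories))
}

domain_from_list <- function(x, where) {
  if (is.null(x$kind)) stop("malformed reference model: missing 'kind' in ", where)
  kind <- as.character(x$kind)
  if (!kind %in% c("numeric", "categorical", "binary", "date"))
    stop("malformed reference model: bad 'kind' value '", kind, "' in ", where)
  value_domain(kind,
               unit = if (is.null(x$unit)) "" else x$unit,
               range = if (is.null(x$range)) NULL else unlist(x$range),
               categories = if (is.null(x$categories)) NULL else unlist(x$categories))
}

#' Load a reference model from its JSON serialization
#'
#' Schema: `{"name", "version", "terms": [{"name", "description",
#' "parent" (or null), "domain": {"kind", "unit", "range", "categories"}}]}`.
#'
#' @param path Path to the reference-model JSON file.
#' @return A `reference_ontology`.
#' @export
load_reference_model <- function(path) {
  if (!file.exists(path)) stop("reference model file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$terms)) stop("malformed reference model: missing 'terms'")
  terms <- lapply(raw$terms, function(t) {
    if (is.null(t$name)) stop("malformed reference model: term without 'name'")
    reference_term(t$name,
                   domain = domain_from_list(t$domain, paste0("term '", t$name, "'")),
                   description = if (is.null(t$description)) "" else t$description,
                   parent = t$parent)
  })
  reference_ontology(terms,
                     name = if (is.null(raw$name)) "reference" else raw$name,
                     version = if (is.null(raw$version)) "1.0" else raw$version,
                     relation = if (is.null(raw$relation)) "has_subclass" else raw$relation)
}

#' Serialize a reference model to canonical JSON
#'
#' Canonical form: fixed key order, terms in stored declaration order,
#' two-space pretty printing, full-precision numbers.  `save` after `load`
#' reproduces a canonical file byte-for-byte.
#'
#' @param ont A `reference_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_reference_model <- function(ont, path) {
  obj <- list(
    name = ont$name, version = ont$version, relation = ont$relation,
    terms = unname(lapply(ont$terms, function(t) {
      list(name = t$name, description = t$description,
           parent = if (is.null(t$parent)) NA else t$parent,
           domain = domain_to_list(t$domain))
    }))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Built-in clinical synonym lexicon
#'
#' A compact offline vocabulary keyed by normalized term form, used both to
#' enrich the medical corpus and by the synthetic-cohort generator when
#' swapping column headers for synonyms.  Any synonym source with the same
#' shape (named list, or a function mapping a term to synonyms) can be
#' supplied instead.
#'
#' @return Named list: normalized term -> character vector of synonyms.
#' @export
builtin_synonyms <- function() {
  list(
    "gender" = c("sex"),
    "age" = c("age years"),
    "lymphadenopathy" = c("swollen lymph nodes", "enlarged lymph nodes"),
    "salivary gland swelling" = c("parotid swelling", "salivary swelling"),
    "anti la" = c("anti ssb", "ssb antibody"),
    "anti ro" = c("anti ssa", "ssa antibody"),
    "c4" = c("complement c4", "complement component 4"),
    "c3" = c("complement c3"),
    "lymphoma" = c("nhl", "non hodgkin lymphoma"),
    "dry eyes" = c("xerophthalmia", "ocular dryness"),
    "dry mouth" = c("xerostomia", "oral dryness"),
    "rheumatoid factor" = c("rf positivity"),
    "fatigue" = c("tiredness"),
    "arthralgia" = c("joint pain"),
    "raynaud phenomenon" = c("raynauds"),
    "purpura" = c("skin purpura"),
    "esr" = c("erythrocyte sedimentation rate"),
    "crp" = c("c reactive protein"),
    "hemoglobin" = c("hb"),
    "white cell count" = c("wbc", "leukocyte count"),
    "platelet count" = c("plt"),
    "igg" = c("immunoglobulin g"),
    "ana" = c("antinuclear antibodies"),
    "schirmer test" = c("schirmers test"),
    "focus score" = c("biopsy focus score")
  )
}

query_synonym_source <- function(source, key) {
  if (is.null(source)) return(character(0))
  res <- tryCatch({
    if (is.function(source)) source(key)
    else source[[key]]
  }, error = function(e) {
    warning("synonym source failed for '", key, "': ", conditionMessage(e),
            "; continuing offline", call. = FALSE)
    character(0)
  })
  if (is.null(res)) character(0) else as.character(res)
}

#' Build the medical corpus from a reference model
#'
#' Flattens the ontology into the matchable corpus: one entry per term with
#' its synonyms (always including the canonical name), normalized tokens,
#' value domain and root-to-term class path.  An optional synonym source
#' enriches every entry with external vocabulary, queried with the term's
#' full normalized form and with each single-word token; enriched synonyms
#' are tagged with their provenance.  With `synonyms = NULL` the corpus is
#' built fully offline.
#'
#' @param ont A `reference_ontology`.
#' @param synonyms Optional synonym source: a named list (normalized term ->
#'   synonyms), a function of one term, or `NULL` for no enrichment.
#' @return An object of class `medical_corpus`.
#' @export
build_corpus <- function(ont, synonyms = NULL) {
  tt <- extract_terminologies(ont)
  entries <- list()
  for (i in seq_len(nrow(tt))) {
    nm <- tt$name[i]
    toks <- normalize_term(nm)
    enriched <- character(0)
    if (!is.null(synonyms)) {
      keys <- unique(c(normalize_key(nm), toks))
      for (k in keys) enriched <- c(enriched, query_synonym_source(synonyms, k))
      enriched <- setdiff(unique(normalize_key(enriched)), c(normalize_key(nm), ""))
    }
    entries[[nm]] <- list(
      synonyms = unique(c(nm, enriched)),
      tokens = toks,
      class_path = tt$class_path[[i]],
      domain = tt$domain[[i]],
      is_leaf = tt$is_leaf[i],
      enriched = enriched
    )
  }
  structure(list(source_model = ont$name, entries = entries),
            class = "medical_corpus")
}

#' @export
print.medical_corpus <- function(x, ...) {
  n_enr <- sum(vapply(x$entries, function(e) length(e$enriched) > 0, logical(1)))
  cat("Medical corpus of '", x$source_model, "': ", length(x$entries),
      " entries (", n_enr, " enriched)\n", sep = "")
  invisible(x)
}

#' Serialize a medical corpus to canonical JSON
#' @param corpus A `medical_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_corpus <- function(corpus, path) {
  obj <- list(
    source_model = corpus$source_model,
    entries = lapply(corpus$entries, function(e) {
      list(synonyms = as.list(e$synonyms), tokens = as.list(e$tokens),
           class_path = as.list(e$class_path),
           domain = domain_to_list(e$domain),
           is_leaf = e$is_leaf,
           enriched = as.list(e$enriched))
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a medical corpus from JSON
#' @param path Path to a corpus JSON file written by [save_corpus()].
#' @return A `medical_corpus`.
#' @export
load_corpus <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$entries)) stop("malformed corpus: missing 'entries'")
  entries <- lapply(raw$entries, function(e) {
    list(synonyms = as.character(unlist(e$synonyms)),
         tokens = as.character(unlist(e$tokens)),
         class_path = as.character(unlist(e$class_path)),
         domain = domain_from_list(e$domain, "corpus entry"),
         is_leaf = isTRUE(e$is_leaf),
         enriched = as.character(unlist(e$enriched)))
  })
  structure(list(source_model = raw$source_model, entries = entries),
            class = "medical_corpus")
}
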