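#' Harmonization configuration
#'
#' @param lexical_threshold Minimum lexical score to accept a match.
#' @param semantic_threshold Minimum semantic score to accept a match.
#' @param semantic_weights Weights of the token score and the class-path
#'   bonus in the semantic score (must sum to 1).
#' @param unknown_label Reference label used when a source category cannot
#'   be recoded with confidence.
#' @param binary_true,binary_false Case-insensitive lexicons mapping source
#'   values to the 1/0 binary convention.
#' @param unit_conversions Named list `term -> list(scale, offset)` of
#'   explicitly configured numeric rescalings; units are never guessed.
#' @param schema `"reference"` (default) gives every harmonized cohort the
#'   full leaf-term schema in depth-first model order, with NA columns for
#'   unmatched terms, so all cohorts share one schema; `"matched"` keeps
#'   only the accepted terms.
#' @return A list of class `harmonization_config`.
#' @export
harmonization_config <- function(lexical_threshold = 0.80,
                                 semantic_threshold = 0.60,
                                 semantic_weights = c(token = 0.8, path = 0.2),
                                 unknown_label = "unknown",
                                 binary_true = c("yes", "y", "true", "1", "present"),
                                 binary_false = c("no", "n", "false", "0", "absent"),
                                 unit_conversions = list(),
                                 schema = c("reference", "matched")) {
  structure(list(lexical_threshold = lexical_threshold,
                 semantic_threshold = semantic_threshold,
                 semantic_weights = semantic_weights,
                 unknown_label = unknown_label,
                 binary_true = tolower(binary_true),
                 binary_false = tolower(binary_false),
                 unit_conversions = unit_conversions,
                 schema = match.arg(schema)),
            class = "harmonization_config")
}

corpus_leaves <- function(corpus) {
  names(corpus$entries)[vapply(corpus$entries, function(e) isTRUE(e$is_leaf),
                               logical(1))]
}

# Greedy descending-score assignment under injectivity.
# cand: data.frame(column, term, score); ties broken by (term, column).
greedy_assign <- function(cand, threshold, method) {
  cand <- cand[cand$score >= threshold, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(source_column = character(0), reference_term = character(0),
                      score = numeric(0), method = character(0),
                      accepted = logical(0), stringsAsFactors = FALSE))
  cand <- cand[order(-cand$score, cand$term, cand$column), , drop = FALSE]
  used_col <- character(0); used_term <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$column[k] %in% used_col || cand$term[k] %in% used_term) next
    keep[k] <- TRUE
    used_col <- c(used_col, cand$column[k])
    used_term <- c(used_term, cand$term[k])
  }
  acc <- cand[keep, , drop = FALSE]
  data.frame(source_column = acc$column, reference_term = acc$term,
             score = acc$score, method = method, accepted = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lexical matching of source columns to corpus terms
#'
#' The candidate score of a (column, term) pair is the best lexical
#' similarity between the column name and any synonym of the term.
#' Candidates are accepted greedily by descending score (ties broken
#' lexicographically by term then column), subject to the threshold and to
#' injectivity: at most one column per term and one term per column.
#'
#' @param columns Character vector of source column names.
#' @param corpus A `medical_corpus`.
#' @param threshold Acceptance threshold (default 0.80).
#' @return Data frame of accepted matches (`source_column`,
#'   `reference_term`, `score`, `method = "lexical"`, `accepted`).
#' @export
lexical_match <- function(columns, corpus, threshold = 0.80) {
  terms <- corpus_leaves(corpus)
  if (length(terms) == 0 || length(columns) == 0)
    return(greedy_assign(data.frame(column = character(0), term = character(0),
                                    score = numeric(0)), threshold, "lexical"))
  cand <- do.call(rbind, lapply(terms, function(tm) {
    syn <- corpus$entries[[tm]]$synonyms
    s <- lexical_similarity_matrix(columns, syn)
    data.frame(column = columns, term = tm, score = apply(s, 1, max),
               stringsAsFactors = FALSE)
  }))
  greedy_assign(cand, threshold, "lexical")
}

semantic_score <- function(column, entry, weights) {
  ct <- normalize_term(column)
  if (length(ct) == 0) return(0)
  entry_tokens <- unique(unlist(lapply(entry$synonyms, normalize_term)))
  tok_scores <- vapply(ct, function(t) {
    if (t %in% entry_tokens) return(1)
    max(vapply(entry_tokens, function(u) lexical_similarity(t, u), numeric(1)), 0)
  }, numeric(1))
  base <- mean(tok_scores)
  ancestors <- utils::head(entry$class_path, -1)
  bonus <- 0
  for (a in ancestors) {
    at <- normalize_term(a)
    bonus <- max(bonus, length(intersect(ct, at)) / length(ct))
  }
  unname(weights[["token"]] * base + weights[["path"]] * bonus)
}

#' Semantic matching of the lexical-stage residue
#'
#' Runs only on columns and terms left unmatched by [lexical_match()].  The
#' semantic score averages, over the column's tokens, each token's best
#' synonym-aware similarity to the term entry's tokens (1 for a token that
#' appears among the tokens of the term or of any of its synonyms, else
#' lexical similarity), weighted 0.8, plus 0.2 times a class-path bonus:
#' the best token-overlap fraction with any ancestor class.
#'
#' @param columns Character vector of still-unmatched source columns.
#' @param corpus A `medical_corpus`.
#' @param threshold Acceptance threshold (default 0.60).
#' @param exclude_terms Terms already taken by the lexical stage.
#' @param weights Token/path weights, see [harmonization_config()].
#' @return Data frame of accepted matches with `method = "semantic"`.
#' @export
semantic_match <- function(columns, corpus, threshold = 0.60,
                           exclude_terms = character(0),
                           weights = c(token = 0.8, path = 0.2)) {
  terms <- setdiff(corpus_leaves(corpus), exclude_terms)
  if (length(terms) == 0 || length(columns) == 0)
    return(greedy_assign(data.frame(column = character(0), term = character(0),
                                    score = numeric(0)), threshold, "semantic"))
  cand <- do.call(rbind, lapply(terms, function(tm) {
    data.frame(column = columns, term = tm,
               score = vapply(columns, function(cn)
                 semantic_score(cn, corpus$entries[[tm]], weights), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  greedy_assign(cand, threshold, "semantic")
}

#' Build value-standardization transforms for accepted matches
#'
#' Categorical sources are recoded to the reference categories by best
#' lexical similarity of the labels (below 0.5 the configured unknown label
#' is used and a warning recorded); binary sources are mapped through the
#' true/false lexicons to the 0/1 convention; numeric sources get an affine
#' rescale only when one is explicitly configured for the term, otherwise
#' the identity (out-of-range values produce a warning).  A transform is
#' the identity exactly when the observed values already satisfy the
#' reference domain.
#'
#' @param matches Data frame of accepted matches.
#' @param table The cohort data frame the matches refer to.
#' @param corpus A `medical_corpus`.
#' @param config A [harmonization_config()].
#' @return Named list `term -> transform`, each a list with `type`
#'   (`identity`, `recode`, `binary`, `affine`) plus its parameters, and a
#'   `warnings` attribute.
#' @export
build_transforms <- function(matches, table, corpus,
                             config = harmonization_config()) {
  table <- as_cohort_table(table)
  warnings <- character(0)
  transforms <- list()
  for (k in seq_len(nrow(matches))) {
    cn <- matches$source_column[k]
    tm <- matches$reference_term[k]
    dom <- corpus$entries[[tm]]$domain
    v <- table[[cn]]
    obs <- unique(v[!is_missing_cell(v)])
    tr <- list(type = "identity")
    if (dom$kind == "binary") {
      if (!all(obs %in% c("0", "1"))) {
        map <- stats::setNames(rep(NA_character_, length(obs)), obs)
        for (o in obs) {
          lo <- tolower(trimws(o))
          if (lo %in% config$binary_true) map[[o]] <- "1"
          else if (lo %in% config$binary_false) map[[o]] <- "0"
        }
        if (anyNA(map)) {
          warnings <- c(warnings, paste0(
            "column '", cn, "': unmapped binary values ",
            paste(names(map)[is.na(map)], collapse = ", ")))
          map[is.na(map)] <- ""
        }
        tr <- list(type = "binary", map = as.list(map))
      }
    } else if (dom$kind == "categorical") {
      if (!all(obs %in% dom$categories)) {
        map <- stats::setNames(character(length(obs)), obs)
        for (o in obs) {
          sims <- vapply(dom$categories, function(rc)
            lexical_similarity(o, rc), numeric(1))
          if (max(sims) >= 0.5) {
            map[[o]] <- dom$categories[which.max(sims)]
          } else {
            map[[o]] <- config$unknown_label
            warnings <- c(warnings, paste0(
              "column '", cn, "': category '", o, "' mapped to '",
              config$unknown_label, "'"))
          }
        }
        tr <- list(type = "recode", map = as.list(map))
      }
    } else if (dom$kind == "numeric") {
      conv <- config$unit_conversions[[tm]]
      if (!is.null(conv)) {
        tr <- list(type = "affine",
                   scale = conv$scale,
                   offset = if (is.null(conv$offset)) 0 else conv$offset)
      } else {
        num <- suppressWarnings(as.numeric(obs))
        out <- !is.na(num) & (num < dom$range[1] | num > dom$range[2])
        if (any(out)) {
          warnings <- c(warnings, paste0(
            "column '", cn, "': ", sum(out),
            " value(s) outside [", dom$range[1], ", ", dom$range[2],
            "] for term '", tm, "' (no conversion configured)"))
        }
      }
    }
    transforms[[tm]] <- tr
  }
  attr(transforms, "warnings") <- warnings
  transforms
}

apply_transform <- function(values, transform, kind) {
  miss <- is_missing_cell(values)
  out <- switch(transform$type,
    identity = values,
    binary = , recode = {
      v <- values
      m <- unlist(transform$map)
      hit <- !miss & v %in% names(m)
      v[hit] <- m[v[hit]]
      v
    },
    affine = {
      v <- values
      num <- suppressWarnings(as.numeric(v))
      v[!miss & !is.na(num)] <- format_numeric_cell(
        num[!miss & !is.na(num)] * transform$scale + transform$offset)
      v
    })
  # type the output per the reference kind
  if (kind %in% c("numeric", "binary")) {
    res <- suppressWarnings(as.numeric(out))
    res[miss] <- NA
    res
  } else {
    out[miss] <- NA
    out
  }
}

#' Harmonize a curated cohort to the medical corpus
#'
#' Lexical matching, then semantic matching on the residue, then value
#' standardization.  The output table uses canonical term names as columns
#' (leaf terms of the reference model, in depth-first order); by default
#' all leaf terms appear, with NA for unmatched ones, so every cohort
#' harmonized against one model shares a schema.
#'
#' @param table A curated cohort data frame.
#' @param corpus A `medical_corpus`.
#' @param config A [harmonization_config()].
#' @return List with `data` (harmonized data frame; numeric/binary terms as
#'   numeric columns), `mapping` (a `harmonization_mapping`), and
#'   `coverage` (a `coverage_report`).
#' @export
harmonize <- function(table, corpus, config = harmonization_config()) {
  table <- as_cohort_table(table)
  cols <- names(table)
  leaves <- corpus_leaves(corpus)

  lex <- lexical_match(cols, corpus, config$lexical_threshold)
  sem <- semantic_match(setdiff(cols, lex$source_column), corpus,
                        config$semantic_threshold,
                        exclude_terms = lex$reference_term,
                        weights = config$semantic_weights)
  matches <- rbind(lex, sem)
  if (nrow(matches) == 0) stop("no alignment possible")

  transforms <- build_transforms(matches, table, corpus, config)
  out_terms <- if (config$schema == "reference") leaves
               else leaves[leaves %in% matches$reference_term]
  out <- lapply(out_terms, function(tm) {
    kind <- corpus$entries[[tm]]$domain$kind
    k <- match(tm, matches$reference_term)
    if (is.na(k)) {
      if (kind %in% c("numeric", "binary")) rep(NA_real_, nrow(table))
      else rep(NA_character_, nrow(table))
    } else {
      apply_transform(table[[matches$source_column[k]]], transforms[[tm]], kind)
    }
  })
  names(out) <- out_terms
  data <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE,
                        optional = TRUE)
  attr(data, "cohort_id") <- attr(table, "cohort_id")

  n_std <- sum(vapply(matches$reference_term, function(tm)
    transforms[[tm]]$type != "identity", logical(1)))
  mapping <- structure(list(
    cohort_id = attr(table, "cohort_id"),
    matches = matches,
    transforms = transforms,
    unmatched_source = setdiff(cols, matches$source_column),
    unmatched_reference = setdiff(leaves, matches$reference_term),
    warnings = attr(transforms, "warnings"),
    thresholds = c(lexical = config$lexical_threshold,
                   semantic = config$semantic_threshold)
  ), class = "harmonization_mapping")
  coverage <- structure(list(
    n_reference_terms = length(leaves),
    n_matched = nrow(matches),
    coverage_pct = 100 * nrow(matches) / length(leaves),
    n_standardized = n_std,
    thresholds = mapping$thresholds
  ), class = "coverage_report")
  list(data = data, mapping = mapping, coverage = coverage)
}

#' @export
print.harmonization_mapping <- function(x, ...) {
  cat("Harmonization mapping",
      if (!is.null(x$cohort_id)) paste0(" for '", x$cohort_id, "'"), "\n  ",
      nrow(x$matches), " accepted matches (",
      sum(x$matches$method == "lexical"), " lexical, ",
      sum(x$matches$method == "semantic"), " semantic)\n  ",
      length(x$unmatched_source), " unmatched source columns, ",
      length(x$unmatched_reference), " unmatched reference terms\n", sep = "")
  if (length(x$warnings)) cat("  warnings: ", length(x$warnings), "\n", sep = "")
  invisible(x)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d/%d reference terms matched (%.1f%%), %d standardized\n",
              x$n_matched, x$n_reference_terms, x$coverage_pct, x$n_standardized))
  invisible(x)
}

#' Write a harmonization mapping and coverage report to JSON
#' @param mapping A `harmonization_mapping`.
#' @param coverage A `coverage_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_mapping <- function(mapping, coverage, path) {
  obj <- list(
    cohort_id = mapping$cohort_id,
    thresholds = as.list(mapping$thresholds),
    matches = mapping$matches,
    transforms = lapply(mapping$transforms, function(tr) tr),
    unmatched_source = mapping$unmatched_source,
    unmatched_reference = mapping$unmatched_reference,
    warnings = mapping$warnings,
    coverage = list(n_reference_terms = coverage$n_reference_terms,
                    n_matched = coverage$n_matched,
                    coverage_pct = coverage$coverage_pct,
                    n_standardized = coverage$n_standardized)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                              null = "null", na = "null"), path, useBytes = TRUE)
  invisible(path)
}
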