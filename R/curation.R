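#' Curation configuration
#'
#' All curation thresholds live here so that every finding is reproducible
#' from the raw table plus this object.
#'
#' @param missing_tokens Cell values (case-insensitive) parsed as missing,
#'   in addition to the empty string and `NA`.
#' @param bad_missing_threshold A feature with a larger missing fraction is
#'   dropped as uninformative ("bad"); constant features are bad too.
#' @param inconsistency_tolerance Fraction of non-empty values allowed to
#'   violate the observed kind or the mapped value domain before a feature
#'   is flagged inconsistent.
#' @param duplicate_agreement Two columns whose non-empty values agree on at
#'   least this fraction of co-present rows are duplicates.
#' @param outlier_fence IQR multiplier for the outlier fences.
#' @param outlier_min_values Minimum non-empty values needed to assess
#'   outliers for a feature.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(missing_tokens = c("", "na", "n/a", "nan", "null", "-"),
                            bad_missing_threshold = 0.5,
                            inconsistency_tolerance = 0.05,
                            duplicate_agreement = 0.99,
                            outlier_fence = 3,
                            outlier_min_values = 8) {
  structure(list(missing_tokens = tolower(missing_tokens),
                 bad_missing_threshold = bad_missing_threshold,
                 inconsistency_tolerance = inconsistency_tolerance,
                 duplicate_agreement = duplicate_agreement,
                 outlier_fence = outlier_fence,
                 outlier_min_values = outlier_min_values),
            class = "curation_config")
}

is_missing_cell <- function(x, config = curation_config()) {
  is.na(x) | tolower(trimws(as.character(x))) %in% config$missing_tokens
}

parses_numeric <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

looks_like_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$|^\\d{1,2}/\\d{1,2}/\\d{2,4}$", trimws(x))
}

# Coerce any cohort-style input to a character data.frame.
as_cohort_table <- function(table) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(lapply(table, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  attr(out, "cohort_id") <- attr(table, "cohort_id")
  out
}

infer_kind <- function(values, n_rows, config = curation_config()) {
  obs <- values[!is_missing_cell(values, config)]
  if (length(obs) == 0) return("unknown")
  num <- parses_numeric(obs)
  if (mean(num) > 0.5) {
    v <- unique(suppressWarnings(as.numeric(obs[num])))
    if (all(v %in% c(0, 1))) "binary" else "numeric"
  } else if (mean(looks_like_date(obs)) > 0.5) {
    "date"
  } else if (length(unique(obs)) <= max(2, ceiling(0.10 * n_rows))) {
    "categorical"
  } else {
    "unknown"
  }
}

#' Profile the features of a cohort table
#'
#' One descriptor per column: the observed kind (majority vote over
#' non-empty cells — mostly numeric-parseable values make a numeric or, if
#' only 0/1, a binary feature; few distinct non-numeric values make a
#' categorical one), the exact missing fraction, and the distinct-value
#' count.
#'
#' @param table A cohort data frame (cells treated as character).
#' @param declared Optional named character vector of declared kinds per
#'   column (`numeric`, `categorical`, `binary`, `date`, `unknown`).
#' @param config A [curation_config()].
#' @return A data frame of feature descriptors.
#' @export
profile_cohort <- function(table, declared = NULL, config = curation_config()) {
  table <- as_cohort_table(table)
  if (nrow(table) == 0) stop("empty cohort")
  n <- nrow(table)
  desc <- lapply(names(table), function(cn) {
    v <- table[[cn]]
    miss <- is_missing_cell(v, config)
    obs <- v[!miss]
    data.frame(
      column = cn,
      declared_kind = if (!is.null(declared) && cn %in% names(declared))
        declared[[cn]] else "unknown",
      observed_kind = infer_kind(v, n, config),
      missing_fraction = sum(miss) / n,
      n_distinct = length(unique(obs)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, desc)
}

#' Detect inconsistent features
#'
#' A feature is inconsistent when (a) its declared kind disagrees with the
#' observed kind, (b) more than the tolerated fraction of its non-empty
#' values fail to parse under the observed kind, or (c) given a mapping to
#' a reference term, more than the tolerated fraction of values fall
#' outside the term's value domain.  Offending cells for (b)/(c) are
#' listed individually.
#'
#' @param table Cohort data frame.
#' @param profile Output of [profile_cohort()] (computed if `NULL`).
#' @param model Optional `reference_ontology` for domain checks.
#' @param mapping Optional named character vector `column -> term name`
#'   used with `model` for rule (c).
#' @param config A [curation_config()].
#' @return Data frame of findings: `column`, `reason`, and a list-column
#'   `cells` of offending row indices.
#' @export
detect_inconsistent <- function(table, profile = NULL, model = NULL,
                                mapping = NULL, config = curation_config()) {
  table <- as_cohort_table(table)
  if (is.null(profile)) profile <- profile_cohort(table, config = config)
  findings <- list()
  for (i in seq_len(nrow(profile))) {
    cn <- profile$column[i]
    kind <- profile$observed_kind[i]
    v <- table[[cn]]
    miss <- is_missing_cell(v, config)
    obs_idx <- which(!miss)
    if (profile$declared_kind[i] != "unknown" &&
        profile$declared_kind[i] != kind) {
      findings[[length(findings) + 1]] <- data.frame(
        column = cn, reason = "declared_vs_observed", stringsAsFactors = FALSE)
      findings[[length(findings)]]$cells <- I(list(integer(0)))
      next
    }
    bad_idx <- integer(0)
    if (kind %in% c("numeric", "binary")) {
      bad_idx <- obs_idx[!parses_numeric(v[obs_idx])]
      if (kind == "binary") {
        num <- suppressWarnings(as.numeric(v[obs_idx]))
        bad_idx <- union(bad_idx, obs_idx[!is.na(num) & !num %in% c(0, 1)])
      }
    } else if (kind == "date") {
      bad_idx <- obs_idx[!looks_like_date(v[obs_idx])]
    }
    if (length(obs_idx) > 0 &&
        length(bad_idx) / length(obs_idx) > config$inconsistency_tolerance) {
      f <- data.frame(column = cn, reason = "unparseable_values",
                      stringsAsFactors = FALSE)
      f$cells <- I(list(sort(bad_idx)))
      findings[[length(findings) + 1]] <- f
      next
    }
    if (!is.null(model) && !is.null(mapping) && cn %in% names(mapping)) {
      term <- mapping[[cn]]
      if (term %in% names(model$terms)) {
        dom <- model$terms[[term]]$domain
        out_idx <- integer(0)
        if (dom$kind == "numeric") {
          num <- suppressWarnings(as.numeric(v[obs_idx]))
          out_idx <- obs_idx[!is.na(num) &
                               (num < dom$range[1] | num > dom$range[2])]
        } else if (dom$kind %in% c("categorical", "binary")) {
          out_idx <- obs_idx[!v[obs_idx] %in% dom$categories]
        }
        if (length(obs_idx) > 0 &&
            length(out_idx) / length(obs_idx) > config$inconsistency_tolerance) {
          f <- data.frame(column = cn, reason = "out_of_domain",
                          stringsAsFactors = FALSE)
          f$cells <- I(list(sort(out_idx)))
          findings[[length(findings) + 1]] <- f
        } else if (length(out_idx) > 0) {
          f <- data.frame(column = cn, reason = "out_of_domain_cells",
                          stringsAsFactors = FALSE)
          f$cells <- I(list(sort(out_idx)))
          findings[[length(findings) + 1]] <- f
        }
      }
    }
  }
  if (length(findings) == 0)
    return(data.frame(column = character(0), reason = character(0),
                      cells = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Detect duplicated features
#'
#' Two columns are duplicates when their normalized names coincide, or when
#' their non-empty values agree on at least the configured fraction of
#' co-present rows; the later column of each pair is the one flagged.
#' Identical columns with no co-present rows cannot be decided and are
#' recorded as indeterminate.
#'
#' @inheritParams detect_inconsistent
#' @return Data frame with columns `first`, `second`, `agreement`,
#'   `status` (`"duplicate"` or `"indeterminate"`).
#' @export
detect_duplicates <- function(table, config = curation_config()) {
  table <- as_cohort_table(table)
  cols <- names(table)
  res <- list()
  keys <- normalize_key(cols)
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i) next
      same_name <- nzchar(keys[i]) && keys[i] == keys[j]
      a <- table[[i]]; b <- table[[j]]
      co <- !is_missing_cell(a, config) & !is_missing_cell(b, config)
      if (same_name || sum(co) > 0) {
        agree <- if (sum(co) > 0) mean(a[co] == b[co]) else NA_real_
        if (same_name || (!is.na(agree) && agree >= config$duplicate_agreement)) {
          res[[length(res) + 1]] <- data.frame(
            first = cols[i], second = cols[j],
            agreement = agree, status = "duplicate", stringsAsFactors = FALSE)
        }
      } else {
        # no co-present rows: vacuous agreement, undecidable
        res[[length(res) + 1]] <- data.frame(
          first = cols[i], second = cols[j],
          agreement = NA_real_, status = "indeterminate", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(first = character(0), second = character(0),
                      agreement = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Detect outlier cells in numeric features
#'
#' A cell is an outlier when it falls outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` (default `k = 3`, linear-interpolation
#' quartiles).  Fences are computed on the distinct non-empty values of the
#' feature, which makes the detector insensitive to mass-duplicated values
#' (for example a median-imputation spike) while leaving genuinely spread
#' data untouched.  Features with fewer than `outlier_min_values` non-empty
#' values are skipped and recorded as such.  A constant feature has
#' collapsed fences and, equality being inside, no outliers.
#'
#' @inheritParams detect_inconsistent
#' @return List with `cells` (data frame `column`, `row`, `value`) and
#'   `skipped` (character vector of features with too few values).
#' @export
detect_outliers <- function(table, profile = NULL, config = curation_config()) {
  table <- as_cohort_table(table)
  if (is.null(profile)) profile <- profile_cohort(table, config = config)
  cells <- list()
  skipped <- character(0)
  num_cols <- profile$column[profile$observed_kind == "numeric"]
  for (cn in num_cols) {
    v <- table[[cn]]
    miss <- is_missing_cell(v, config)
    num <- suppressWarnings(as.numeric(v))
    obs_idx <- which(!miss & !is.na(num))
    if (length(obs_idx) < config$outlier_min_values) {
      skipped <- c(skipped, cn)
      next
    }
    u <- unique(num[obs_idx])
    q <- stats::quantile(u, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - config$outlier_fence * iqr
    hi <- q[2] + config$outlier_fence * iqr
    out <- obs_idx[num[obs_idx] < lo | num[obs_idx] > hi]
    if (length(out) > 0)
      cells[[length(cells) + 1]] <- data.frame(
        column = cn, row = out, value = v[out], stringsAsFactors = FALSE)
  }
  list(
    cells = if (length(cells) > 0) do.call(rbind, cells)
    else data.frame(column = character(0), row = integer(0),
                    value = character(0), stringsAsFactors = FALSE),
    skipped = skipped
  )
}

feature_mode <- function(values) {
  tab <- table(values)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1]  # tie -> lexicographically smallest
}

format_numeric_cell <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

#' Impute missing values
#'
#' Numeric features receive the feature median (robust to the skew that
#' triggers outlier flags); categorical, binary and other features receive
#' the mode, with ties broken by the lexicographically smallest value.
#' Every imputed cell is recorded.
#'
#' @inheritParams detect_inconsistent
#' @return List with the imputed `table` and an `actions` data frame
#'   (`type = "impute_cell"`, `column`, `row`, `value`).
#' @export
impute_missing <- function(table, profile = NULL, config = curation_config()) {
  table <- as_cohort_table(table)
  if (is.null(profile)) profile <- profile_cohort(table, config = config)
  actions <- list()
  for (i in seq_len(nrow(profile))) {
    cn <- profile$column[i]
    v <- table[[cn]]
    miss <- is_missing_cell(v, config)
    if (!any(miss) || all(miss)) next
    obs <- v[!miss]
    fill <- if (profile$observed_kind[i] == "numeric") {
      format_numeric_cell(stats::median(as.numeric(obs[parses_numeric(obs)])))
    } else {
      feature_mode(obs)
    }
    table[[cn]][miss] <- fill
    actions[[length(actions) + 1]] <- data.frame(
      type = "impute_cell", column = cn, row = which(miss), value = fill,
      stringsAsFactors = FALSE)
  }
  list(table = table,
       actions = if (length(actions) > 0) do.call(rbind, actions)
       else empty_actions())
}

empty_actions <- function() {
  data.frame(type = character(0), column = character(0), row = integer(0),
             value = character(0), stringsAsFactors = FALSE)
}

#' Curate a cohort table
#'
#' The full quality-enhancement pipeline, in fixed order: profile; drop bad
#' features (missing fraction above threshold, or constant); drop
#' inconsistent features; drop the later column of each duplicate pair;
#' blank outlier cells (subsequently treated as missing); impute all
#' remaining missing values.  Rows are never dropped.  The returned report
#' carries a replayable action log: applying it to the raw table with
#' [apply_curation()] reproduces the curated table cell for cell.
#'
#' @param table Cohort data frame.
#' @param model Optional `reference_ontology` for domain-based
#'   inconsistency checks.
#' @param mapping Optional named character vector `column -> term` for the
#'   domain checks.
#' @param declared Optional declared kinds (see [profile_cohort()]).
#' @param config A [curation_config()].
#' @return List with `table` (curated) and `report` (a `curation_report`).
#' @export
curate <- function(table, model = NULL, mapping = NULL, declared = NULL,
                   config = curation_config()) {
  raw <- as_cohort_table(table)
  prof0 <- profile_cohort(raw, declared = declared, config = config)
  actions <- empty_actions()
  drop_column <- function(cn, why) {
    data.frame(type = "drop_column", column = cn, row = NA_integer_,
               value = why, stringsAsFactors = FALSE)
  }
  cur <- raw

  # 1. bad features: too much missingness, or constant among observed values
  bad <- prof0$column[prof0$missing_fraction > config$bad_missing_threshold |
                        prof0$n_distinct <= 1]
  for (cn in bad) actions <- rbind(actions, drop_column(cn, "bad"))
  cur <- cur[, setdiff(names(cur), bad), drop = FALSE]

  # 2. inconsistent features
  prof <- prof0[prof0$column %in% names(cur), , drop = FALSE]
  inc <- detect_inconsistent(cur, prof, model = model, mapping = mapping,
                             config = config)
  inc_cols <- unique(inc$column[inc$reason %in%
                                  c("declared_vs_observed", "unparseable_values",
                                    "out_of_domain")])
  for (cn in inc_cols) actions <- rbind(actions, drop_column(cn, "inconsistent"))
  cur <- cur[, setdiff(names(cur), inc_cols), drop = FALSE]

  # 3. duplicate columns (the later of each pair)
  dup <- detect_duplicates(cur, config = config)
  dup_cols <- unique(dup$second[dup$status == "duplicate"])
  for (cn in dup_cols) actions <- rbind(actions, drop_column(cn, "duplicate"))
  cur <- cur[, setdiff(names(cur), dup_cols), drop = FALSE]
  if (ncol(cur) == 0) stop("no usable features")

  # 4. blank outlier cells
  prof <- profile_cohort(cur, config = config)
  outl <- detect_outliers(cur, prof, config = config)
  if (nrow(outl$cells) > 0) {
    for (k in seq_len(nrow(outl$cells))) {
      cn <- outl$cells$column[k]; r <- outl$cells$row[k]
      cur[[cn]][r] <- ""
      actions <- rbind(actions, data.frame(
        type = "blank_cell", column = cn, row = r, value = "",
        stringsAsFactors = FALSE))
    }
  }

  # 5. impute (kinds re-profiled after blanking)
  prof <- profile_cohort(cur, config = config)
  imp <- impute_missing(cur, prof, config = config)
  cur <- imp$table
  actions <- rbind(actions, imp$actions)

  prof_final <- profile_cohort(cur, config = config)
  report <- structure(list(
    cohort_id = attr(raw, "cohort_id"),
    profile = prof0,
    n_bad = length(bad),
    n_inconsistent = length(inc_cols),
    n_duplicate = length(dup_cols),
    n_outlier_cells = nrow(outl$cells),
    n_imputed_cells = sum(imp$actions$type == "impute_cell"),
    outlier_skipped = outl$skipped,
    total_missing_pct = 100 * mean(prof0$missing_fraction[
      prof0$column %in% names(cur)]),
    actions = actions,
    config = config
  ), class = "curation_report")
  stopifnot(all(prof_final$missing_fraction == 0))
  attr(cur, "cohort_id") <- attr(raw, "cohort_id")
  list(table = cur, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report",
      if (!is.null(x$cohort_id)) paste0(" for '", x$cohort_id, "'"),
      "\n  features profiled: ", nrow(x$profile),
      "\n  dropped: ", x$n_bad, " bad, ", x$n_inconsistent, " inconsistent, ",
      x$n_duplicate, " duplicate",
      "\n  outlier cells blanked: ", x$n_outlier_cells,
      "\n  cells imputed: ", x$n_imputed_cells,
      "\n  raw missingness of retained features: ",
      sprintf("%.2f%%", x$total_missing_pct), "\n", sep = "")
  invisible(x)
}

#' Replay a curation action log
#'
#' Applies the actions recorded in a [curate()] report to the raw table,
#' reproducing the curated table exactly.
#'
#' @param table The raw cohort data frame the report was computed on.
#' @param report A `curation_report`.
#' @return The curated data frame.
#' @export
apply_curation <- function(table, report) {
  cur <- as_cohort_table(table)
  acts <- report$actions
  for (k in seq_len(nrow(acts))) {
    a <- acts[k, ]
    if (a$type == "drop_column") {
      cur <- cur[, setdiff(names(cur), a$column), drop = FALSE]
    } else if (a$type %in% c("blank_cell", "impute_cell")) {
      cur[[a$column]][a$row] <- a$value
    }
  }
  attr(cur, "cohort_id") <- attr(as_cohort_table(table), "cohort_id")
  cur
}
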