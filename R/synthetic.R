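#' Configuration of the synthetic multi-cohort generator
#'
#' Defaults emulate a four-cohort rare-outcome clinical study: a shared
#' latent outcome model with ~5% prevalence, per-cohort schema noise
#' (lexical perturbation, synonym swaps, encoding variants), per-cohort
#' missingness spanning roughly 17-45%, and a small number of injected
#' quality defects per cohort.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_rows Rows per cohort (recycled/truncated to `n_cohorts`).
#' @param n_terms Number of leaf parameters in the generated reference
#'   model.
#' @param depth Hierarchy depth of the generated model.
#' @param term_presence_prob Probability a non-essential parameter is
#'   present in a cohort.
#' @param edit_fraction Fraction of a column name's characters randomly
#'   substituted (at most; rounded down per name).
#' @param synonym_swap_prob Probability a column header is swapped for a
#'   synonym from the lexicon.
#' @param case_noise_prob Probability of case/separator noise on a header.
#' @param missing_rates Per-cohort missing-cell fraction injected into
#'   non-essential columns (exact per-column counts).
#' @param outlier_rate Per-numeric-column fraction of cells replaced by
#'   far-out values (0 disables).
#' @param n_duplicate_cols,n_bad_cols,n_inconsistent_cols Injected defect
#'   columns per cohort.
#' @param prevalence Outcome prevalence the intercept is calibrated to.
#' @param effects Named log-odds per canonical term: per-SD for numeric
#'   terms, per-indicator for binary terms, first-category indicator for
#'   categorical terms.
#' @param min_cases Minimum cases per cohort; if the Bernoulli draw yields
#'   fewer, the highest-risk rows are set to cases so that downstream
#'   matching and evaluation stay defined.
#' @param seed Master seed; identical (config, seed) gives byte-identical
#'   cohorts.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cohorts = 4,
                             n_rows = c(400, 400, 200, 200),
                             n_terms = 20, depth = 3,
                             term_presence_prob = 0.9,
                             edit_fraction = 0.10,
                             synonym_swap_prob = 0.3,
                             case_noise_prob = 0.5,
                             missing_rates = c(0.30, 0.22, 0.15, 0.10),
                             outlier_rate = 0,
                             n_duplicate_cols = 1,
                             n_bad_cols = 1,
                             n_inconsistent_cols = 1,
                             prevalence = 0.05,
                             effects = c("C4" = -3.2,
                                         "lymphadenopathy" = 4.5,
                                         "salivary gland swelling" = 4.0,
                                         "Anti-La" = 3.5,
                                         "rheumatoid factor" = 3.2,
                                         "dry eyes" = 2.9,
                                         "C3" = -1.9,
                                         "gender" = 1.6,
                                         "age" = 0.65),
                             min_cases = 3,
                             seed = 42) {
  stopifnot(n_cohorts >= 2, prevalence > 0, prevalence < 0.5,
            edit_fraction >= 0, edit_fraction <= 1,
            term_presence_prob >= 0, term_presence_prob <= 1)
  structure(list(n_cohorts = n_cohorts,
                 n_rows = rep_len(n_rows, n_cohorts),
                 n_terms = n_terms, depth = depth,
                 term_presence_prob = term_presence_prob,
                 edit_fraction = edit_fraction,
                 synonym_swap_prob = synonym_swap_prob,
                 case_noise_prob = case_noise_prob,
                 missing_rates = rep_len(missing_rates, n_cohorts),
                 outlier_rate = outlier_rate,
                 n_duplicate_cols = n_duplicate_cols,
                 n_bad_cols = n_bad_cols,
                 n_inconsistent_cols = n_inconsistent_cols,
                 prevalence = prevalence, effects = effects,
                 min_cases = min_cases, seed = as.integer(seed)),
            class = "generator_config")
}

core_term_specs <- function() {
  list(
    list(name = "gender", parent = "Demographics",
         domain = value_domain("categorical", categories = c("female", "male"))),
    list(name = "age", parent = "Demographics",
         domain = value_domain("numeric", unit = "years", range = c(18, 90))),
    list(name = "C4", parent = "Complement",
         domain = value_domain("numeric", unit = "mg/dL", range = c(8, 60))),
    list(name = "Anti-La", parent = "Serology", domain = value_domain("binary")),
    list(name = "lymphadenopathy", parent = "Symptoms",
         domain = value_domain("binary")),
    list(name = "salivary gland swelling", parent = "Symptoms",
         domain = value_domain("binary")),
    list(name = "lymphoma", parent = "Outcomes", domain = value_domain("binary"))
  )
}

extra_term_specs <- function() {
  list(
    list(name = "C3", parent = "Complement",
         domain = value_domain("numeric", unit = "mg/dL", range = c(50, 200))),
    list(name = "dry eyes", parent = "Symptoms", domain = value_domain("binary")),
    list(name = "dry mouth", parent = "Symptoms", domain = value_domain("binary")),
    list(name = "fatigue", parent = "Symptoms", domain = value_domain("binary")),
    list(name = "arthralgia", parent = "Symptoms", domain = value_domain("binary")),
    list(name = "raynaud phenomenon", parent = "Symptoms",
         domain = value_domain("binary")),
    list(name = "purpura", parent = "Symptoms", domain = value_domain("binary")),
    list(name = "rheumatoid factor", parent = "Serology",
         domain = value_domain("binary")),
    list(name = "ANA", parent = "Serology", domain = value_domain("binary")),
    list(name = "anti Ro", parent = "Serology", domain = value_domain("binary")),
    list(name = "ESR", parent = "Laboratory",
         domain = value_domain("numeric", unit = "mm/h", range = c(1, 120))),
    list(name = "CRP", parent = "Laboratory",
         domain = value_domain("numeric", unit = "mg/L", range = c(0, 100))),
    list(name = "hemoglobin", parent = "Laboratory",
         domain = value_domain("numeric", unit = "g/dL", range = c(7, 18))),
    list(name = "white cell count", parent = "Laboratory",
         domain = value_domain("numeric", unit = "10^9/L", range = c(1, 20))),
    list(name = "platelet count", parent = "Laboratory",
         domain = value_domain("numeric", unit = "10^9/L", range = c(50, 600))),
    list(name = "IgG", parent = "Laboratory",
         domain = value_domain("numeric", unit = "mg/dL", range = c(500, 3000))),
    list(name = "schirmer test", parent = "Laboratory",
         domain = value_domain("numeric", unit = "mm", range = c(0, 35))),
    list(name = "focus score", parent = "Laboratory",
         domain = value_domain("numeric", unit = "foci/4mm^2", range = c(0, 12)))
  )
}

#' Generate a reference model for synthetic studies
#'
#' A forest-shaped hierarchy with mixed numeric/categorical/binary leaf
#' parameters under grouping classes.  The named core parameters (`C4`,
#' `lymphadenopathy`, `salivary gland swelling`, `Anti-La`, `gender`,
#' `age`, and the outcome `lymphoma`) are always included so that signal-
#' and rule-recovery checks are meaningful; additional realistic clinical
#' parameters are drawn (seeded) until `n_terms` leaves exist.
#'
#' @param n_terms Number of leaf parameters (at least 2; at most 25).
#' @param depth Hierarchy depth: 3 keeps the intermediate `Complement`
#'   class under `Laboratory`; 2 flattens it.
#' @param seed Integer seed.
#' @param required Extra term names (from the built-in clinical pool) that
#'   must be present regardless of the sampling, e.g. every term carrying
#'   a planted effect.
#' @return A `reference_ontology`.
#' @export
generate_reference <- function(n_terms = 20, depth = 3, seed = 42,
                               required = character(0)) {
  stopifnot(n_terms >= 2)
  set.seed(seed)
  core <- core_term_specs()
  extra <- extra_term_specs()
  extra_names <- vapply(extra, `[[`, character(1), "name")
  req_idx <- which(extra_names %in% required)
  specs <- if (n_terms <= length(core)) {
    core[seq_len(n_terms)]
  } else {
    k <- min(n_terms - length(core), length(extra))
    pool <- union(req_idx, seq_along(extra))
    pick <- req_idx
    if (k > length(pick))
      pick <- c(pick, sample(setdiff(seq_along(extra), pick), k - length(pick)))
    c(core, extra[sort(pick[seq_len(k)])])
  }
  if (depth < 3) {
    specs <- lapply(specs, function(s) {
      if (s$parent == "Complement") s$parent <- "Laboratory"
      s
    })
  }
  parents_used <- unique(vapply(specs, `[[`, character(1), "parent"))
  terms <- list()
  add <- function(t) terms[[length(terms) + 1]] <<- t
  for (root in intersect(c("Demographics", "Laboratory", "Serology",
                           "Symptoms", "Outcomes"),
                         c(parents_used, if ("Complement" %in% parents_used)
                           "Laboratory"))) {
    add(reference_term(root, value_domain("binary"),
                       description = paste(root, "grouping class")))
  }
  if ("Complement" %in% parents_used)
    add(reference_term("Complement", value_domain("binary"),
                       description = "complement proteins", parent = "Laboratory"))
  for (s in specs)
    add(reference_term(s$name, s$domain, parent = s$parent))
  reference_ontology(terms, name = "pss_reference", version = "1.0")
}

# Shared latent study parameters: drawn once per study so every cohort
# samples from the same distributions and outcome model.
study_shared <- function(model, config) {
  set.seed(config$seed)
  leaves <- leaf_terms(model)
  stats <- list()
  for (tm in leaves) {
    dom <- model$terms[[tm]]$domain
    if (dom$kind == "numeric") {
      lo <- dom$range[1]; hi <- dom$range[2]
      mu <- stats::runif(1, lo + 0.3 * (hi - lo), lo + 0.6 * (hi - lo))
      sdv <- (hi - lo) / 8
      stats[[tm]] <- list(kind = "numeric", mean = mu, sd = sdv,
                          lo = lo, hi = hi,
                          integer = tm == "age")
    } else if (dom$kind == "binary") {
      stats[[tm]] <- list(kind = "binary", prevalence = stats::runif(1, 0.15, 0.45))
    } else {
      k <- length(dom$categories)
      pr <- if (tm == "gender") c(0.9, rep(0.1 / (k - 1), k - 1)) else {
        g <- stats::rgamma(k, 2)
        g / sum(g)
      }
      stats[[tm]] <- list(kind = "categorical", categories = dom$categories,
                          probs = pr)
    }
  }
  list(stats = stats, effects = config$effects, lexicon = builtin_synonyms())
}

perturb_name <- function(name, config, lexicon) {
  key <- normalize_key(name)
  if (stats::runif(1) < config$synonym_swap_prob && key %in% names(lexicon)) {
    syn <- lexicon[[key]]
    name <- syn[sample.int(length(syn), 1)]
  }
  if (stats::runif(1) < config$case_noise_prob) {
    sep <- sample(c(" ", "_", "-"), 1)
    name <- gsub(" ", sep, name, fixed = TRUE)
    style <- sample(3, 1)
    if (style == 1) name <- toupper(name)
    else if (style == 2) {
      substr(name, 1, 1) <- toupper(substr(name, 1, 1))
    }
  }
  n_edits <- floor(config$edit_fraction * nchar(name))
  if (n_edits > 0) {
    chars <- strsplit(name, "")[[1]]
    alpha <- which(grepl("[a-zA-Z]", chars))
    if (length(alpha) > 0) {
      pos <- sample(alpha, min(n_edits, length(alpha)))
      chars[pos] <- sample(letters, length(pos), replace = TRUE)
      name <- paste(chars, collapse = "")
    }
  }
  name
}

#' Generate one synthetic cohort with ground truth
#'
#' Samples patient covariates from the study's shared per-term
#' distributions, draws the rare outcome from a logistic model whose
#' intercept is calibrated to the configured prevalence, renames columns by
#' lexical perturbation and synonym swaps, re-encodes some binary and
#' categorical columns to variant encodings, and injects missingness and
#' quality defects at recorded locations.  The outcome, age and sex
#' columns are kept complete (they drive matching and evaluation).
#'
#' @param model A `reference_ontology` (see [generate_reference()]).
#' @param config A [generator_config()].
#' @param cohort_index Index of the cohort (1-based; selects size, missing
#'   rate and the cohort's sub-seed).
#' @param shared Internal: pre-drawn shared study parameters.
#' @return List with `table` (character data frame, one row per patient)
#'   and `truth` (column map, defect locations, labels, effects).
#' @export
generate_cohort <- function(model, config, cohort_index, shared = NULL) {
  if (is.null(shared)) shared <- study_shared(model, config)
  n <- config$n_rows[cohort_index]
  essential <- c("lymphoma", "age", "gender")
  set.seed(config$seed + 1009L * cohort_index)
  leaves <- leaf_terms(model)
  present <- vapply(leaves, function(tm) {
    tm %in% essential || tm %in% names(shared$effects) ||
      stats::runif(1) < config$term_presence_prob
  }, logical(1))
  present_terms <- leaves[present]

  # latent values
  values <- list()
  for (tm in present_terms) {
    st <- shared$stats[[tm]]
    values[[tm]] <- switch(st$kind,
      numeric = {
        v <- pmin(pmax(stats::rnorm(n, st$mean, st$sd), st$lo), st$hi)
        if (isTRUE(st$integer)) round(v) else round(v, 2)
      },
      binary = stats::rbinom(n, 1, st$prevalence),
      categorical = sample(st$categories, n, replace = TRUE, prob = st$probs))
  }

  # outcome from the shared logistic model
  lp <- rep(0, n)
  for (tm in names(shared$effects)) {
    if (!tm %in% present_terms || tm == "lymphoma") next
    st <- shared$stats[[tm]]
    contrib <- switch(st$kind,
      numeric = (values[[tm]] - st$mean) / st$sd,
      binary = values[[tm]],
      categorical = as.numeric(values[[tm]] == st$categories[1]))
    lp <- lp + shared$effects[[tm]] * contrib
  }
  f <- function(a) mean(stats::plogis(a + lp)) - config$prevalence
  a <- stats::uniroot(f, c(-30, 10))$root
  p <- stats::plogis(a + lp)
  y <- stats::rbinom(n, 1, p)
  if (sum(y) < config$min_cases) {
    y[order(-p)[seq_len(config$min_cases)]] <- 1
  }
  values[["lymphoma"]] <- y

  # encode to character cells with per-column encoding variants
  encodings <- list()
  cols <- list()
  for (tm in present_terms) {
    st <- shared$stats[[tm]]
    v <- values[[tm]]
    if (st$kind == "binary" && tm != "lymphoma") {
      enc <- sample(c("01", "yesno", "truefalse"), 1, prob = c(0.5, 0.3, 0.2))
      cell <- switch(enc, "01" = as.character(v),
                     yesno = ifelse(v == 1, "yes", "no"),
                     truefalse = ifelse(v == 1, "TRUE", "FALSE"))
    } else if (st$kind == "categorical") {
      enc <- sample(c("plain", "title"), 1)
      cell <- if (enc == "title")
        vapply(as.character(v), function(s) {
          substr(s, 1, 1) <- toupper(substr(s, 1, 1)); s
        }, character(1), USE.NAMES = FALSE)
      else as.character(v)
    } else {
      enc <- "plain"
      cell <- vapply(v, format_numeric_cell, character(1))
    }
    encodings[[tm]] <- enc
    cols[[tm]] <- cell
  }

  # perturb headers (unique after perturbation)
  new_names <- character(length(present_terms))
  for (i in seq_along(present_terms)) {
    nm <- perturb_name(present_terms[i], config, shared$lexicon)
    if (nm %in% new_names[seq_len(i - 1)]) nm <- paste(nm, i)
    new_names[i] <- nm
  }
  column_map <- stats::setNames(present_terms, new_names)
  tab <- stats::setNames(cols, new_names)
  tab <- as.data.frame(tab, stringsAsFactors = FALSE, check.names = FALSE,
                       optional = TRUE)

  # inject missingness (exact per-column counts; essentials stay complete)
  miss_rate <- config$missing_rates[cohort_index]
  missing_cells <- list()
  for (nm in new_names) {
    if (column_map[[nm]] %in% essential) next
    k <- floor(miss_rate * n)
    if (k > 0) {
      rows <- sample.int(n, k)
      tab[[nm]][rows] <- ""
      missing_cells[[nm]] <- rows
    }
  }

  # inject outlier cells in numeric non-essential columns
  outlier_cells <- data.frame(column = character(0), row = integer(0),
                              stringsAsFactors = FALSE)
  if (config$outlier_rate > 0) {
    for (nm in new_names) {
      tm <- column_map[[nm]]
      st <- shared$stats[[tm]]
      if (st$kind != "numeric" || tm %in% essential) next
      k <- max(1, round(config$outlier_rate * n))
      ok <- which(!is_missing_cell(tab[[nm]]))
      rows <- sample(ok, min(k, length(ok)))
      tab[[nm]][rows] <- format_numeric_cell(st$hi + 10 * (st$hi - st$lo))
      outlier_cells <- rbind(outlier_cells,
                             data.frame(column = nm, row = rows,
                                        stringsAsFactors = FALSE))
    }
  }

  # defect columns
  inconsistent_cols <- character(0)
  if (config$n_inconsistent_cols > 0) {
    for (i in seq_len(config$n_inconsistent_cols)) {
      nm <- paste("extra measurement", i)
      v <- vapply(round(stats::rnorm(n, 10, 2), 2), format_numeric_cell,
                  character(1))
      bad_rows <- sample.int(n, max(1, ceiling(0.08 * n)))
      v[bad_rows] <- "invalid"
      tab[[nm]] <- v
      inconsistent_cols <- c(inconsistent_cols, nm)
    }
  }
  bad_cols <- character(0)
  if (config$n_bad_cols > 0) {
    for (i in seq_len(config$n_bad_cols)) {
      nm <- paste("free text note", i)
      tab[[nm]] <- rep("", n)
      bad_cols <- c(bad_cols, nm)
    }
  }
  duplicate_cols <- character(0)
  if (config$n_duplicate_cols > 0) {
    src <- sample(new_names, min(config$n_duplicate_cols, length(new_names)))
    for (nm in src) {
      dn <- paste(nm, "copy")
      tab[[dn]] <- tab[[nm]]
      duplicate_cols <- c(duplicate_cols, dn)
    }
  }

  attr(tab, "cohort_id") <- paste0("cohort", cohort_index)
  list(table = tab,
       truth = list(cohort_id = paste0("cohort", cohort_index),
                    column_map = column_map,
                    present_terms = present_terms,
                    encodings = encodings,
                    labels = y,
                    intercept = a,
                    effects = shared$effects,
                    missing_cells = missing_cells,
                    outlier_cells = outlier_cells,
                    duplicate_cols = duplicate_cols,
                    bad_cols = bad_cols,
                    inconsistent_cols = inconsistent_cols))
}

#' Generate a full synthetic multi-cohort study
#'
#' Cohorts share one latent outcome model (the planted signal) but differ
#' in schema perturbation, value encodings, missingness and sizes; default
#' sizes (200, 200, 100, 100) echo a 3-train / 1-test split at desk scale.
#'
#' @param config A [generator_config()].
#' @param model Optional pre-built `reference_ontology`; generated from
#'   the config when `NULL`.
#' @return List with `cohorts` (named list of tables), `truth` (per-cohort
#'   ground-truth slices plus the shared parameters), `model`, and
#'   `config`.
#' @export
generate_study <- function(config = generator_config(), model = NULL) {
  if (is.null(model))
    model <- generate_reference(config$n_terms, config$depth, config$seed,
                                required = names(config$effects))
  shared <- study_shared(model, config)
  out <- lapply(seq_len(config$n_cohorts), function(i)
    generate_cohort(model, config, i, shared))
  cohorts <- lapply(out, `[[`, "table")
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  truths <- lapply(out, `[[`, "truth")
  names(truths) <- names(cohorts)
  list(cohorts = cohorts,
       truth = list(cohorts = truths, shared = shared),
       model = model, config = config)
}

#' Fraction of planted column-to-term links recovered by a mapping
#'
#' @param mapping A `harmonization_mapping`.
#' @param truth A per-cohort ground-truth slice from [generate_cohort()].
#' @return Recovered fraction in `[0, 1]` of the planted pairs whose
#'   column reached the harmonizer.
#' @export
mapping_recovery <- function(mapping, truth) {
  seen <- c(mapping$matches$source_column, mapping$unmatched_source)
  planted <- truth$column_map[names(truth$column_map) %in% seen]
  if (length(planted) == 0) return(NA_real_)
  hit <- vapply(names(planted), function(cn) {
    k <- match(cn, mapping$matches$source_column)
    !is.na(k) && mapping$matches$reference_term[k] == planted[[cn]]
  }, logical(1))
  mean(hit)
}
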