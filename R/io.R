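#' Read a cohort table from CSV
#'
#' Cells are read as character (one row per patient, one column per
#' feature); kind inference is left to [profile_cohort()].
#'
#' @param path CSV file with a header row.
#' @param cohort_id Identifier attached to the table (default: file name).
#' @param sep Field delimiter.
#' @return A character data frame with a `cohort_id` attribute.
#' @export
read_cohort <- function(path, cohort_id = NULL, sep = ",") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        sep = sep)
  attr(df, "cohort_id") <- if (is.null(cohort_id))
    tools::file_path_sans_ext(basename(path)) else cohort_id
  df
}

#' Write a cohort table to CSV
#' @param table Data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' Write a curation report to JSON
#' @param report A `curation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_curation_report <- function(report, path) {
  obj <- list(cohort_id = report$cohort_id,
              profile = report$profile,
              counts = list(bad = report$n_bad,
                            inconsistent = report$n_inconsistent,
                            duplicate = report$n_duplicate,
                            outlier_cells = report$n_outlier_cells,
                            imputed_cells = report$n_imputed_cells),
              total_missing_pct = report$total_missing_pct,
              actions = report$actions)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                              null = "null", na = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' Write a consistency report to JSON
#' @param report A `consistency_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_consistency_report <- function(report, path) {
  obj <- list(alpha = report$alpha, reference = report$reference,
              pass = report$pass,
              explained_variance = report$explained_variance,
              tests = report$tests)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                              null = "null", na = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' Write an evaluation summary (and its ROC points) to JSON/CSV
#' @param summary An `evaluation_summary`.
#' @param path Output JSON path.
#' @param roc_path Optional CSV path for the per-run ROC points.
#' @return `path`, invisibly.
#' @export
save_evaluation_summary <- function(summary, path, roc_path = NULL) {
  obj <- list(algorithm = summary$plan$algorithm,
              train = summary$plan$train, test = summary$plan$test,
              n_runs = summary$plan$n_runs,
              metrics = summary$metrics,
              summary = as.data.frame(summary$summary),
              mean_age_gap = summary$mean_age_gap)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA,
                              null = "null", na = "null"), path, useBytes = TRUE)
  if (!is.null(roc_path)) {
    roc <- do.call(rbind, lapply(seq_along(summary$runs), function(r)
      cbind(run = r, summary$runs[[r]]$roc)))
    utils::write.csv(roc, roc_path, row.names = FALSE)
  }
  invisible(path)
}
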