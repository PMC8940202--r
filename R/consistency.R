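#' First two principal components of a harmonized numeric matrix
#'
#' Columns are z-scored (zero-variance columns dropped with a warning)
#' before an eigendecomposition of the covariance (= correlation) matrix.
#' Components are ordered by decreasing eigenvalue and signed so that each
#' component's largest-magnitude loading is positive, making results
#' reproducible across solvers.
#'
#' @param x Numeric matrix or data frame, at least 3 rows and 2 usable
#'   (non-constant) numeric columns.
#' @return List with `scores` (n x 2), `explained_variance` (shares of the
#'   first two eigenvalues over all eigenvalues), `loadings`, and
#'   `dropped` (names of zero-variance columns).
#' @export
first_two_pcs <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 3) stop("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  drop <- which(is.na(sds) | sds == 0)
  dropped <- if (length(drop)) colnames(x)[drop] else character(0)
  if (length(drop) > 0) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, -drop, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 usable numeric columns")
  z <- scale(x)
  e <- eigen(stats::cov(z), symmetric = TRUE)
  v <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  scores <- z %*% v
  colnames(scores) <- c("PC1", "PC2")
  list(scores = scores,
       explained_variance = e$values[1:2] / sum(e$values),
       loadings = v,
       dropped = dropped)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' The statistic is the sum of the ranks of `x` in the pooled ranking
#' (midranks for ties).  The p-value is exact — by enumeration over all
#' rank assignments — when the combined sample size is at most 12 and
#' there are no ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `statistic` (rank sum of `x`), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  ties <- any(duplicated(pooled))
  if (n <= 12 && !ties) {
    sums <- utils::combn(n, nx, FUN = sum)
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    list(statistic = w, p.value = p, method = "exact")
  } else {
    e <- nx * (n + 1) / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab)
    v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
    z <- max(0, abs(w - e) - 0.5) / sqrt(v)
    list(statistic = w, p.value = min(1, 2 * stats::pnorm(-z)),
         method = "normal")
  }
}

numeric_view <- function(df) {
  keep <- vapply(df, function(col) {
    v <- suppressWarnings(as.numeric(as.character(col)))
    !all(is.na(v))
  }, logical(1))
  m <- vapply(df[keep], function(col)
    suppressWarnings(as.numeric(as.character(col))), numeric(nrow(df)))
  matrix(m, nrow = nrow(df), dimnames = list(NULL, names(df)[keep]))
}

#' Post-harmonization consistency check
#'
#' Fits the first two principal components once on the integrated dataset
#' (row-concatenation of all cohorts), projects every cohort's rows into
#' that shared basis, and compares, per cohort and per component, the
#' cohort's score distribution with the integrated one via the rank-sum
#' test.  By default each cohort is compared against the remaining pooled
#' rows (`reference = "complement"`), so the two samples are independent
#' and the test holds its nominal size; `reference = "pooled"` compares
#' against the full integrated scores instead (the cohort is then a subset
#' of the comparison sample, which makes the test conservative).  The
#' check passes when every test's p-value exceeds `alpha`.
#'
#' @param cohorts Named list of harmonized data frames sharing one schema.
#' @param alpha Significance level (default 0.05).
#' @param reference `"complement"` or `"pooled"`.
#' @return A `consistency_report`: data frame of per-cohort, per-component
#'   tests, the explained-variance shares, and the overall pass flag.
#' @export
consistency_check <- function(cohorts, alpha = 0.05,
                              reference = c("complement", "pooled")) {
  reference <- match.arg(reference)
  stopifnot(length(cohorts) >= 1)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  schemas <- lapply(cohorts, names)
  for (k in seq_along(cohorts)) {
    if (!identical(schemas[[k]], schemas[[1]])) {
      diff <- union(setdiff(schemas[[k]], schemas[[1]]),
                    setdiff(schemas[[1]], schemas[[k]]))
      stop("schema mismatch between cohorts '", names(cohorts)[1], "' and '",
           names(cohorts)[k], "'; differing columns: ",
           paste(diff, collapse = ", "))
    }
  }
  pooled_df <- do.call(rbind, lapply(unname(cohorts), function(x) {
    rownames(x) <- NULL
    x
  }))
  pooled <- numeric_view(pooled_df)
  complete <- colSums(is.na(pooled)) == 0
  if (sum(complete) < 2)
    stop("need at least 2 complete numeric columns across cohorts")
  pooled <- pooled[, complete, drop = FALSE]
  pcs <- first_two_pcs(pooled)
  idx <- rep(names(cohorts), vapply(cohorts, nrow, integer(1)))
  tests <- list()
  for (cn in names(cohorts)) {
    own <- pcs$scores[idx == cn, , drop = FALSE]
    other <- if (reference == "complement")
      pcs$scores[idx != cn, , drop = FALSE] else pcs$scores
    for (comp in 1:2) {
      if (nrow(other) == 0) {
        tests[[length(tests) + 1]] <- data.frame(
          cohort = cn, component = comp, statistic = NA_real_,
          p_value = 1, pass = TRUE, stringsAsFactors = FALSE)
      } else {
        tst <- rank_sum_test(own[, comp], other[, comp])
        tests[[length(tests) + 1]] <- data.frame(
          cohort = cn, component = comp, statistic = tst$statistic,
          p_value = tst$p.value, pass = tst$p.value > alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, tests)
  structure(list(tests = tests,
                 explained_variance = pcs$explained_variance,
                 alpha = alpha, reference = reference,
                 pass = all(tests$pass)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency check (alpha = %g, reference = %s): %s\n  PC1/PC2 explained variance: %.3f / %.3f\n",
    x$alpha, x$reference, if (x$pass) "PASS" else "FAIL",
    x$explained_variance[1], x$explained_variance[2]))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
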