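#' Age- and sex-matched control downsampling
#'
#' For each case (in seed-randomized order) greedily selects, without
#' replacement, `ratio` controls of the same sex with minimal absolute age
#' difference (ties broken by the smaller row index).  When same-sex
#' controls run out the selection falls back to nearest-age controls of
#' any sex and a warning is recorded; when fewer than `ratio * n_cases`
#' controls exist at all, every control is returned with an insufficiency
#' warning.
#'
#' @param space Data frame of one private space (harmonized cohort).
#' @param outcome,age,sex Column names of the binary outcome (0/1), age in
#'   years, and sex.
#' @param ratio Controls per case (default 2, the 1:2 design).
#' @param seed Integer seed randomizing the case order.
#' @return Integer vector of selected control row indices, with attributes
#'   `cases` (case row indices), `warnings`, and `mean_age_gap`.
#' @export
match_controls <- function(space, outcome = "lymphoma", age = "age",
                           sex = "gender", ratio = 2, seed = 0) {
  y <- as.numeric(as.character(space[[outcome]]))
  cases <- which(y == 1)
  controls <- which(y == 0)
  if (length(cases) == 0) stop("no positive class")
  warnings <- character(0)
  ages <- suppressWarnings(as.numeric(as.character(space[[age]])))
  sexes <- as.character(space[[sex]])
  if (length(controls) < ratio * length(cases)) {
    warnings <- c(warnings, sprintf(
      "insufficient controls: %d needed, %d available; using all",
      ratio * length(cases), length(controls)))
    out <- controls
    attr(out, "cases") <- cases
    attr(out, "warnings") <- warnings
    attr(out, "mean_age_gap") <- NA_real_
    return(out)
  }
  set.seed(seed)
  case_order <- if (length(cases) > 1) sample(cases) else cases
  avail <- rep(TRUE, nrow(space))
  avail[-controls] <- FALSE
  selected <- integer(0)
  gaps <- numeric(0)
  fallback <- FALSE
  for (ci in case_order) {
    for (k in seq_len(ratio)) {
      cand <- which(avail & sexes == sexes[ci])
      if (length(cand) == 0) {
        cand <- which(avail)
        fallback <- TRUE
      }
      if (length(cand) == 0) break
      gap <- abs(ages[cand] - ages[ci])
      gap[is.na(gap)] <- Inf
      pick <- cand[which.min(gap)]  # which.min: first (smallest index) on ties
      avail[pick] <- FALSE
      selected <- c(selected, pick)
      gaps <- c(gaps, abs(ages[pick] - ages[ci]))
    }
  }
  if (fallback)
    warnings <- c(warnings, "same-sex controls exhausted; nearest-age fallback used")
  out <- selected
  attr(out, "cases") <- cases
  attr(out, "warnings") <- warnings
  attr(out, "mean_age_gap") <- mean(gaps[is.finite(gaps)])
  out
}

# ---- feature encoding and scaling (fitted on the first batch, frozen) ----

# Numeric columns are passed through and, when they take enough distinct
# values, additionally expanded into quartile-bin indicators (breakpoints
# from the reference batch).  The indicator expansion gives the count-based
# model family (multinomial NB) access to the information continuous labs
# carry, and is redundant-but-harmless for the other families.
build_encoder <- function(df, columns) {
  spec <- lapply(columns, function(cn) {
    col <- df[[cn]]
    if (is.numeric(col)) {
      v <- col[!is.na(col)]
      breaks <- if (length(unique(v)) > 4)
        stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      else NULL
      list(type = "numeric", breaks = breaks)
    } else {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      list(type = "onehot", levels = lv)
    }
  })
  names(spec) <- columns
  structure(list(columns = columns, spec = spec), class = "feature_encoder")
}

apply_encoder <- function(encoder, df) {
  pieces <- lapply(encoder$columns, function(cn) {
    sp <- encoder$spec[[cn]]
    col <- df[[cn]]
    if (sp$type == "numeric") {
      v <- as.numeric(col)
      m <- matrix(v, ncol = 1)
      colnames(m) <- cn
      if (!is.null(sp$breaks)) {
        b <- findInterval(v, sp$breaks)
        ind <- vapply(0:3, function(k) as.numeric(b == k), numeric(length(v)))
        ind <- matrix(ind, nrow = length(v))
        ind[is.na(v), ] <- NA
        colnames(ind) <- paste0(cn, "|q", 1:4)
        m <- cbind(m, ind)
      }
      m
    } else {
      v <- as.character(col)
      m <- vapply(sp$levels, function(l) as.numeric(!is.na(v) & v == l),
                  numeric(length(v)))
      m <- matrix(m, nrow = length(v))
      m[is.na(v), ] <- NA
      colnames(m) <- paste0(cn, "=", sp$levels)
      m
    }
  })
  do.call(cbind, pieces)
}

fit_scaler <- function(x) {
  structure(list(min = apply(x, 2, min, na.rm = TRUE),
                 max = apply(x, 2, max, na.rm = TRUE),
                 source = "first_batch"),
            class = "minmax_scaler")
}

apply_scaler <- function(scaler, x) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  z <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  z[z < 0] <- 0
  z[z > 1] <- 1
  z[is.na(z)] <- 0.5  # unobserved feature value: midpoint of the frozen scale
  z
}

# ---- per-algorithm hyperparameter grids ----

#' Default hyperparameter grid of an algorithm
#'
#' @param algorithm One of `"xgboost"`, `"svm_linear"`, `"logistic"`,
#'   `"multinomial_nb"`, `"mlp"`.
#' @return Data frame, one row per configuration, in declaration order.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    xgboost = expand.grid(nrounds = c(15, 30), max_depth = c(2, 3),
                          eta = c(0.05, 0.1)),
    svm_linear = ,
    logistic = data.frame(lambda = c(1e-4, 1e-3, 1e-2)),
    mlp = data.frame(size = c(16, 32), epochs = c(20, 20)),
    multinomial_nb = data.frame(smoothing = c(1, 2, 5)),
    stop("unknown algorithm '", algorithm, "'")
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- algorithm cores -----------------------------------------------------

nb_init <- function(xs, y, smoothing) {
  list(class_counts = c(sum(y == 0), sum(y == 1)),
       feature_sums = rbind(colSums(xs[y == 0, , drop = FALSE]),
                            colSums(xs[y == 1, , drop = FALSE])),
       smoothing = smoothing)
}

nb_accumulate <- function(state, xs, y) {
  state$class_counts <- state$class_counts +
    c(sum(y == 0), sum(y == 1))
  state$feature_sums <- state$feature_sums +
    rbind(colSums(xs[y == 0, , drop = FALSE]),
          colSums(xs[y == 1, , drop = FALSE]))
  state
}

nb_log_conditionals <- function(state) {
  a <- state$smoothing
  p <- ncol(state$feature_sums)
  log((state$feature_sums + a) / (rowSums(state$feature_sums) + a * p))
}

nb_predict <- function(state, xs) {
  logprior <- log(state$class_counts / sum(state$class_counts))
  logcond <- nb_log_conditionals(state)
  joint <- sweep(xs %*% t(logcond), 2, logprior, "+")
  m <- apply(joint, 1, max)
  ex <- exp(joint - m)
  ex[, 2] / rowSums(ex)
}

sgd_epochs_per_batch <- 100L

sgd_pass <- function(state, xs, y, loss, lambda, seed) {
  set.seed(seed)
  n <- nrow(xs)
  w <- state$w; b <- state$b; t <- state$t
  eta0 <- 0.5
  for (ep in seq_len(sgd_epochs_per_batch)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- eta0 / (1 + eta0 * lambda * t)
      xi <- xs[i, ]
      z <- sum(w * xi) + b
      if (loss == "log") {
        g <- sigmoid(z) - y[i]
        w <- w - eta * (g * xi + lambda * w)
        b <- b - eta * g
      } else {  # hinge
        ypm <- 2 * y[i] - 1
        if (ypm * z < 1) {
          w <- w - eta * (lambda * w - ypm * xi)
          b <- b + eta * ypm
        } else {
          w <- w - eta * lambda * w
        }
      }
    }
  }
  list(w = w, b = b, t = t)
}

xgb_params <- function(hp) {
  # row/column subsampling guards against overfitting the small matched
  # batches (tens of rows) typical of rare-outcome downsampled training
  list(objective = "binary:logistic", max_depth = as.integer(hp$max_depth),
       eta = hp$eta, subsample = 0.8, colsample_bytree = 0.8,
       nthread = 1, base_score = 0.5)
}

xgb_chain_margin <- function(boosters, xs) {
  m <- rep(0, nrow(xs))
  for (b in boosters) {
    dm <- xgboost::xgb.DMatrix(xs, base_margin = m, nthread = 1)
    m <- predict(b, dm, outputmargin = TRUE)
  }
  m
}

# ---- incremental model interface ----------------------------------------

#' Fit an incremental model on its first batch
#'
#' Fits one of the five supported classifier families on the first
#' (matched, downsampled) batch and returns a handle that can be advanced
#' over later batches with [update_model()] without revisiting earlier
#' data.  Per-algorithm incremental contracts: multinomial naive Bayes
#' accumulates class/feature sufficient statistics; linear SVM and
#' logistic regression take stochastic-gradient passes (hinge / log loss);
#' the multi-layer perceptron continues gradient training from its current
#' weights; boosted trees append rounds using the existing ensemble's
#' margin as base margin.  A min-max scaling to `[0, 1]` is fitted on this
#' first batch, frozen, and applied to every later batch and to test data
#' for all algorithms (multinomial NB requires nonnegative features; the
#' same scale keeps the families comparable).
#'
#' @param algorithm `"xgboost"`, `"svm_linear"`, `"logistic"`,
#'   `"multinomial_nb"` or `"mlp"`.
#' @param x Numeric feature matrix with column names.
#' @param y Binary outcome vector (0/1); both classes must be present.
#' @param hyperparams Named list of hyperparameters; missing entries fall
#'   back to the first row of [default_grid()].
#' @param seed Integer seed pinning all stochastic components.
#' @return An object of class `incremental_model`.
#' @export
init_fit <- function(algorithm, x, y, hyperparams = NULL, seed = 0) {
  algorithm <- match.arg(algorithm, c("xgboost", "svm_linear", "logistic",
                                      "multinomial_nb", "mlp"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("first batch must contain both classes")
  hp <- as.list(default_grid(algorithm)[1, , drop = FALSE])
  for (nm in names(hyperparams)) hp[[nm]] <- hyperparams[[nm]]
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  state <- switch(algorithm,
    multinomial_nb = nb_init(xs, y, hp$smoothing),
    logistic = sgd_pass(list(w = rep(0, ncol(xs)), b = 0, t = 0),
                        xs, y, "log", hp$lambda, seed),
    svm_linear = sgd_pass(list(w = rep(0, ncol(xs)), b = 0, t = 0),
                          xs, y, "hinge", hp$lambda, seed),
    mlp = {
      set.seed(seed)
      fit <- nnet::nnet(x = xs, y = y, size = hp$size, maxit = hp$epochs,
                        decay = 1e-3, entropy = TRUE, trace = FALSE,
                        MaxNWts = 100000)
      list(fit = fit, size = hp$size, epochs = hp$epochs)
    },
    xgboost = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(xs, label = y,
                                     base_margin = rep(0, nrow(xs)),
                                     nthread = 1)
      b <- xgboost::xgb.train(params = xgb_params(hp), data = dtrain,
                              nrounds = as.integer(hp$nrounds), verbose = 0)
      list(boosters = list(b), rounds = as.integer(hp$nrounds))
    })
  structure(list(algorithm = algorithm, hyperparams = hp, scaler = scaler,
                 feature_names = colnames(x), n_batches_seen = 1L,
                 seed = seed, state = state),
            class = "incremental_model")
}

#' Advance an incremental model with a new batch
#'
#' @param model An `incremental_model`.
#' @param x Feature matrix of the new batch (same columns as at init).
#' @param y Binary outcome vector; a single-class batch is skipped with a
#'   warning.
#' @return The updated model.
#' @export
update_model <- function(model, x, y) {
  x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_names))
    stop("schema mismatch: batch columns differ from the model's schema")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    warning("single-class batch skipped")
    return(model)
  }
  xs <- apply_scaler(model$scaler, x)
  batch_seed <- model$seed + 31L * model$n_batches_seen
  model$state <- switch(model$algorithm,
    multinomial_nb = nb_accumulate(model$state, xs, y),
    logistic = sgd_pass(model$state, xs, y, "log",
                        model$hyperparams$lambda, batch_seed),
    svm_linear = sgd_pass(model$state, xs, y, "hinge",
                          model$hyperparams$lambda, batch_seed),
    mlp = {
      set.seed(batch_seed)
      fit <- nnet::nnet(x = xs, y = y, size = model$state$size,
                        maxit = model$state$epochs, decay = 1e-3,
                        entropy = TRUE, trace = FALSE, MaxNWts = 100000,
                        Wts = model$state$fit$wts)
      list(fit = fit, size = model$state$size, epochs = model$state$epochs)
    },
    xgboost = {
      set.seed(batch_seed)
      m <- xgb_chain_margin(model$state$boosters, xs)
      dtrain <- xgboost::xgb.DMatrix(xs, label = y, base_margin = m,
                                     nthread = 1)
      b <- xgboost::xgb.train(params = xgb_params(model$hyperparams),
                              data = dtrain,
                              nrounds = as.integer(model$hyperparams$nrounds),
                              verbose = 0)
      list(boosters = c(model$state$boosters, list(b)),
           rounds = c(model$state$rounds,
                      as.integer(model$hyperparams$nrounds)))
    })
  model$n_batches_seen <- model$n_batches_seen + 1L
  model
}

#' Class-1 probability scores of an incremental model
#'
#' @param object An `incremental_model`.
#' @param x Feature matrix (same columns as at init).
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.incremental_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!identical(colnames(x), object$feature_names))
    stop("schema mismatch: columns differ from the model's schema")
  xs <- apply_scaler(object$scaler, x)
  switch(object$algorithm,
    multinomial_nb = nb_predict(object$state, xs),
    logistic = ,
    svm_linear = sigmoid(as.numeric(xs %*% object$state$w + object$state$b)),
    mlp = as.numeric(predict(object$state$fit, xs)),
    xgboost = sigmoid(xgb_chain_margin(object$state$boosters, xs)))
}

#' @export
print.incremental_model <- function(x, ...) {
  cat("Incremental model (", x$algorithm, "): ", x$n_batches_seen,
      " batch(es) seen, ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

# ---- hyperparameter optimization ----------------------------------------

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- if (length(idx) > 1) sample(idx) else idx
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Grid-search hyperparameter optimization on the first training batch
#'
#' Exhaustive search over the grid with stratified k-fold (default 3)
#' cross-validation, selecting the configuration with the highest mean AUC
#' (ties go to the earliest grid row).  If a training fold ends up with a
#' single class the fold count drops to 2; if still degenerate, an error
#' is raised.
#'
#' @param algorithm Algorithm id (see [init_fit()]).
#' @param x,y First training batch (matrix and 0/1 outcome).
#' @param grid Data frame of configurations; `NULL` for [default_grid()].
#' @param seed Integer seed for fold assignment and fits.
#' @param folds Number of CV folds.
#' @param repeats Number of repeated fold assignments averaged per
#'   configuration; repetition stabilizes the selection on the small
#'   matched batches this stage sees.
#' @return List with `hyperparams` (the selected row, as a list) and `cv`
#'   (per-configuration mean AUC log).
#' @export
tune_hyperparameters <- function(algorithm, x, y, grid = NULL, seed = 0,
                                 folds = 3, repeats = 3) {
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  x <- as.matrix(x); y <- as.numeric(y)
  k <- folds
  assignments <- list()
  for (rep_i in seq_len(repeats)) {
    repeat {
      fold <- stratified_folds(y, k, seed + 7919L * (rep_i - 1L))
      degenerate <- any(vapply(seq_len(k), function(f)
        length(unique(y[fold != f])) < 2 || length(unique(y[fold == f])) < 2,
        logical(1)))
      if (!degenerate) break
      if (k > 2) k <- 2
      else stop("cross-validation folds are single-class; batch too degenerate")
    }
    assignments[[rep_i]] <- fold
  }
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- as.list(grid[g, , drop = FALSE])
    aucs <- unlist(lapply(assignments, function(fold)
      vapply(seq_len(k), function(f) {
        m <- init_fit(algorithm, x[fold != f, , drop = FALSE], y[fold != f],
                      hyperparams = hp, seed = seed)
        s <- predict(m, x[fold == f, , drop = FALSE])
        trapezoid_auc(s, y[fold == f])
      }, numeric(1))))
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)  # first max on ties = earliest grid row
  list(hyperparams = as.list(grid[best, , drop = FALSE]),
       cv = cbind(grid, mean_auc = mean_auc))
}

# ---- evaluation ----------------------------------------------------------

#' ROC points by threshold sweep
#'
#' @param scores Numeric class-1 scores.
#' @param labels Binary labels (0/1).
#' @return Data frame of `(threshold, fpr, tpr)` ordered from the strictest
#'   threshold down, starting at (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  np <- sum(labels == 1); nn <- sum(labels == 0)
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(l == 1)[keep]
  fp <- cumsum(l == 0)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / nn),
             tpr = c(0, tp / np))
}

#' Trapezoidal area under the ROC curve
#'
#' Equals the concordant-pair (Mann-Whitney) statistic with ties counted
#' one half.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
trapezoid_auc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Evaluate a fitted model on a held-out test space
#'
#' The full test space is scored (no downsampling at test time), classes
#' are decided at probability 0.5, and accuracy, sensitivity, specificity
#' and the trapezoidal AUC are computed from the confusion counts and the
#' threshold-swept ROC.
#'
#' @param model An `incremental_model`.
#' @param x Test feature matrix.
#' @param y Test binary labels; both classes must be present.
#' @return A `run_result`: confusion counts, the four metrics, and the ROC
#'   points.
#' @export
evaluate_model <- function(model, x, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("single-class test set: metrics undefined")
  scores <- predict(model, x)
  pred <- as.numeric(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  structure(list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = trapezoid_auc(scores, y),
    roc = roc_points(scores, y),
    scores = scores
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

# ---- experiment orchestration -------------------------------------------

#' Define an incremental training plan
#'
#' @param train Character vector of training space ids, in update order.
#' @param test Single test space id (must not appear in `train`).
#' @param algorithm Algorithm id (see [init_fit()]).
#' @param n_runs Number of repeats with different control subsets.
#' @param seeds One seed per run; defaults to `0:(n_runs - 1)`.
#' @param control_ratio Controls per case in the matched downsampling.
#' @param outcome,age,sex Column names in the harmonized spaces.
#' @param grid Hyperparameter grid (`NULL` for the default).
#' @param tune Whether to run grid-search CV on the first space's batch.
#' @return A list of class `training_plan`.
#' @export
training_plan <- function(train, test, algorithm = "xgboost", n_runs = 5,
                          seeds = NULL, control_ratio = 2,
                          outcome = "lymphoma", age = "age", sex = "gender",
                          grid = NULL, tune = TRUE) {
  if (test %in% train) stop("test space must not appear among training spaces")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(seeds)) seeds <- seq(0, n_runs - 1)
  if (length(seeds) != n_runs) stop("need one seed per run")
  structure(list(train = train, test = test, algorithm = algorithm,
                 n_runs = n_runs, seeds = as.integer(seeds),
                 control_ratio = control_ratio, outcome = outcome,
                 age = age, sex = sex, grid = grid, tune = tune),
            class = "training_plan")
}

space_features <- function(spaces, plan) {
  cols <- setdiff(names(spaces[[plan$train[1]]]), plan$outcome)
  for (s in plan$train) {
    df <- spaces[[s]]
    complete <- vapply(cols, function(cn) !anyNA(df[[cn]]), logical(1))
    cols <- cols[complete]
  }
  if (length(cols) == 0) stop("no complete features across training spaces")
  cols
}

#' Run an incremental training/testing experiment
#'
#' For every run: age/sex-matched 1:2 control downsampling in each training
#' space with the run's seed, hyperparameter tuning on the first space's
#' batch, an initial fit there, incremental updates through the remaining
#' training spaces in order, and evaluation on the full held-out test
#' space.  Feature encoding (one-hot for categorical terms) and the min-max
#' scaling are derived from the first training batch only.  The summary
#' reports each metric's mean and standard deviation across runs.
#'
#' @param plan A [training_plan()].
#' @param spaces Named list of harmonized data frames (shared schema).
#' @return An `evaluation_summary`: per-run results, per-metric mean/sd,
#'   the selected hyperparameters per run, and the final run's model and
#'   pooled training matrix (for [extract_rules()]).
#' @export
run_experiment <- function(plan, spaces) {
  stopifnot(inherits(plan, "training_plan"))
  missing_spaces <- setdiff(c(plan$train, plan$test), names(spaces))
  if (length(missing_spaces) > 0)
    stop("unknown spaces: ", paste(missing_spaces, collapse = ", "))
  features <- space_features(spaces, plan)
  runs <- list()
  chosen <- list()
  age_gaps <- numeric(0)
  final_model <- NULL
  train_pool <- NULL
  for (r in seq_len(plan$n_runs)) {
    s <- plan$seeds[r]
    batches <- list()
    for (i in seq_along(plan$train)) {
      sp <- spaces[[plan$train[i]]]
      sel <- match_controls(sp, plan$outcome, plan$age, plan$sex,
                            ratio = plan$control_ratio, seed = s + 131L * i)
      rows <- c(attr(sel, "cases"), as.integer(sel))
      age_gaps <- c(age_gaps, attr(sel, "mean_age_gap"))
      batches[[i]] <- sp[rows, , drop = FALSE]
    }
    encoder <- build_encoder(batches[[1]], features)
    xs <- lapply(batches, function(b) apply_encoder(encoder, b))
    ys <- lapply(batches, function(b) as.numeric(as.character(b[[plan$outcome]])))
    hp <- if (isTRUE(plan$tune)) {
      tuned <- tune_hyperparameters(plan$algorithm, xs[[1]], ys[[1]],
                                    grid = plan$grid, seed = s)
      tuned$hyperparams
    } else NULL
    model <- init_fit(plan$algorithm, xs[[1]], ys[[1]], hyperparams = hp,
                      seed = s)
    if (length(batches) > 1) {
      for (i in 2:length(batches)) model <- update_model(model, xs[[i]], ys[[i]])
    }
    test_df <- spaces[[plan$test]]
    x_test <- apply_encoder(encoder, test_df)
    y_test <- as.numeric(as.character(test_df[[plan$outcome]]))
    runs[[r]] <- evaluate_model(model, x_test, y_test)
    chosen[[r]] <- model$hyperparams
    final_model <- model
    train_pool <- do.call(rbind, xs)
  }
  metrics <- data.frame(
    run = seq_len(plan$n_runs),
    accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
    sensitivity = vapply(runs, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(runs, `[[`, numeric(1), "specificity"),
    auc = vapply(runs, `[[`, numeric(1), "auc"))
  mean_sd <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  structure(list(
    plan = plan, runs = runs, metrics = metrics,
    summary = rbind(accuracy = mean_sd(metrics$accuracy),
                    sensitivity = mean_sd(metrics$sensitivity),
                    specificity = mean_sd(metrics$specificity),
                    auc = mean_sd(metrics$auc)),
    hyperparams = chosen,
    mean_age_gap = mean(age_gaps, na.rm = TRUE),
    final_model = final_model,
    train_pool = train_pool
  ), class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("Incremental experiment (", x$plan$algorithm, "): train ",
      paste(x$plan$train, collapse = " -> "), ", test ", x$plan$test,
      ", ", x$plan$n_runs, " run(s)\n", sep = "")
  s <- x$summary
  for (m in rownames(s))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, s[m, "mean"], s[m, "sd"]))
  invisible(x)
}

#' Leave-one-cohort-out evaluation
#'
#' Iterates the training plan over every choice of test space (the
#' remaining spaces train, in their given order).
#'
#' @param spaces Named list of harmonized data frames.
#' @param ... Arguments passed to [training_plan()] (except `train`/`test`).
#' @return Named list of `evaluation_summary`, one per held-out space.
#' @export
leave_one_cohort_out <- function(spaces, ...) {
  out <- lapply(names(spaces), function(ts) {
    plan <- training_plan(train = setdiff(names(spaces), ts), test = ts, ...)
    run_experiment(plan, spaces)
  })
  names(out) <- names(spaces)
  out
}

# ---- rule extraction ------------------------------------------------------

#' Extract decision rules from a boosted-tree model
#'
#' Fits a single shallow surrogate regression tree to the model's predicted
#' class-1 probabilities on the pooled training data, so the ensemble's
#' decision surface is summarized by a handful of readable splits; leaf
#' values are the mean predicted class-1 probability in the leaf.  Also
#' reports the top gain-ranked features of the ensemble.
#'
#' @param model An `incremental_model` with `algorithm = "xgboost"`.
#' @param x Pooled training feature matrix.
#' @param max_depth Maximum surrogate depth (default 3).
#' @param top_k Number of gain-ranked features to report.
#' @param cp Complexity parameter of the surrogate fit.
#' @return A `decision_rule_tree`: the surrogate `rpart` fit, the features
#'   used at internal nodes, leaf probabilities, and the gain-ranked
#'   `top_features`.
#' @export
extract_rules <- function(model, x, max_depth = 3, top_k = 5, cp = 0.05) {
  if (!inherits(model, "incremental_model") || model$algorithm != "xgboost")
    stop("rules available for xgboost only")
  x <- as.matrix(x)
  probs <- predict(model, x)
  safe <- make.names(colnames(x), unique = TRUE)
  name_map <- stats::setNames(colnames(x), safe)
  df <- as.data.frame(x)
  colnames(df) <- safe
  df$.prob <- probs
  fit <- rpart::rpart(.prob ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = cp, minsplit = 10,
                        minbucket = 10, xval = 0))
  vars <- as.character(fit$frame$var)
  node_features <- unname(name_map[unique(vars[vars != "<leaf>"])])
  leaves <- fit$frame[vars == "<leaf>", c("n", "yval")]
  names(leaves) <- c("n", "class1_probability")
  imp <- list()
  for (b in model$state$boosters) {
    tab <- tryCatch(xgboost::xgb.importance(model = b), error = function(e) NULL)
    if (!is.null(tab) && nrow(tab) > 0)
      imp[[length(imp) + 1]] <- data.frame(feature = tab$Feature,
                                           gain = tab$Gain)
  }
  top_features <- character(0)
  if (length(imp) > 0) {
    agg <- stats::aggregate(gain ~ feature, do.call(rbind, imp), sum)
    agg <- agg[order(-agg$gain), ]
    top_features <- utils::head(agg$feature, top_k)
  }
  structure(list(tree = fit, node_features = node_features,
                 leaves = leaves, top_features = top_features,
                 max_depth = max_depth),
            class = "decision_rule_tree")
}

#' @export
print.decision_rule_tree <- function(x, ...) {
  cat("Surrogate decision tree (depth <=", x$max_depth, ")\n")
  print(x$tree)
  cat("Top gain-ranked features:", paste(x$top_features, collapse = ", "), "\n")
  invisible(x)
}
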