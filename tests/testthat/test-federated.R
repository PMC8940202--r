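test_that("control matching honors the 1:2 sex-concordant nearest-age design", {
  set.seed(20)
  n <- 105
  space <- data.frame(
    lymphoma = c(rep(1, 5), rep(0, 100)),
    age = c(40, 50, 60, 70, 80, round(runif(100, 20, 90))),
    gender = c(rep("female", 5),
               sample(c("female", "male"), 100, replace = TRUE)),
    check.names = FALSE)
  sel <- match_controls(space, ratio = 2, seed = 1)
  expect_length(sel, 10)
  expect_true(all(space$gender[sel] == "female"))
  expect_true(all(space$lymphoma[sel] == 0))
  expect_false(anyDuplicated(sel) > 0)
  # exhaustion: fewer controls than needed returns them all with a warning
  small <- data.frame(lymphoma = c(rep(1, 5), rep(0, 7)),
                      age = round(runif(12, 30, 70)),
                      gender = rep("female", 12), check.names = FALSE)
  sel2 <- match_controls(small, ratio = 2, seed = 1)
  expect_length(sel2, 7)
  expect_match(attr(sel2, "warnings"), "insufficient")
  expect_error(match_controls(data.frame(lymphoma = rep(0, 5), age = 1:5,
                                         gender = rep("female", 5)),
                              seed = 1), "no positive class")
})

test_that("nearest-age selection equals a brute-force matching oracle", {
  space <- data.frame(
    lymphoma = c(1, 1, rep(0, 8)),
    age = c(50, 70, 49, 52, 55, 61, 68, 72, 80, 90),
    gender = rep("female", 10), check.names = FALSE)
  sel <- match_controls(space, ratio = 2, seed = 3)
  # greedy oracle in case order sampled with the same seed
  set.seed(3)
  order_cases <- sample(c(1L, 2L))
  avail <- 3:10
  expected <- integer(0)
  for (ci in order_cases) {
    for (k in 1:2) {
      gap <- abs(space$age[avail] - space$age[ci])
      pick <- avail[which.min(gap)]
      avail <- setdiff(avail, pick)
      expected <- c(expected, pick)
    }
  }
  expect_equal(as.integer(sel), expected)
})

test_that("multinomial NB accumulates exact sufficient statistics", {
  x <- matrix(c(1, 0, 1, 0,
                0, 1, 1, 0), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(0, 0, 1, 1)
  m <- init_fit("multinomial_nb", x, y, hyperparams = list(smoothing = 1))
  expect_equal(unname(m$state$class_counts), c(2, 2))
  expect_equal(unname(m$state$feature_sums),
               rbind(c(1, 1), c(1, 1)))
  # incremental update equals the pooled fit exactly (shared scaler)
  set.seed(30)
  xb <- matrix(rbinom(200, 1, 0.4), 50, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  xb[1, ] <- 0; xb[2, ] <- 1   # pin the min-max scale in the first batch
  yb <- rep(c(0, 1), 25)
  m1 <- init_fit("multinomial_nb", xb[1:30, ], yb[1:30],
                 hyperparams = list(smoothing = 1))
  m1 <- update_model(m1, xb[31:50, ], yb[31:50])
  mp <- init_fit("multinomial_nb", xb, yb, hyperparams = list(smoothing = 1))
  expect_equal(m1$state$feature_sums, mp$state$feature_sums, tolerance = 1e-12)
  expect_equal(m1$state$class_counts, mp$state$class_counts)
  # repeating the first batch doubles every sufficient statistic,
  # leaving the class priors identical
  m2 <- update_model(init_fit("multinomial_nb", xb, yb,
                              hyperparams = list(smoothing = 1)), xb, yb)
  expect_equal(unname(m2$state$class_counts), 2 * unname(mp$state$class_counts))
  expect_equal(m2$state$feature_sums, 2 * mp$state$feature_sums,
               tolerance = 1e-12)
  expect_equal(m2$state$class_counts / sum(m2$state$class_counts),
               mp$state$class_counts / sum(mp$state$class_counts))
})

test_that("models are deterministic and guard their schema", {
  set.seed(31)
  x <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c(0, 1), 25)
  probe <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  for (alg in c("xgboost", "svm_linear", "logistic", "multinomial_nb", "mlp")) {
    m1 <- init_fit(alg, x, y, seed = 5)
    m2 <- init_fit(alg, x, y, seed = 5)
    expect_equal(predict(m1, probe), predict(m2, probe), tolerance = 1e-12)
    bad <- probe; colnames(bad) <- paste0("w", 1:4)
    expect_error(predict(m1, bad), "schema mismatch")
    expect_error(update_model(m1, bad, rep(c(0, 1), 5)), "schema mismatch")
    expect_warning(update_model(m1, probe, rep(1, 10)), "single-class")
  }
  expect_error(init_fit("logistic", x, rep(1, 50)), "both classes")
})

test_that("linear SVM separates separable data and xgboost appends rounds", {
  set.seed(32)
  x <- matrix(c(runif(30, 0, 0.3), runif(30, 0.7, 1)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 30)
  m <- init_fit("svm_linear", x, y, hyperparams = list(lambda = 1e-4), seed = 1)
  expect_equal(mean((predict(m, x) >= 0.5) == y), 1)
  # xgboost: updates append boosting rounds on top of the existing margin
  set.seed(33)
  x2 <- matrix(runif(300), 75, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y2 <- as.numeric(x2[, 1] + 0.3 * runif(75) > 0.65)
  mb <- init_fit("xgboost", x2[1:40, ], y2[1:40],
                 hyperparams = list(nrounds = 5, max_depth = 2, eta = 0.3),
                 seed = 2)
  mb2 <- update_model(mb, x2[41:75, ], y2[41:75])
  expect_equal(mb2$state$rounds, c(5L, 5L))
  n_trees <- sum(vapply(mb2$state$boosters, function(b)
    length(grep("booster\\[", xgboost::xgb.dump(b))), integer(1)))
  expect_equal(n_trees, 10L)
  expect_equal(mb2$n_batches_seen, 2L)
  # the update changes predictions where the new batch carries signal
  expect_false(isTRUE(all.equal(predict(mb, x2), predict(mb2, x2))))
})

test_that("grid search selects by cross-validated AUC with stable ties", {
  set.seed(34)
  y <- rep(c(0, 1), each = 20)
  x <- cbind(s = rnorm(40, 2.5 * y), n = rnorm(40))
  grid <- data.frame(lambda = c(0.5, 1e-4))  # heavy vs light regularization
  tuned <- tune_hyperparameters("logistic", x, y, grid = grid, seed = 1)
  expect_equal(tuned$hyperparams$lambda, 1e-4)
  expect_equal(nrow(tuned$cv), 2)
  # size-1 grid still runs CV and returns the entry
  t2 <- tune_hyperparameters("multinomial_nb", x, y,
                             grid = data.frame(smoothing = 2), seed = 1)
  expect_equal(t2$hyperparams$smoothing, 2)
  # determinism
  t3 <- tune_hyperparameters("logistic", x, y, grid = grid, seed = 1)
  expect_identical(tuned$hyperparams, t3$hyperparams)
})

test_that("evaluation metrics follow their confusion-count identities", {
  m <- structure(list(algorithm = "logistic",
                      feature_names = "f",
                      scaler = structure(list(min = 0, max = 1,
                                              source = "first_batch"),
                                         class = "minmax_scaler"),
                      state = list(w = 20, b = -10)),
                 class = "incremental_model")
  x <- matrix(c(0.9, 0.8, 0.3, 0.2), ncol = 1, dimnames = list(NULL, "f"))
  r <- evaluate_model(m, x, c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # AUC = concordant-pair fraction: scores (.9,.3,.8,.2) -> 3/4
  expect_equal(trapezoid_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  # random scores on a large balanced set sit at 1/2
  set.seed(35)
  expect_lt(abs(trapezoid_auc(runif(2000), rep(c(0, 1), 1000)) - 0.5), 0.03)
  expect_error(evaluate_model(m, x, rep(1, 4)), "single-class")
  # identities recomputed from stored confusion counts
  cc <- r$confusion
  expect_equal(r$accuracy, (cc["tp"] + cc["tn"]) / sum(cc),
               ignore_attr = TRUE)
  expect_equal(r$sensitivity, cc["tp"] / (cc["tp"] + cc["fn"]),
               ignore_attr = TRUE)
  expect_equal(r$specificity, cc["tn"] / (cc["tn"] + cc["fp"]),
               ignore_attr = TRUE)
})

test_that("experiments run end to end with deterministic summaries", {
  spaces <- list(s1 = toy_space(150, 40), s2 = toy_space(150, 41),
                 s3 = toy_space(120, 42), s4 = toy_space(150, 43))
  plan <- training_plan(train = c("s1", "s2", "s3"), test = "s4",
                        algorithm = "logistic", n_runs = 2, seeds = 0:1,
                        tune = FALSE)
  r1 <- run_experiment(plan, spaces)
  r2 <- run_experiment(plan, spaces)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$summary["auc", "mean"], mean(r1$metrics$auc))
  expect_equal(r1$summary["auc", "sd"], sd(r1$metrics$auc))
  # a single run reports zero dispersion
  plan1 <- training_plan(train = c("s1", "s2"), test = "s4",
                         algorithm = "multinomial_nb", n_runs = 1, seeds = 7,
                         tune = FALSE)
  rr <- run_experiment(plan1, spaces)
  expect_equal(unname(rr$summary[, "sd"]), rep(0, 4))
  expect_equal(rr$summary["accuracy", "mean"], rr$runs[[1]]$accuracy)
  # test space never appears among training spaces
  expect_error(training_plan(train = c("s1", "s4"), test = "s4"),
               "must not appear")
  # scaling and encoding derive from the first batch only
  expect_equal(r1$final_model$scaler$source, "first_batch")
  # leave-one-cohort-out covers every space as the held-out one
  loco <- leave_one_cohort_out(spaces[1:3], algorithm = "multinomial_nb",
                               n_runs = 1, seeds = 0, tune = FALSE)
  expect_equal(names(loco), names(spaces)[1:3])
})

test_that("rule extraction summarizes the boosted model and guards its input", {
  set.seed(36)
  n <- 200
  x <- cbind(driver = rbinom(n, 1, 0.5), other = runif(n))
  y <- x[, "driver"]
  m <- init_fit("xgboost", x, y,
                hyperparams = list(nrounds = 20, max_depth = 2, eta = 0.3),
                seed = 1)
  rules <- extract_rules(m, x)
  expect_equal(rules$node_features, "driver")
  expect_equal(rules$top_features[1], "driver")
  expect_true(all(rules$leaves$class1_probability >= 0 &
                    rules$leaves$class1_probability <= 1))
  stump <- extract_rules(m, x, max_depth = 1)
  expect_lte(length(stump$node_features), 1)
  m2 <- init_fit("logistic", x, y, seed = 1)
  expect_error(extract_rules(m2, x), "xgboost only")
})
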