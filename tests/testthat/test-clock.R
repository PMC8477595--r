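test_that("the lambda grid spans 1e-3 to 1e3 with 100 log-spaced values", {
  g <- make_lambda_grid()
  expect_length(g, 100)
  expect_equal(g[1], 1e-3)
  expect_equal(g[100], 1e3)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 99), tolerance = 1e-12)
})

test_that("lambda = 0 matches the OLS oracle on an n > p toy", {
  set.seed(9)
  n <- 10; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  y <- 2 + X %*% c(1, -0.5, 0.2) + rnorm(n, 0, 0.1)
  for (alpha in c(0, 0.5, 1)) {
    m <- fit_final(X, drop(y), alpha = alpha, grid = c(1e-8, 1e-4, 1),
                   lambda = 1e-8, thresh = 1e-14)
    pred <- predict_age(m, X)
    b <- ols_oracle(X, drop(y))
    pred_ols <- drop(cbind(1, X) %*% b)
    expect_equal(as.numeric(pred), pred_ols, tolerance = 1e-6)
  }
})

test_that("lambda -> infinity drives predictions to the training mean", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("L", 1:3)))
  y <- rnorm(20, 25, 10)
  m <- fit_final(X, y, alpha = 0.5, grid = c(1e5, 1e6), lambda = 1e6)
  expect_equal(as.numeric(predict_age(m, X)), rep(mean(y), 20), tolerance = 1e-6)
  expect_equal(m$n_loci_selected, 0)
})

test_that("tuning is deterministic given the seed", {
  d <- small_dataset(seed = 6L)
  t1 <- tune(d$matrix, d$ages, seed = 5L)
  t2 <- tune(d$matrix, d$ages, seed = 5L)
  expect_identical(t1$lambda_best, t2$lambda_best)
  expect_equal(t1$cv_metrics, t2$cv_metrics)
  expect_error(tune(d$matrix[1:5, ], d$ages[1:5], folds = 10), "folds")
  expect_error(tune(d$matrix, rep(1, length(d$ages))), "constant")
})

test_that("ridge keeps all loci; lasso and elastic net are sparse on sparse truth", {
  set.seed(11)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p, 50, 5), n, p,
              dimnames = list(NULL, paste0("L", 1:p)))
  ages <- runif(n, 0, 51)
  X[, 1] <- 20 + 0.9 * ages + rnorm(n, 0, 1)
  X[, 2] <- 70 - 0.7 * ages + rnorm(n, 0, 1)
  ridge <- fit_final(X, ages, alpha = 0, seed = 2L)
  enet <- fit_final(X, ages, alpha = 0.5, seed = 2L)
  lasso <- fit_final(X, ages, alpha = 1, seed = 2L)
  expect_equal(length(ridge$coefficients), p)
  expect_lt(enet$n_loci_selected, p)
  expect_lt(lasso$n_loci_selected, p)
  expect_true(all(c("L1", "L2") %in% names(enet$coefficients)))
})

test_that("elastic-net objective at the fit is below OLS and zero solutions", {
  set.seed(12)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  y <- drop(5 + X %*% rnorm(p) + rnorm(n, 0, 0.5))
  lambda <- 0.5; alpha <- 0.5
  m <- fit_final(X, y, alpha = alpha, grid = c(lambda, 1), lambda = lambda,
                 thresh = 1e-12)
  std <- rdnaclock:::standardize_fit(X)
  beta <- setNames(rep(0, p), colnames(X))
  beta[names(m$coefficients)] <- m$coefficients
  obj_fit <- rdnaclock:::enet_objective(std$X, y, m$intercept, beta, lambda, alpha)
  b_ols <- ols_oracle(std$X, y)
  obj_ols <- rdnaclock:::enet_objective(std$X, y, b_ols[1], b_ols[-1], lambda, alpha)
  obj_zero <- rdnaclock:::enet_objective(std$X, y, mean(y), rep(0, p), lambda, alpha)
  expect_lte(obj_fit, obj_ols + 1e-8)
  expect_lte(obj_fit, obj_zero + 1e-8)
})

test_that("training MAE is non-decreasing in lambda at fixed alpha", {
  set.seed(13)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p, 50, 4), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  ages <- runif(n, 0, 51)
  X[, 1] <- 30 + 0.8 * ages + rnorm(n)
  grid <- 10^seq(-3, 3, length.out = 20)
  fits <- lapply(grid, function(l)
    fit_final(X, ages, alpha = 0.5, grid = grid, lambda = l, thresh = 1e-12))
  rmse <- vapply(fits, function(m) m$metrics$rmse, numeric(1))
  mae <- vapply(fits, function(m) m$metrics$mae, numeric(1))
  # the objective penalizes squared error, so training RMSE is monotone in
  # lambda; MAE tracks it but is only near-monotone
  expect_true(all(diff(rmse) > -1e-8))
  expect_true(all(diff(mae) > -1e-2))
})

test_that("predict_age applies the standardized linear form exactly", {
  model <- structure(list(
    alpha = 0.5, lambda = 1, intercept = 5,
    coefficients = c(L1 = 0.5), center = c(L1 = 20), scale = c(L1 = 10),
    n_loci_selected = 1L, metrics = list(), version = "0"),
    class = "ClockModel")
  X <- matrix(40, 1, 1, dimnames = list("s1", "L1"))
  expect_equal(as.numeric(predict_age(model, X)), 6)
  expect_error(predict_age(model, matrix(1, 1, 1, dimnames = list(NULL, "Lx"))),
               "model loci")
})

test_that("negative predictions are reported and flagged, not truncated", {
  model <- structure(list(
    alpha = 0.5, lambda = 1, intercept = -5,
    coefficients = c(L1 = 1), center = c(L1 = 0), scale = c(L1 = 1),
    n_loci_selected = 1L, metrics = list(), version = "0"),
    class = "ClockModel")
  X <- matrix(c(-2, 10), 2, 1, dimnames = list(c("a", "b"), "L1"))
  p <- predict_age(model, X)
  expect_equal(as.numeric(p), c(-7, 5))
  expect_equal(unname(attr(p, "flagged_negative")), c(TRUE, FALSE))
})

test_that("serialized models reload to identical predictions", {
  d <- small_dataset(seed = 14L)
  m <- fit_final(d$matrix, d$ages, seed = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  clock_write_json(m, path)
  m2 <- clock_read_json(path)
  expect_equal(as.numeric(predict_age(m2, d$matrix)),
               as.numeric(predict_age(m, d$matrix)), tolerance = 1e-12)
})

test_that("precision_sd is the n-1 SD of differences and bias-blind", {
  expect_equal(precision_sd(c(10, 20), c(11, 19)), sqrt(2))
  expect_equal(precision_sd(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(precision_sd(c(3, 4, 5), c(1, 2, 3)), 0)  # constant offset
  expect_error(precision_sd(1:3, 1:2), "mismatch")
  expect_error(precision_sd(1, 1), "at least 2")
})

test_that("LOOCV holds each sample out of its own training set", {
  set.seed(15)
  n <- 5
  X <- matrix(rnorm(n * 2, 50, 5), n, 2,
              dimnames = list(paste0("s", 1:n), c("L1", "L2")))
  ages <- runif(n, 0, 51)
  rep <- loocv(X, ages, alpha = 0.5, grid = c(0.01, 1), folds = 3, seed = 1L)
  expect_equal(nrow(rep$predictions), n)
  for (i in seq_len(n)) {
    expect_false(paste0("s", i) %in% rep$training_samples[[paste0("s", i)]])
    expect_length(rep$training_samples[[i]], n - 1)
  }
})

test_that("LOOCV recovers a perfectly linear single-locus signal", {
  ages <- c(0, 24, 51)
  X <- matrix(20 + 1.2 * ages, 3, 1, dimnames = list(paste0("s", 1:3), "L1"))
  rep <- loocv(X, ages, alpha = 0.5, grid = c(1e-6, 1e-4), folds = 2, seed = 1L)
  expect_lt(max(abs(rep$predictions$difference)), 0.5)
})

test_that("LOOCV predictions are invariant to sample storage order", {
  set.seed(16)
  n <- 8
  X <- matrix(rnorm(n * 3, 50, 5), n, 3,
              dimnames = list(paste0("s", 1:n), paste0("L", 1:3)))
  ages <- runif(n, 0, 51)
  r1 <- loocv(X, ages, grid = c(0.01, 0.1, 1), folds = 3, seed = 2L)
  perm <- c(5, 3, 8, 1, 2, 7, 6, 4)
  r2 <- loocv(X[perm, ], ages[perm], grid = c(0.01, 0.1, 1), folds = 3, seed = 2L)
  p1 <- setNames(r1$predictions$predicted, rownames(X))
  p2 <- setNames(r2$predictions$predicted, rownames(X)[perm])
  expect_equal(p1[names(p2)], p2, tolerance = 1e-9)
})

test_that("LOOCV with an intercept-only model equals the closed-form oracle", {
  # leave-one-out mean predictor: pred_i = (sum(y) - y_i) / (n - 1)
  set.seed(17)
  y <- runif(12, 0, 51)
  X <- matrix(50, 12, 2, dimnames = list(paste0("s", 1:12), c("L1", "L2")))
  X <- X + matrix(rnorm(24, 0, 1e-9), 12, 2)  # break constancy, no signal
  rep <- loocv(X, y, grid = c(1e5, 1e6), folds = 3, seed = 1L)
  oracle <- (sum(y) - y) / (length(y) - 1)
  expect_equal(rep$predictions$predicted, oracle, tolerance = 1e-4)
})

test_that("compare_models prefers sparse fits on sparse truth", {
  set.seed(18)
  n <- 60; p <- 50
  X <- matrix(rnorm(n * p, 50, 4), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  ages <- runif(n, 0, 51)
  for (j in 1:5) X[, j] <- 20 + (0.4 + 0.1 * j) * ages + rnorm(n, 0, 1.5)
  cmp <- compare_models(X, ages, seed = 4L)
  tab <- cmp$table
  expect_equal(tab$n_loci[tab$alpha == 0], p)  # ridge never zeroes out
  expect_lt(tab$mae[tab$alpha == 1], tab$mae[tab$alpha == 0])
  expect_lt(tab$mae[tab$alpha == 0.5], tab$mae[tab$alpha == 0])
  expect_true(cmp$chosen_alpha %in% c(0.5, 1))
})

test_that("pure-noise panels yield near-zero CV R-squared", {
  set.seed(19)
  X <- matrix(rnorm(50 * 30, 50, 5), 50, 30,
              dimnames = list(NULL, paste0("L", 1:30)))
  ages <- runif(50, 0, 51)
  cv <- tune(X, ages, alpha = 0.5, seed = 3L)
  best <- which(cv$cv_metrics$lambda == cv$lambda_best)
  expect_lt(cv$cv_metrics$r2_pooled[best], 0.2)
})

test_that("reduced_model selects top-R2 loci and matches OLS behaviour", {
  set.seed(20)
  n <- 50
  ages <- runif(n, 0, 51)
  X <- matrix(rnorm(n * 20, 50, 3), n, 20, dimnames = list(NULL, paste0("L", 1:20)))
  for (j in 1:6) X[, j] <- 20 + (0.3 + 0.1 * j) * ages + rnorm(n, 0, 1)
  model <- fit_final(X, ages, alpha = 0.5, seed = 7L)
  screen <- screen_all(X, ages)
  expect_error(reduced_model(X, ages, screen, model,
                             k = length(model$coefficients) + 1), "exceeds")
  red <- reduced_model(X, ages, screen, model, k = 3)
  expect_length(red$coefficients, 3)
  # k = 1 equals the best single locus's simple regression
  red1 <- reduced_model(X, ages, screen, model, k = 1)
  best_locus <- names(red1$coefficients)
  fit <- fit_locus(X[, best_locus], ages)
  # invert: regression of age on methylation, compare predictions
  lmfit <- lm(ages ~ X[, best_locus])
  expect_equal(as.numeric(predict_age(red1, X)), unname(fitted(lmfit)),
               tolerance = 1e-9)
  # full-k OLS refit cannot be worse than the penalized fit on training data
  redk <- reduced_model(X, ages, screen, model, k = length(model$coefficients))
  expect_lte(redk$metrics$rmse, model$metrics$rmse + 1e-9)
})

test_that("reduced model recovers an exactly-15-locus truth", {
  set.seed(21)
  n <- 80
  ages <- runif(n, 0, 51)
  p <- 40
  X <- matrix(rnorm(n * p, 50, 3), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  informative <- paste0("L", 1:15)
  for (j in 1:15) X[, j] <- 20 + (0.5 + 0.05 * j) * ages + rnorm(n, 0, 0.5)
  model <- fit_final(X, ages, alpha = 0.5, seed = 2L)
  screen <- screen_all(X, ages)
  red <- reduced_model(X, ages, screen, model, k = 15)
  expect_setequal(names(red$coefficients), informative)
})

test_that("sex_effects detects a constructed female shift and skips single-sex cohorts", {
  set.seed(22)
  n <- 40
  ages <- rep(25, n)
  sex <- rep(c("F", "M"), each = n / 2)
  p <- 12
  X <- matrix(rnorm(n * p, 50, 2), n, p, dimnames = list(NULL, paste0("L", 1:p)))
  X[sex == "F", ] <- X[sex == "F", ] + 5
  model <- structure(list(
    alpha = 0.5, lambda = 1, intercept = 25,
    coefficients = setNames(rep(0.5, p), paste0("L", 1:p)),
    center = setNames(rep(50, p), paste0("L", 1:p)),
    scale = setNames(rep(2, p), paste0("L", 1:p)),
    n_loci_selected = p, metrics = list(), version = "0"),
    class = "ClockModel")
  sheet <- data.frame(sample_id = paste0("s", 1:n), sex = sex, cohort = "m25")
  res <- sex_effects(X, sheet, model, cohorts = "m25")
  expect_equal(unname(res$sign_counts[["m25"]]["female_higher"]), p)
  expect_lt(res$anova$p, 0.01)
  sheet2 <- sheet; sheet2$sex <- "F"
  expect_warning(sex_effects(X, sheet2, model, cohorts = "m25"), "single sex")
})
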