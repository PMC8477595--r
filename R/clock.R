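#' Penalty grid for the elastic-net clock
#'
#' 100 log-uniformly spaced lambda values from 1e-3 to 1e3 inclusive, the
#' grid over which ridge (alpha = 0), elastic net (0.5) and lasso (1) clocks
#' are tuned by 10-fold cross-validation.
#'
#' @return numeric vector of length 100, increasing.
#' @export
make_lambda_grid <- function() 10^seq(-3, 3, length.out = 100)

# Standardize columns to zero mean / unit variance; constant columns get
# scale 1 so they stay finite (their coefficient is necessarily 0).
standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[is.na(scl) | scl == 0] <- 1   # single-row or constant columns
  list(center = ctr, scale = scl,
       X = sweep(sweep(X, 2, ctr), 2, scl, "/"))
}

standardize_apply <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

# Fit a glmnet path over the full (decreasing) lambda grid on
# pre-standardized predictors. glmnet needs >= 2 columns, so single-locus
# designs get a constant zero dummy whose coefficient is exactly 0; callers
# drop it via drop_pad().
PAD_COL <- "..pad.."

pad_single <- function(Xs) {
  if (ncol(Xs) > 1) return(Xs)
  cbind(Xs, matrix(0, nrow(Xs), 1, dimnames = list(NULL, PAD_COL)))
}

drop_pad <- function(beta) beta[setdiff(names(beta), PAD_COL)]

fit_glmnet_path <- function(Xs, y, alpha, grid, thresh = 1e-8) {
  glmnet::glmnet(pad_single(Xs), y, alpha = alpha,
                 lambda = sort(grid, decreasing = TRUE),
                 standardize = FALSE, thresh = thresh, maxit = 1e6)
}

# Elastic-net objective (1/2) * mean squared error + lambda * penalty, on
# standardized predictors; used by invariant tests.
enet_objective <- function(Xs, y, intercept, beta, lambda, alpha) {
  r <- y - (intercept + drop(Xs %*% beta))
  mean(r^2) / 2 + lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

#' Tune the penalty strength by k-fold cross-validation
#'
#' Predictors are standardized inside each training fold; the selected
#' lambda minimises the median across folds of the mean absolute error.
#' Fold assignment is deterministic given `seed`.
#'
#' @param matrix_obj `MethylationMatrix` or samples x loci numeric matrix.
#' @param ages response, months.
#' @param alpha elastic-net mixing parameter (0 ridge, 1 lasso).
#' @param grid lambda grid, default [make_lambda_grid()].
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param thresh glmnet coordinate-descent convergence threshold.
#' @return list with `lambda_best` and `cv_metrics` (per-lambda median/mean
#'   MAE, median/mean RMSE, pooled-prediction R-squared).
#' @export
tune <- function(matrix_obj, ages, alpha = 0.5, grid = make_lambda_grid(),
                 folds = 10, seed = 1L, thresh = 1e-8) {
  X <- meth_values(matrix_obj)
  n <- nrow(X)
  if (n < folds) stopf("need at least as many samples (%d) as folds (%d)", n, folds)
  if (var(ages) == 0) stopf("constant ages: nothing to tune")
  lam <- sort(grid, decreasing = TRUE)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  mae <- rmse <- matrix(NA_real_, folds, length(lam))
  pooled <- matrix(NA_real_, n, length(lam))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    std <- standardize_fit(X[tr, , drop = FALSE])
    fit <- fit_glmnet_path(std$X, ages[tr], alpha, lam, thresh)
    Xte <- pad_single(standardize_apply(X[!tr, , drop = FALSE],
                                        std$center, std$scale))
    pred <- predict(fit, Xte)                      # n_test x n_lambda
    # glmnet may truncate the path; align on returned lambdas
    j <- match(round(log(fit$lambda), 10), round(log(lam), 10))
    pm <- matrix(NA_real_, sum(!tr), length(lam))
    pm[, j[!is.na(j)]] <- pred[, !is.na(j), drop = FALSE]
    err <- pm - ages[!tr]
    mae[k, ] <- colMeans(abs(err))
    rmse[k, ] <- sqrt(colMeans(err^2))
    pooled[!tr, ] <- pm
  }
  med_mae <- apply(mae, 2, median)
  best <- which.min(med_mae)
  r2 <- apply(pooled, 2, function(p)
    if (all(is.na(p)) || sd(p, na.rm = TRUE) == 0) 0 else
      suppressWarnings(stats::cor(p, ages, use = "complete.obs")^2))
  list(lambda_best = lam[best],
       cv_metrics = data.frame(
         lambda = lam,
         mae_median = med_mae, mae_mean = colMeans(mae),
         rmse_median = apply(rmse, 2, median), rmse_mean = colMeans(rmse),
         r2_pooled = r2))
}

#' Fit the final penalized clock
#'
#' Standardizes all samples, tunes lambda if not supplied, and refits at
#' `lambda_best`. Coefficients are stored on the standardized-predictor
#' scale together with the standardization parameters, so a serialized
#' model predicts reproducibly on its own.
#'
#' @inheritParams tune
#' @param lambda fixed penalty; `NULL` tunes internally.
#' @return object of class `ClockModel`.
#' @export
fit_final <- function(matrix_obj, ages, alpha = 0.5, grid = make_lambda_grid(),
                      lambda = NULL, folds = 10, seed = 1L, thresh = 1e-8) {
  X <- meth_values(matrix_obj)
  if (nrow(X) == 0 || ncol(X) == 0) stopf("empty methylation matrix")
  cv <- NULL
  if (is.null(lambda)) {
    if (nrow(X) < 4) {
      # too few samples to cross-validate; use the weakest penalty
      lambda <- min(grid)
    } else {
      cv <- tune(matrix_obj, ages, alpha, grid, min(folds, floor(nrow(X) / 2)),
                 seed, thresh)
      lambda <- cv$lambda_best
    }
  }
  std <- standardize_fit(X)
  fit <- fit_glmnet_path(std$X, ages, alpha, grid, thresh)
  j <- which.min(abs(log(fit$lambda) - log(lambda)))
  beta <- drop_pad(fit$beta[, j])
  intercept <- fit$a0[j]
  keep <- if (alpha == 0) rep(TRUE, length(beta)) else beta != 0
  pred <- intercept + drop(std$X %*% beta)
  model <- structure(list(
    alpha = alpha,
    lambda = lambda,
    intercept = unname(intercept),
    coefficients = beta[keep],
    center = std$center[keep],
    scale = std$scale[keep],
    n_loci_selected = sum(beta != 0),
    metrics = list(
      mae = mean(abs(ages - pred)),
      rmse = sqrt(mean((ages - pred)^2)),
      r2_cor = if (sd(pred) == 0) 0 else stats::cor(pred, ages)^2,
      r2_sse = 1 - sum((ages - pred)^2) / sum((ages - mean(ages))^2)),
    cv_metrics = cv$cv_metrics,
    seed = seed,
    version = as.character(utils::packageVersion("rdnaclock"))),
    class = "ClockModel")
  model
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf(
    "ClockModel: alpha=%g lambda=%.4g, %d loci, training MAE %.3g months\n",
    x$alpha, x$lambda, x$n_loci_selected, x$metrics$mae))
  invisible(x)
}

#' Predict age from a fitted clock
#'
#' `age = intercept + sum coef_l * (x_l - center_l) / scale_l`. All model
#' loci must be present; there is no imputation. Negative predictions are
#' returned as-is with a `flagged_negative` attribute.
#'
#' @param model a `ClockModel`.
#' @param matrix_obj `MethylationMatrix` or numeric matrix containing every
#'   model locus as a named column.
#' @return predicted ages in months, named by sample.
#' @export
predict_age <- function(model, matrix_obj) {
  X <- meth_values(matrix_obj)
  loci <- names(model$coefficients)
  missing <- setdiff(loci, colnames(X))
  if (length(missing))
    stopf("matrix lacks %d model loci: %s", length(missing),
          paste(utils::head(missing, 5), collapse = ", "))
  Xs <- standardize_apply(X[, loci, drop = FALSE], model$center, model$scale)
  pred <- model$intercept + drop(Xs %*% model$coefficients)
  names(pred) <- rownames(X)
  structure(pred, flagged_negative = pred < 0)
}

#' Precision of an ageing model
#'
#' Sample standard deviation (n - 1 denominator) of the differences between
#' known and predicted ages. Deliberately bias-blind: a constant offset
#' yields 0.
#'
#' @param known,predicted equal-length age vectors, months.
#' @return SD of the differences, months.
#' @export
precision_sd <- function(known, predicted) {
  if (length(known) != length(predicted)) stopf("length mismatch")
  if (length(known) < 2) stopf("need at least 2 pairs")
  sd(known - predicted)
}

# Brown-Forsythe (median-centred Levene) test for equal variances between
# two groups; returns the p-value.
levene_p <- function(x, g) {
  g <- factor(g)
  dev <- abs(x - stats::ave(x, g, FUN = median))
  fit <- stats::aov(dev ~ g)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

# Build a precision report from held-out predictions.
precision_report <- function(known, predicted, cohorts, training_samples = NULL) {
  diff <- known - predicted
  per_cohort <- tapply(diff, cohorts, mean)
  aov_tab <- anova_diff <- NULL
  tukey <- NULL
  if (length(unique(cohorts)) > 1) {
    f <- factor(cohorts)
    fit <- aov(diff ~ f)
    s <- summary(fit)[[1]]
    anova_diff <- list(F = s[["F value"]][1],
                       df = c(s[["Df"]][1], s[["Df"]][2]),
                       p = s[["Pr(>F)"]][1])
    tukey <- as.data.frame(TukeyHSD(fit)$f)
    tukey$comparison <- rownames(tukey)
    rownames(tukey) <- NULL
  }
  structure(list(
    predictions = data.frame(known = known, predicted = predicted,
                             difference = diff, cohort = cohorts),
    precision_sd = precision_sd(known, predicted),
    per_cohort_mean_difference = per_cohort,
    anova = anova_diff,
    tukey = tukey,
    training_samples = training_samples),
    class = "PrecisionReport")
}

#' @export
print.PrecisionReport <- function(x, ...) {
  cat(sprintf("PrecisionReport: n=%d, precision SD %.3f months\n",
              nrow(x$predictions), x$precision_sd))
  invisible(x)
}

#' Leave-one-out cross-validation of the full clock pipeline
#'
#' For each sample the complete tuning + fitting pipeline runs on the other
#' n - 1 samples (sorted by sample id, so held-out predictions do not depend
#' on storage order) and predicts the held-out sample. Precision is the SD
#' of (known - predicted); differences are compared across cohorts by ANOVA
#' with Tukey HSD.
#'
#' @inheritParams tune
#' @param cohorts cohort labels per sample (defaults to one cohort).
#' @return a `PrecisionReport`; `$training_samples` records each held-out
#'   model's training ids for protocol audits.
#' @export
loocv <- function(matrix_obj, ages, alpha = 0.5, grid = make_lambda_grid(),
                  folds = 10, seed = 1L, cohorts = NULL, thresh = 1e-8) {
  X <- meth_values(matrix_obj)
  n <- nrow(X)
  if (n < 3) stopf("need at least 3 samples for LOOCV")
  ids <- rownames(X) %||% sprintf("S%04d", seq_len(n))
  rownames(X) <- ids
  if (is.null(cohorts)) cohorts <- rep("all", n)
  predicted <- numeric(n)
  training <- vector("list", n)
  for (i in seq_len(n)) {
    tr_ids <- sort(ids[-i])
    Xtr <- X[tr_ids, , drop = FALSE]
    ytr <- ages[match(tr_ids, ids)]
    model <- fit_final(Xtr, ytr, alpha = alpha, grid = grid,
                       folds = min(folds, length(tr_ids)),
                       seed = child_seed(seed, ids[i]), thresh = thresh)
    predicted[i] <- predict_age(model, X[i, , drop = FALSE])
    training[[i]] <- tr_ids
  }
  names(training) <- ids
  rep <- precision_report(ages, predicted, cohorts, training)
  rep$r2 <- if (sd(predicted) == 0) 0 else stats::cor(predicted, ages)^2
  rep
}

# LOOCV for a fixed-locus ordinary least squares model (used by the
# reduced-locus clock, whose locus set is selected once, upstream).
loocv_ols <- function(matrix_obj, ages, loci, cohorts = NULL) {
  X <- meth_values(matrix_obj)[, loci, drop = FALSE]
  n <- nrow(X)
  if (is.null(cohorts)) cohorts <- rep("all", n)
  predicted <- vapply(seq_len(n), function(i) {
    fit <- lm.fit(cbind(1, X[-i, , drop = FALSE]), ages[-i])
    b <- fit$coefficients
    b[is.na(b)] <- 0
    drop(c(1, X[i, ]) %*% b)
  }, numeric(1))
  rep <- precision_report(ages, predicted, cohorts)
  rep$r2 <- if (sd(predicted) == 0) 0 else stats::cor(predicted, ages)^2
  rep
}

#' Compare ridge, elastic net and lasso clocks
#'
#' Tunes each alpha over the same grid and folds and tabulates median CV
#' MAE, RMSE, pooled R-squared and the number of loci in the refitted final
#' model. The chosen alpha has the lowest median MAE; alphas within
#' `tol` relative MAE of the best are tie-broken by fewer loci.
#'
#' @inheritParams tune
#' @param alphas mixing parameters to compare.
#' @param tol relative MAE tolerance treated as a tie.
#' @return list with `table` (one row per alpha) and `chosen_alpha`.
#' @export
compare_models <- function(matrix_obj, ages, grid = make_lambda_grid(),
                           alphas = c(0, 0.5, 1), folds = 10, seed = 1L,
                           tol = 0.01) {
  rows <- lapply(alphas, function(a) {
    cv <- tune(matrix_obj, ages, a, grid, folds, seed)
    i <- which.min(cv$cv_metrics$mae_median)
    model <- fit_final(matrix_obj, ages, alpha = a, grid = grid,
                       lambda = cv$lambda_best, seed = seed)
    data.frame(alpha = a, lambda = cv$lambda_best,
               mae = cv$cv_metrics$mae_median[i],
               rmse = cv$cv_metrics$rmse_median[i],
               r2 = cv$cv_metrics$r2_pooled[i],
               n_loci = model$n_loci_selected)
  })
  tab <- do.call(rbind, rows)
  best_mae <- min(tab$mae)
  tied <- which(tab$mae <= best_mae * (1 + tol))
  chosen <- tied[which.min(tab$n_loci[tied])]
  list(table = tab, chosen_alpha = tab$alpha[chosen])
}

#' Reduced-locus ordinary least squares clock
#'
#' Takes the `k` clock loci with highest single-locus R-squared (ties broken
#' by lower genomic position), refits an unpenalized multiple regression,
#' and returns it as a `ClockModel` (standardized-scale coefficients, so
#' [predict_age()] and serialization work unchanged).
#'
#' @param matrix_obj training matrix.
#' @param ages training ages, months.
#' @param screen_result a `ScreenResult` covering the model loci.
#' @param model the penalized `ClockModel` whose loci are ranked.
#' @param k number of loci to keep.
#' @return a `ClockModel` with `alpha = NA` (unpenalized).
#' @export
reduced_model <- function(matrix_obj, ages, screen_result, model, k = 15) {
  sel <- names(model$coefficients)
  if (k > length(sel))
    stopf("k = %d exceeds the %d selected loci", k, length(sel))
  tab <- screen_result$table
  idx <- match(sel, tab$locus_id)
  if (any(is.na(idx))) stopf("screen results do not cover all model loci")
  ord <- order(-tab$r_squared[idx], tab$position[idx])
  top <- sel[ord][seq_len(k)]
  X <- meth_values(matrix_obj)[, top, drop = FALSE]
  fit <- lm(ages ~ X)
  beta_raw <- coef(fit)[-1]
  beta_raw[is.na(beta_raw)] <- 0
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  beta_std <- beta_raw * scl
  intercept <- unname(coef(fit)[1] + sum(beta_raw * ctr))
  pred <- intercept + drop(standardize_apply(X, ctr, scl) %*% beta_std)
  structure(list(
    alpha = NA_real_, lambda = 0,
    intercept = intercept,
    coefficients = setNames(beta_std, top),
    center = setNames(ctr, top), scale = setNames(scl, top),
    n_loci_selected = k,
    metrics = list(
      mae = mean(abs(ages - pred)),
      rmse = sqrt(mean((ages - pred)^2)),
      r2_cor = if (sd(pred) == 0) 0 else stats::cor(pred, ages)^2,
      r2_sse = 1 - sum((ages - pred)^2) / sum((ages - mean(ages))^2)),
    cv_metrics = NULL, seed = NA_integer_,
    version = as.character(utils::packageVersion("rdnaclock"))),
    class = "ClockModel")
}

#' Sex-effect diagnostics on clock loci and predictions
#'
#' Per model locus and cohort: a two-sided two-sample t test of percent
#' methylation between females and males (pooled variance unless a
#' Brown-Forsythe test rejects equal variances, then Welch), with raw and
#' Holm-adjusted p-values and the sign of (female - male). Also counts how
#' many loci are female-higher per cohort and tests sex on predicted age by
#' a type-II ANOVA controlling for cohort.
#'
#' @param matrix_obj methylation matrix covering the model loci.
#' @param samplesheet data frame with `sample_id`, `sex`, `cohort`.
#' @param model a `ClockModel`.
#' @param cohorts cohort labels to analyse (others ignored).
#' @return list with `per_locus` (one row per cohort x locus),
#'   `sign_counts` (per cohort: loci female-higher / total), and `anova`
#'   (F, df, p for sex on predicted age controlling cohort).
#' @export
sex_effects <- function(matrix_obj, samplesheet, model, cohorts) {
  X <- meth_values(matrix_obj)
  loci <- names(model$coefficients)
  rows <- list()
  sign_counts <- list()
  used_cohorts <- character(0)
  for (co in cohorts) {
    in_co <- samplesheet$cohort == co
    sex <- samplesheet$sex[in_co]
    if (length(unique(sex[!is.na(sex)])) < 2) {
      warnf("cohort %s has a single sex; skipped", co)
      next
    }
    used_cohorts <- c(used_cohorts, co)
    Xc <- X[in_co, loci, drop = FALSE]
    res <- lapply(loci, function(l) {
      xf <- Xc[sex == "F", l]; xm <- Xc[sex == "M", l]
      lev_p <- tryCatch(levene_p(c(xf, xm), rep(c("F", "M"), c(length(xf), length(xm)))),
                        error = function(e) NA_real_)
      equal_var <- is.na(lev_p) || lev_p >= 0.05
      tt <- tryCatch(t.test(xf, xm, var.equal = equal_var),
                     error = function(e) list(p.value = NA_real_))
      data.frame(cohort = co, locus_id = l,
                 diff_f_minus_m = mean(xf) - mean(xm),
                 p_raw = tt$p.value, equal_var = equal_var,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    ok <- !is.na(res$p_raw)
    res$p_holm <- NA_real_
    res$p_holm[ok] <- holm_adjust(res$p_raw[ok])
    rows[[co]] <- res
    sign_counts[[co]] <- c(female_higher = sum(res$diff_f_minus_m > 0),
                           total = nrow(res))
  }
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL
  anova_out <- NULL
  if (length(used_cohorts) >= 1) {
    in_any <- samplesheet$cohort %in% used_cohorts & !is.na(samplesheet$sex)
    pred <- predict_age(model, X[in_any, , drop = FALSE])
    co_f <- factor(samplesheet$cohort[in_any])
    sex_f <- factor(samplesheet$sex[in_any])
    reduced <- if (nlevels(co_f) > 1) lm(pred ~ co_f) else lm(pred ~ 1)
    full <- if (nlevels(co_f) > 1) lm(pred ~ co_f + sex_f) else lm(pred ~ sex_f)
    an <- anova(reduced, full)
    anova_out <- list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                      p = an$`Pr(>F)`[2])
  }
  list(per_locus = per_locus, sign_counts = sign_counts, anova = anova_out)
}

#' Serialize a clock model to JSON
#' @param model a `ClockModel`.
#' @param path output path.
#' @export
clock_write_json <- function(model, path) {
  obj <- unclass(model)
  obj$cv_metrics <- NULL
  # named vectors must serialize as JSON objects to keep locus names
  for (f in c("coefficients", "center", "scale"))
    obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a clock model written by [clock_write_json()]
#' @param path file path.
#' @return a `ClockModel`.
#' @export
clock_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "center", "scale")) {
    v <- unlist(obj[[f]])
    obj[[f]] <- if (is.null(v)) setNames(numeric(0), character(0)) else v
  }
  obj$cv_metrics <- NULL
  structure(obj, class = "ClockModel")
}
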