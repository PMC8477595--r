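#' Simple linear regression of percent methylation on age at one locus
#'
#' Ordinary least squares of methylation (percent) on age (months), with the
#' two-sided slope p-value from the t distribution on n - 2 df.
#'
#' @param meth percent methylation vector.
#' @param ages ages in months, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `p_raw`, `direction`
#'   (`hyper`/`hypo`/`flat`) and `n`.
#' @export
fit_locus <- function(meth, ages) {
  ok <- !is.na(meth) & !is.na(ages)
  meth <- meth[ok]; ages <- ages[ok]
  n <- length(meth)
  if (n < 3) stopf("need at least 3 samples to fit a locus")
  if (var(ages) == 0) stopf("degenerate design: all ages equal")
  sxx <- sum((ages - mean(ages))^2)
  sxy <- sum((ages - mean(ages)) * (meth - mean(meth)))
  slope <- sxy / sxx
  intercept <- mean(meth) - slope * mean(ages)
  fitted <- intercept + slope * ages
  sse <- sum((meth - fitted)^2)
  sst <- sum((meth - mean(meth))^2)
  if (sst == 0) {            # constant methylation: flat locus
    slope <- 0; r2 <- 0; p <- 1
  } else {
    r2 <- 1 - sse / sst
    se <- sqrt(sse / (n - 2) / sxx)
    p <- if (se == 0) 0 else 2 * pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r_squared = r2, p_raw = p,
       direction = if (slope > 0) "hyper" else if (slope < 0) "hypo" else "flat",
       n = n)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sort p ascending, multiply the i-th smallest by (m - i + 1), enforce a
#' running maximum, cap at 1, and return in the original order.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  ord <- order(p_values)
  adj <- pmin(1, cummax(p_values[ord] * (m - seq_len(m) + 1)))
  adj[order(ord)]
}

#' Saturation age of a locus's linear trajectory
#'
#' The extrapolated age (months from hatching) at which the fitted line
#' reaches 100\% (hypermethylating) or 0\% (hypomethylating). Flat loci
#' never saturate (+Inf); an intercept already outside \[0, 100\] returns 0.
#'
#' @param result a fit from [fit_locus()] (or any list with `slope`,
#'   `intercept`).
#' @return months to saturation.
#' @export
saturation_age <- function(result) {
  a <- result$intercept; b <- result$slope
  if (a < 0 || a > 100) return(0)
  if (b > 0) (100 - a) / b else if (b < 0) -a / b else Inf
}

#' Screen every locus for a methylation--age relationship
#'
#' Vectorised per-locus OLS across the matrix, Holm correction over all
#' loci, saturation-age extrapolation, and a summary reporting saturation
#' statistics both including and excluding the single most extreme
#' (largest finite) saturation age.
#'
#' @param matrix_obj a `MethylationMatrix` or samples x loci numeric matrix.
#' @param ages ages in months, one per sample (NA rows are dropped).
#' @param alpha significance level applied to Holm-adjusted p-values.
#' @return list of class `ScreenResult`: `table` (one row per locus, ordered
#'   by region/position, with slope, intercept, r_squared, p_raw,
#'   p_adjusted, direction, saturation_age), `n_significant`, `alpha` and
#'   `saturation_summary`.
#' @export
screen_all <- function(matrix_obj, ages, alpha = 0.05) {
  X <- meth_values(matrix_obj)
  ok <- !is.na(ages)
  X <- X[ok, , drop = FALSE]; ages <- ages[ok]
  n <- nrow(X)
  if (n < 3) stopf("need at least 3 aged samples")
  if (var(ages) == 0) stopf("degenerate design: all ages equal")
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  ybar <- colMeans(X)
  sxy <- drop(crossprod(xc, X))
  slope <- sxy / sxx
  intercept <- ybar - slope * mean(ages)
  sst <- colSums(X^2) - n * ybar^2
  sse <- pmax(0, sst - slope^2 * sxx)
  r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
  slope[sst == 0] <- 0
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- ifelse(sst == 0, 1, 2 * pt(-abs(tstat), df = n - 2))
  p_adj <- holm_adjust(p)
  loci <- if (inherits(matrix_obj, "MethylationMatrix")) matrix_obj$loci else
    data.frame(locus_id = colnames(X) %||% paste0("L", seq_len(ncol(X))),
               region = NA_character_, position = seq_len(ncol(X)))
  tab <- data.frame(
    locus_id = loci$locus_id, region = loci$region, position = loci$position,
    slope = slope, intercept = intercept, r_squared = r2,
    p_raw = p, p_adjusted = p_adj,
    direction = ifelse(slope > 0, "hyper", ifelse(slope < 0, "hypo", "flat")),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$saturation_age <- vapply(seq_len(nrow(tab)), function(i)
    saturation_age(list(slope = tab$slope[i], intercept = tab$intercept[i])),
    numeric(1))
  ord <- order(tab$region, tab$position)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  sig <- tab$p_adjusted < alpha
  sat <- tab$saturation_age[sig & is.finite(tab$saturation_age)]
  summarise_sat <- function(v) if (length(v) == 0)
    c(mean = NA_real_, min = NA_real_, max = NA_real_) else
    c(mean = mean(v), min = min(v), max = max(v))
  sat_excl <- if (length(sat) > 1) sat[-which.max(sat)] else sat
  structure(list(
    table = tab,
    n_significant = sum(sig),
    alpha = alpha,
    saturation_summary = list(
      including_extreme = summarise_sat(sat),
      excluding_extreme = summarise_sat(sat_excl))),
    class = "ScreenResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult: %d loci, %d significant (Holm p < %g)\n",
              nrow(x$table), x$n_significant, x$alpha))
  invisible(x)
}

#' Write screening results as CSV
#'
#' Schema: `Gene, Position, coefficient, R2, Adjusted_p`, plus raw p,
#' direction and saturation age.
#'
#' @param screen a `ScreenResult`.
#' @param path output path.
#' @export
write_screen_csv <- function(screen, path) {
  tab <- screen$table
  out <- data.frame(Gene = tab$region, Position = tab$position,
                    coefficient = tab$slope, R2 = tab$r_squared,
                    Adjusted_p = tab$p_adjusted, Raw_p = tab$p_raw,
                    Direction = tab$direction,
                    Saturation_age_months = tab$saturation_age)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
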