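#' Evaluate a von Bertalanffy growth curve
#'
#' Standard form: `L(t) = Linf * (1 - exp(-K (t - t0)))`. Francis form
#' re-expresses the same curve by its mean lengths `L1 < L2 < L3` at
#' reference ages `tau1 < tau2 = (tau1 + tau3)/2 < tau3`:
#' `L(t) = L1 + (L3 - L1) * (1 - r^(2 (t - tau1)/(tau3 - tau1))) / (1 - r^2)`
#' with `r = (L3 - L2) / (L2 - L1)`; `r = 1` is handled by its linear limit.
#'
#' @param params for `standard`: list/vector with `Linf`, `K`, `t0`; for
#'   `francis`: `L1`, `L2`, `L3`, `tau1`, `tau3`.
#' @param age months (vectorised).
#' @param parameterisation `"standard"` or `"francis"`.
#' @return predicted carapace length, mm.
#' @export
vbgm_predict <- function(params, age, parameterisation = c("standard", "francis")) {
  parameterisation <- match.arg(parameterisation)
  p <- as.list(params)
  if (parameterisation == "standard") {
    p$Linf * (1 - exp(-p$K * (age - p$t0)))
  } else {
    if (!(p$L1 < p$L2 && p$L2 < p$L3))
      stopf("Francis parameters require L1 < L2 < L3")
    r <- (p$L3 - p$L2) / (p$L2 - p$L1)
    u <- (age - p$tau1) / (p$tau3 - p$tau1)
    if (abs(r - 1) < 1e-9) {
      # r -> 1 is the K -> 0 linear-growth limit
      p$L1 + (p$L3 - p$L1) * u
    } else {
      p$L1 + (p$L3 - p$L1) * (1 - r^(2 * u)) / (1 - r^2)
    }
  }
}

# Ford-Walford style starting values for the standard parameterisation.
vbgm_start <- function(ages, lengths) {
  linf0 <- 1.1 * max(lengths)
  # log-linearise: log(1 - L/Linf0) = K*t0 - K*t
  y <- 1 - lengths / linf0
  ok <- y > 1e-6
  k0 <- 0.1
  t00 <- 0
  if (sum(ok) >= 2 && var(ages[ok]) > 0) {
    fit <- lm(log(y[ok]) ~ ages[ok])
    if (is.finite(coef(fit)[2]) && coef(fit)[2] < 0) {
      k0 <- -unname(coef(fit)[2])
      t00 <- unname(coef(fit)[1]) / k0
    }
  }
  c(Linf = linf0, K = max(k0, 1e-4), t0 = t00)
}

#' Fit a von Bertalanffy growth model
#'
#' Nonlinear least squares on length residuals via quasi-Newton
#' minimisation (robust to zero-residual data, unlike Gauss-Newton
#' criteria). Standard fits start from a Ford-Walford log-linearisation;
#' Francis fits start from empirical mean lengths near the reference ages.
#' Non-convergence and degenerate inputs are flagged, never silent.
#'
#' @param ages,lengths observed ages (months) and carapace lengths (mm);
#'   >= 4 pairs spanning >= 3 distinct ages.
#' @param parameterisation `"standard"` or `"francis"`.
#' @param tau reference ages `(tau1, tau3)` for the Francis form; default
#'   range of the observed ages.
#' @param start optional named start values.
#' @return object of class `VBGMFit`: `params`, `parameterisation`, `sse`,
#'   `residual_sd`, `converged`, `n`.
#' @export
fit_vbgm <- function(ages, lengths, parameterisation = c("standard", "francis"),
                     tau = NULL, start = NULL) {
  parameterisation <- match.arg(parameterisation)
  ok <- !is.na(ages) & !is.na(lengths)
  ages <- ages[ok]; lengths <- lengths[ok]
  n <- length(ages)
  degenerate <- n < 4 || length(unique(ages)) < 3 || var(lengths) == 0
  if (n < 4) stopf("need at least 4 (age, length) pairs")
  if (is.null(tau)) tau <- range(ages)
  if (parameterisation == "standard") {
    par0 <- if (is.null(start)) vbgm_start(ages, lengths) else
      unlist(start)[c("Linf", "K", "t0")]
    obj <- function(p) {
      if (p[1] <= 0 || p[2] <= 0) return(1e12)
      sum((lengths - p[1] * (1 - exp(-p[2] * (ages - p[3]))))^2)
    }
  } else {
    par0 <- if (is.null(start)) {
      taus <- c(tau[1], mean(tau), tau[2])
      l0 <- vapply(taus, function(tt)
        mean(lengths[abs(ages - tt) <= diff(tau) / 4 + 1e-9]), numeric(1))
      if (any(!is.finite(l0)) || any(diff(l0) <= 0))
        l0 <- quantile(lengths, c(0.1, 0.5, 0.9), names = FALSE)
      if (any(diff(l0) <= 0)) l0 <- sort(l0) + c(0, 1e-3, 2e-3)
      c(L1 = l0[1], L2 = l0[2], L3 = l0[3])
    } else unlist(start)[c("L1", "L2", "L3")]
    obj <- function(p) {
      if (!(p[1] < p[2] && p[2] < p[3])) return(1e12)
      pr <- vbgm_predict(list(L1 = p[1], L2 = p[2], L3 = p[3],
                              tau1 = tau[1], tau3 = tau[2]), ages, "francis")
      sum((lengths - pr)^2)
    }
  }
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  # Nelder-Mead polish guards against BFGS stopping early; convergence is
  # accepted if either optimizer reports clean termination
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-15))
  conv_ok <- opt$convergence == 0 || opt2$convergence == 0
  if (opt2$value < opt$value) opt <- opt2
  opt$convergence <- if (conv_ok) 0 else opt$convergence
  params <- as.list(opt$par)
  if (parameterisation == "francis") {
    params$tau1 <- tau[1]; params$tau3 <- tau[2]
  }
  converged <- !degenerate && opt$convergence == 0 && opt$value < 1e11
  structure(list(
    parameterisation = parameterisation,
    params = params,
    tau = tau,
    sse = opt$value,
    residual_sd = sqrt(opt$value / max(1, n - 3)),
    converged = converged,
    degenerate = degenerate,
    n = n), class = "VBGMFit")
}

#' @export
print.VBGMFit <- function(x, ...) {
  cat(sprintf("VBGMFit (%s): %s; SSE=%.4g; converged=%s\n",
              x$parameterisation,
              paste(names(x$params), signif(unlist(x$params), 5),
                    sep = "=", collapse = " "),
              x$sse, x$converged))
  invisible(x)
}

#' Convert a growth fit between parameterisations
#'
#' Exact algebra: with `h = (tau3 - tau1)/2`, the Francis ratio is
#' `r = exp(-K h)`, so `K = -2 log(r) / (tau3 - tau1)`,
#' `Linf = L1 + (L3 - L1)/(1 - r^2)` and
#' `t0 = tau1 + log(1 - L1/Linf)/K`. The `r -> 1` (K -> 0) degenerate case
#' is rejected for standard targets.
#'
#' @param fit a `VBGMFit` (or a list with `parameterisation`, `params`).
#' @param target `"standard"` or `"francis"`.
#' @param tau1,tau3 reference ages when converting to Francis.
#' @return a `VBGMFit` in the target parameterisation (same curve, SSE and
#'   flags carried over).
#' @export
convert_parameterisation <- function(fit, target = c("standard", "francis"),
                                     tau1 = NULL, tau3 = NULL) {
  target <- match.arg(target)
  p <- fit$params
  if (fit$parameterisation == target) return(fit)
  if (target == "francis") {
    if (is.null(tau1) || is.null(tau3)) {
      tau1 <- fit$tau[1]; tau3 <- fit$tau[2]
    }
    taus <- c(tau1, (tau1 + tau3) / 2, tau3)
    L <- vbgm_predict(p, taus, "standard")
    if (!(L[1] < L[2] && L[2] < L[3]))
      stopf("curve is not increasing over (tau1, tau3); cannot convert")
    out <- list(L1 = L[1], L2 = L[2], L3 = L[3], tau1 = tau1, tau3 = tau3)
    new_tau <- c(tau1, tau3)
  } else {
    if (p$L1 >= p$L3) stopf("invalid Francis parameters: L1 >= L3")
    r <- (p$L3 - p$L2) / (p$L2 - p$L1)
    if (r <= 0) stopf("invalid Francis parameters: non-positive ratio")
    if (abs(r - 1) < 1e-12)
      stopf("r = 1 describes linear growth (K -> 0); no finite standard form")
    K <- -2 * log(r) / (p$tau3 - p$tau1)
    Linf <- p$L1 + (p$L3 - p$L1) / (1 - r^2)
    t0 <- p$tau1 + log(1 - p$L1 / Linf) / K
    out <- list(Linf = Linf, K = K, t0 = t0)
    new_tau <- c(p$tau1, p$tau3)
  }
  structure(list(parameterisation = target, params = out, tau = new_tau,
                 sse = fit$sse, residual_sd = fit$residual_sd,
                 converged = fit$converged,
                 degenerate = isTRUE(fit$degenerate), n = fit$n),
            class = "VBGMFit")
}

#' Bootstrap confidence intervals for growth parameters
#'
#' Nonparametric case resampling of (age, length) pairs; each replicate is
#' refit and percentile intervals are taken over converged replicates.
#' Replicates that fail to converge are dropped and counted; more than 20\%
#' failures escalates to a warning.
#'
#' @inheritParams fit_vbgm
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `fit` (full-data `VBGMFit`), `ci` (per-parameter lower/
#'   upper), `n_failed`, `n_boot`, `level`.
#' @export
bootstrap_ci <- function(ages, lengths, parameterisation = "standard",
                         tau = NULL, n_boot = 1000, level = 0.95, seed = 1L) {
  fit <- fit_vbgm(ages, lengths, parameterisation, tau = tau)
  if (!fit$converged) stopf("full-data fit did not converge; no bootstrap")
  par_names <- setdiff(names(fit$params), c("tau1", "tau3"))
  n <- length(ages)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(
        fit_vbgm(ages[idx], lengths[idx], parameterisation, tau = fit$tau,
                 start = fit$params[par_names]),
        error = function(e) NULL)
      if (is.null(bf) || !bf$converged) return(NULL)
      unlist(bf$params[par_names])
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    warnf("%d of %d bootstrap replicates failed to converge", n_failed, n_boot)
  mat <- do.call(rbind, draws[ok])
  a <- (1 - level) / 2
  ci <- t(apply(mat, 2, quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(fit = fit, ci = as.data.frame(ci), n_failed = n_failed,
       n_boot = n_boot, level = level)
}
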