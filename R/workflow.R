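#' Build and validate a pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param counts_dir directory of per-sample coverage files; `NULL` runs the
#'   synthetic generator instead.
#' @param samples_csv sample sheet path (required with `counts_dir`).
#' @param sim a [sim_config()] used when `counts_dir` is `NULL`.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "quantify", "screen", "train", "loocv", "predict",
#'   "growth", "report")` in that order.
#' @param min_reads QC coverage threshold.
#' @param alpha elastic-net mixing parameter for the final clock.
#' @param k_reduced loci in the reduced model; 0 disables it.
#' @param n_boot growth bootstrap replicates; 0 disables the bootstrap.
#' @param seed global seed fanned out to each stage via a deterministic
#'   child-seed scheme.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       counts_dir = NULL, samples_csv = NULL,
                       sim = sim_config(),
                       stages = c("simulate", "quantify", "screen", "train",
                                  "loocv", "predict", "growth", "report"),
                       min_reads = 10, alpha = 0.5, k_reduced = 0,
                       n_boot = 200, seed = 1L) {
  all_stages <- c("simulate", "quantify", "screen", "train", "loocv",
                  "predict", "growth", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  if (!is.null(counts_dir)) {
    if (!dir.exists(counts_dir)) stopf("counts_dir does not exist: %s", counts_dir)
    if (is.null(samples_csv) || !file.exists(samples_csv))
      stopf("samples_csv must exist when counts_dir is given")
    stages <- setdiff(stages, "simulate")
  }
  if ("train" %in% stages && k_reduced > 0 && !("screen" %in% stages))
    stopf("the reduced model requires the screen stage")
  if (any(c("train", "loocv", "predict") %in% stages) &&
      !("quantify" %in% stages) && is.null(counts_dir))
    stopf("model stages require quantify (or an external counts_dir)")
  structure(list(out_dir = out_dir, counts_dir = counts_dir,
                 samples_csv = samples_csv, sim = sim, stages = stages,
                 min_reads = min_reads, alpha = alpha, k_reduced = k_reduced,
                 n_boot = n_boot, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate, quantify (QC + percent
#' methylation), screen, train (+ optional reduced model), loocv, predict
#' (wild samples), growth, report -- writing every artifact plus a manifest
#' of parameters, seeds and file hashes. Re-running with an identical
#' config and seed reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return list of in-memory artifacts (invisibly also written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if ("simulate" %in% config$stages) {
    art$sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- child_seed(config$seed, "simulate")
      simulate_dataset(cfg, out_dir = file.path(out, "data"))
    })
    counts_dir <- file.path(out, "data", "coverage")
    sheet <- art$sim$samplesheet
  } else {
    counts_dir <- config$counts_dir
    sheet <- read.csv(config$samples_csv, stringsAsFactors = FALSE)
  }
  if ("quantify" %in% config$stages) {
    art$qc <- stage("quantify", {
      counts <- read_coverage_dir(counts_dir, sheet)
      qc <- apply_qc(counts, min_reads = config$min_reads)
      write_methylation_matrix(qc$matrix, file.path(out, "matrix.csv"))
      jsonlite::write_json(
        list(n_loci_input = qc$report$n_loci_input,
             n_loci_retained = qc$report$n_loci_retained,
             min_reads = qc$report$min_reads,
             dropped = qc$report$dropped),
        file.path(out, "qc.json"), auto_unbox = TRUE, digits = NA)
      qc
    })
  }
  known <- !is.na(sheet$age_months)
  mat <- art$qc$matrix
  known_mat <- structure(list(values = mat$values[known, , drop = FALSE],
                              loci = mat$loci, samples = mat$samples[known]),
                         class = "MethylationMatrix")
  ages <- sheet$age_months[known]
  if ("screen" %in% config$stages) {
    art$screen <- stage("screen", {
      sc <- screen_all(known_mat, ages)
      write_screen_csv(sc, file.path(out, "screen.csv"))
      sc
    })
  }
  if ("train" %in% config$stages) {
    art$model <- stage("train", {
      m <- fit_final(known_mat, ages, alpha = config$alpha,
                     seed = child_seed(config$seed, "train"))
      clock_write_json(m, file.path(out, "model.json"))
      m
    })
    if (config$k_reduced > 0) {
      art$reduced <- stage("train", {
        r <- reduced_model(known_mat, ages, art$screen, art$model,
                           k = config$k_reduced)
        clock_write_json(r, file.path(out, "model_reduced.json"))
        r
      })
    }
  }
  if ("loocv" %in% config$stages) {
    art$loocv <- stage("loocv", {
      lv <- loocv(known_mat, ages, alpha = config$alpha,
                  seed = child_seed(config$seed, "loocv"),
                  cohorts = sheet$cohort[known])
      write.csv(lv$predictions, file.path(out, "loocv_predictions.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(precision_sd = lv$precision_sd, r2 = lv$r2,
             anova = lv$anova,
             per_cohort_mean_difference =
               as.list(lv$per_cohort_mean_difference)),
        file.path(out, "precision.json"), auto_unbox = TRUE, digits = NA)
      lv
    })
  }
  if ("predict" %in% config$stages && any(!known)) {
    art$wild <- stage("predict", {
      wm <- mat$values[!known, , drop = FALSE]
      pred <- predict_age(art$model, wm)
      df <- data.frame(sample_id = sheet$sample_id[!known],
                       predicted_age_months = as.numeric(pred))
      write.csv(df, file.path(out, "wild_predictions.csv"), row.names = FALSE)
      df
    })
  }
  if ("growth" %in% config$stages) {
    art$growth <- stage("growth", {
      sized <- known & !is.na(sheet$carapace_length_mm) & sheet$age_months >= 7
      g <- fit_vbgm(sheet$age_months[sized], sheet$carapace_length_mm[sized],
                    "standard")
      res <- list(params = g$params, converged = g$converged,
                  residual_sd = g$residual_sd, n = g$n)
      if (config$n_boot > 0 && g$converged) {
        bs <- bootstrap_ci(sheet$age_months[sized],
                           sheet$carapace_length_mm[sized], "standard",
                           n_boot = config$n_boot,
                           seed = child_seed(config$seed, "growth"))
        res$ci <- bs$ci
        res$n_failed <- bs$n_failed
      }
      jsonlite::write_json(res, file.path(out, "growth.json"),
                           auto_unbox = TRUE, digits = NA)
      g
    })
  }
  if ("report" %in% config$stages) {
    stage("report", make_report(art, sheet, out))
  }
  manifest <- list(
    config = list(stages = config$stages, min_reads = config$min_reads,
                  alpha = config$alpha, k_reduced = config$k_reduced,
                  n_boot = config$n_boot, seed = config$seed),
    version = as.character(utils::packageVersion("rdnaclock")),
    files = as.list(tools::md5sum(list.files(out, recursive = TRUE,
                                             full.names = TRUE,
                                             pattern = "\\.(csv|json|md|cov)$"))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(art)
}

#' Render a human-readable run report
#'
#' Deterministic markdown summary of whatever artifacts exist: QC counts,
#' screening summary, model comparison numbers, LOOCV precision and wild
#' age predictions. Missing artifacts cause their section to be omitted
#' with a notice.
#'
#' @param art artifact list from [run_pipeline()].
#' @param sheet the sample sheet used.
#' @param out_dir directory to write `report.md` into.
#' @return the report path, invisibly.
#' @export
make_report <- function(art, sheet, out_dir) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  lines <- c("# rDNA methylation clock run report", "")
  known <- !is.na(sheet$age_months)
  demo <- as.data.frame(table(cohort = sheet$cohort), stringsAsFactors = FALSE)
  lines <- c(lines, "## Sample demography", "",
             "| cohort | n |", "|---|---|",
             sprintf("| %s | %d |", demo$cohort, demo$Freq), "")
  if (!is.null(art$qc)) {
    r <- art$qc$report
    lines <- c(lines, "## Locus QC", "",
               sprintf("- loci sequenced: %d", r$n_loci_input),
               sprintf("- loci retained (>= %d reads, no missing): %d",
                       r$min_reads, r$n_loci_retained), "")
  } else lines <- c(lines, "## Locus QC", "", "_not run_", "")
  if (!is.null(art$screen)) {
    s <- art$screen
    sat <- s$saturation_summary
    lines <- c(lines, "## Per-locus screening", "",
               sprintf("- significant after Holm (p < %g): %d / %d",
                       s$alpha, s$n_significant, nrow(s$table)),
               sprintf("- saturation age (months), significant loci: mean %s, min %s, max %s",
                       fmt(sat$including_extreme["mean"]),
                       fmt(sat$including_extreme["min"]),
                       fmt(sat$including_extreme["max"])),
               sprintf("- excluding the most extreme locus: mean %s, max %s",
                       fmt(sat$excluding_extreme["mean"]),
                       fmt(sat$excluding_extreme["max"])), "")
  } else lines <- c(lines, "## Per-locus screening", "", "_not run_", "")
  if (!is.null(art$model)) {
    m <- art$model
    lines <- c(lines, "## Ageing model", "",
               sprintf("- alpha %g, lambda %s, %d loci selected",
                       m$alpha, fmt(m$lambda), m$n_loci_selected),
               sprintf("- training MAE %s months, RMSE %s, R2 %s",
                       fmt(m$metrics$mae), fmt(m$metrics$rmse),
                       fmt(m$metrics$r2_cor)), "")
  } else lines <- c(lines, "## Ageing model", "", "_not run_", "")
  if (!is.null(art$loocv)) {
    lv <- art$loocv
    lines <- c(lines, "## LOOCV precision", "",
               sprintf("- precision SD %s months, R2 %s",
                       fmt(lv$precision_sd), fmt(lv$r2)), "")
  } else lines <- c(lines, "## LOOCV precision", "", "_not run_", "")
  if (!is.null(art$wild)) {
    p <- art$wild$predicted_age_months
    br <- pretty(p, 10)
    h <- hist(p, breaks = br, plot = FALSE)
    lines <- c(lines, "## Wild age predictions", "",
               sprintf("- n = %d, mean %s months, range %s--%s",
                       length(p), fmt(mean(p)), fmt(min(p)), fmt(max(p))),
               "", "| bin start | count |", "|---|---|",
               sprintf("| %s | %d |", fmt(h$breaks[-length(h$breaks)]),
                       h$counts), "")
  } else lines <- c(lines, "## Wild age predictions", "", "_not run_", "")
  if (!is.null(art$growth)) {
    g <- art$growth
    lines <- c(lines, "## Growth model", "",
               sprintf("- %s fit: %s (converged: %s)",
                       g$parameterisation,
                       paste(names(g$params), vapply(g$params, fmt, ""),
                             sep = "=", collapse = ", "),
                       g$converged), "")
  } else lines <- c(lines, "## Growth model", "", "_not run_", "")
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' @importFrom graphics hist
NULL
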