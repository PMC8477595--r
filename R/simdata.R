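#' Simulation configuration for a synthetic lobster methylation study
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults emulate a known-age European lobster cohort design: seven
#' hatchery cohorts aged 0--51 months (n = 155) plus 38 wild-caught animals
#' of unknown age, 436 sequenced CpGs of which roughly 60\% carry a linear
#' methylation--age trend, mean per-locus read coverage 7107 (25,253 for the
#' two oldest cohorts, sequenced on a second run), and a bisulphite
#' conversion rate of 99.5\%.
#'
#' @param n_loci number of CpG loci on the panel.
#' @param frac_informative fraction of loci with a nonzero methylation--age
#'   slope.
#' @param cohort_ages_months known cohort ages, months post-hatching.
#' @param cohort_sizes samples per cohort; same length as
#'   `cohort_ages_months`.
#' @param n_wild number of unknown-age wild samples.
#' @param wild_age_range_months interval the (latent) wild ages are drawn
#'   uniformly from.
#' @param coverage_mean,coverage_mean_batch2 negative-binomial mean read
#'   coverage per (sample, locus) cell for batch 1 / batch 2 samples.
#' @param coverage_dispersion negative-binomial size parameter; larger means
#'   closer to Poisson.
#' @param conversion_rate bisulphite conversion rate in (0, 1]; unconverted
#'   unmethylated cytosines read as methylated.
#' @param missing_rate per-cell probability that a (sample, locus) datum is
#'   withheld entirely (amplicon dropout).
#' @param batch_shift additive percent-methylation offset applied to batch-2
#'   samples before read sampling (a technical artefact knob).
#' @param sex_shift additive percent offset (female minus male) applied to
#'   every locus; 0 disables sex structure.
#' @param sex_shift_sign_by_cohort optional numeric vector (one per cohort,
#'   values in -1/0/1) reversing the sex shift per cohort.
#' @param age_jitter_sd SD (months) of within-cohort age jitter; 0 keeps
#'   cohorts at their nominal ages.
#' @param sd_individual between-individual biological noise SD (percent) at
#'   every locus.
#' @param intercept_range,slope_range uniform ranges the per-locus baseline
#'   methylation (percent at age 0) and absolute slope (percent/month) are
#'   drawn from; slopes get a random sign so hyper- and hypomethylating loci
#'   are both represented.
#' @param growth_params named list with `Linf` (mm), `K` (per month) and `t0`
#'   (months) of the von Bertalanffy curve governing body size.
#' @param cv_Linf coefficient of variation of individual asymptotic size.
#' @param sd_measure measurement noise SD on carapace length, mm.
#' @param seed integer seed; every derived stage reseeds deterministically
#'   from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 436L,
                       frac_informative = 0.60,
                       cohort_ages_months = c(0, 1.8, 7.3, 12.5, 24.8, 40, 51),
                       cohort_sizes = c(27L, 29L, 26L, 19L, 32L, 5L, 17L),
                       n_wild = 38L,
                       wild_age_range_months = c(48, 108),
                       coverage_mean = 7107,
                       coverage_mean_batch2 = 25253,
                       coverage_dispersion = 5,
                       conversion_rate = 0.995,
                       missing_rate = 0.001,
                       batch_shift = 0,
                       sex_shift = 0,
                       sex_shift_sign_by_cohort = NULL,
                       age_jitter_sd = 0,
                       sd_individual = 2,
                       intercept_range = c(10, 90),
                       slope_range = c(0.1, 1.0),
                       growth_params = list(Linf = 46.2, K = 0.06, t0 = 3.288),
                       cv_Linf = 0.05,
                       sd_measure = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!is_count(n_loci) || n_loci < 1) stopf("n_loci must be a positive integer")
  for (f in c("frac_informative", "conversion_rate", "missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stopf("%s must be a fraction in [0, 1]", f)
  }
  if (length(cohort_ages_months) != length(cohort_sizes))
    stopf("cohort_ages_months and cohort_sizes must have equal length")
  if (any(cohort_sizes < 0) || any(cohort_ages_months < 0))
    stopf("cohort ages and sizes must be non-negative")
  if (coverage_mean <= 0 || coverage_mean_batch2 <= 0 || coverage_dispersion <= 0)
    stopf("coverage parameters must be positive")
  if (length(wild_age_range_months) != 2 || diff(wild_age_range_months) < 0)
    stopf("wild_age_range_months must be an increasing interval")
  if (!is.null(sex_shift_sign_by_cohort) &&
      length(sex_shift_sign_by_cohort) != length(cohort_ages_months))
    stopf("sex_shift_sign_by_cohort must have one entry per cohort")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic CpG locus panel
#'
#' Draws per-locus linear methylation trajectories. Exactly
#' `round(frac_informative * n_loci)` loci receive a nonzero slope; signs are
#' assigned alternately so hypermethylating and hypomethylating loci are
#' balanced. Loci are laid out across the rDNA regions 18S, ITS1, ITS2 and
#' 28S with unique positions per region.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `locus_id`, `region`, `position`,
#'   `intercept_a`, `slope_b`, `sd_individual`.
#' @export
make_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_loci
  n_inf <- round(config$frac_informative * n)
  regions <- c("18S", "ITS1", "ITS2", "28S")
  with_seed(child_seed(config$seed, "panel"), {
    region <- sort(sample(rep_len(regions, n)))
    # region is sorted, so split() blocks are contiguous and unlist() keeps
    # positions aligned with region
    position <- unlist(lapply(split(seq_len(n), region), function(idx) {
      sort(sample.int(5 * length(idx) + 50, length(idx)))
    }), use.names = FALSE)
    intercept <- runif(n, config$intercept_range[1], config$intercept_range[2])
    slope <- numeric(n)
    if (n_inf > 0) {
      which_inf <- sample.int(n, n_inf)
      mag <- runif(n_inf, config$slope_range[1], config$slope_range[2])
      sign <- rep_len(c(1, -1), n_inf)[sample.int(n_inf)]
      slope[which_inf] <- mag * sign
    }
    data.frame(
      locus_id = paste0(region, "_", position),
      region = region,
      position = position,
      intercept_a = intercept,
      slope_b = slope,
      sd_individual = rep(config$sd_individual, n),
      stringsAsFactors = FALSE
    )
  })
}

#' Expected (true) percent methylation at a locus
#'
#' Evaluates the locus's linear trajectory and clamps into \[0, 100\],
#' encoding saturation: once a locus is fully methylated or fully
#' unmethylated it stays there.
#'
#' @param locus one row of a panel (list/data.frame with `intercept_a`,
#'   `slope_b`).
#' @param age age in months, >= 0 (vectorised).
#' @param individual_offset additive biological offset, percent.
#' @return percent methylation in \[0, 100\].
#' @export
true_methylation <- function(locus, age, individual_offset = 0) {
  if (any(age < 0)) stopf("age must be non-negative")
  clamp(locus$intercept_a + locus$slope_b * age + individual_offset, 0, 100)
}

#' Generate the sample sheet for a synthetic study
#'
#' Builds per-sample metadata: cohort label, age (NA for wild samples in the
#' public sheet; the latent wild age lives in the truth object), tissue, sex,
#' and sequencing batch. The two oldest cohorts form batch 2.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `sample_id`, `age_months`, `tissue`,
#'   `sex`, `cohort`, `batch` plus hidden column `true_age_months`.
#' @export
make_samplesheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ages <- config$cohort_ages_months
  sizes <- config$cohort_sizes
  n_known <- sum(sizes)
  with_seed(child_seed(config$seed, "samples"), {
    cohort <- rep(paste0("m", ages), sizes)
    known_age <- rep(ages, sizes)
    if (config$age_jitter_sd > 0)
      known_age <- pmax(0, known_age + rnorm(n_known, 0, config$age_jitter_sd))
    wild_age <- runif(config$n_wild, config$wild_age_range_months[1],
                      config$wild_age_range_months[2])
    n_batch2 <- sum(sizes[ages >= 40])
    batch <- c(rep(1L, n_known - n_batch2), rep(2L, n_batch2),
               rep(1L, config$n_wild))
    n_all <- n_known + config$n_wild
    data.frame(
      sample_id = sprintf("L%03d", seq_len(n_all)),
      age_months = c(known_age, rep(NA_real_, config$n_wild)),
      tissue = c(rep("claw", n_known - n_batch2), rep("leg", n_batch2),
                 rep("antenna", config$n_wild)),
      sex = sample(c("F", "M"), n_all, replace = TRUE),
      cohort = c(cohort, rep("wild", config$n_wild)),
      batch = batch,
      true_age_months = c(known_age, wild_age),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate per-CpG bisulphite read counts
#'
#' For every (sample, locus) cell, draws read coverage from a negative
#' binomial with the batch-specific mean, then methylated reads from a
#' binomial at the observed methylation probability. Observed methylation is
#' the true linear trajectory plus individual noise (and any batch/sex
#' shifts), inflated by bisulphite non-conversion:
#' `p_obs = p_true + (100 - p_true) * (1 - conversion_rate)`.
#' A `missing_rate` fraction of cells is withheld entirely.
#'
#' @param panel locus panel from [make_panel()].
#' @param samplesheet sample sheet from [make_samplesheet()].
#' @param config a [sim_config()].
#' @return list with `counts` (a `MethylCountTable`) and `truth` (per-sample
#'   true ages and the samples x loci true-methylation matrix before
#'   sequencing noise).
#' @export
simulate_counts <- function(panel, samplesheet, config) {
  stopifnot(inherits(config, "sim_config"))
  n_s <- nrow(samplesheet)
  n_l <- nrow(panel)
  ages <- samplesheet$true_age_months
  if (is.null(ages)) ages <- samplesheet$age_months
  if (any(is.na(ages))) stopf("samplesheet must carry true ages for simulation")
  with_seed(child_seed(config$seed, "counts"), {
    offsets <- matrix(rnorm(n_s * n_l, 0, rep(panel$sd_individual, each = n_s)),
                      n_s, n_l)
    p_true <- clamp(matrix(rep(panel$intercept_a, each = n_s), n_s, n_l) +
                    outer(ages, panel$slope_b) + offsets, 0, 100)
    p_cell <- p_true
    if (config$batch_shift != 0)
      p_cell[samplesheet$batch == 2L, ] <-
        p_cell[samplesheet$batch == 2L, ] + config$batch_shift
    if (config$sex_shift != 0) {
      sgn <- rep(1, n_s)
      if (!is.null(config$sex_shift_sign_by_cohort)) {
        names(config$sex_shift_sign_by_cohort) <-
          paste0("m", config$cohort_ages_months)
        m <- config$sex_shift_sign_by_cohort[samplesheet$cohort]
        sgn <- ifelse(is.na(m), 1, m)
      }
      fem <- samplesheet$sex == "F"
      p_cell[fem, ] <- p_cell[fem, ] + (config$sex_shift * sgn[fem]) / 2
      p_cell[!fem, ] <- p_cell[!fem, ] - (config$sex_shift * sgn[!fem]) / 2
    }
    p_cell <- clamp(p_cell, 0, 100)
    # non-conversion: unmethylated C occasionally read as methylated
    p_obs <- p_cell + (100 - p_cell) * (1 - config$conversion_rate)
    mu <- ifelse(samplesheet$batch == 2L,
                 config$coverage_mean_batch2, config$coverage_mean)
    coverage <- matrix(rnbinom(n_s * n_l, size = config$coverage_dispersion,
                               mu = rep(mu, n_l)), n_s, n_l)
    meth <- matrix(rbinom(n_s * n_l, as.vector(coverage),
                          as.vector(p_obs) / 100), n_s, n_l)
    unmeth <- coverage - meth
    drop <- matrix(runif(n_s * n_l) < config$missing_rate, n_s, n_l)
    drop <- drop | coverage == 0L
    meth[drop] <- NA_integer_
    unmeth[drop] <- NA_integer_
    counts <- meth_count_table(meth, unmeth, panel, samplesheet$sample_id)
    truth <- list(
      sample_id = samplesheet$sample_id,
      true_age_months = ages,
      sex = samplesheet$sex,
      batch = samplesheet$batch,
      true_methylation = `dimnames<-`(p_true,
                                      list(samplesheet$sample_id,
                                           panel$locus_id))
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate carapace lengths from a von Bertalanffy growth curve
#'
#' `CL_i = Linf_i * (1 - exp(-K (age_i - t0))) + e_i` with individual
#' asymptotic sizes lognormal around `Linf` (CV `cv_Linf`) and Gaussian
#' measurement error; negative lengths are truncated at 0 and flagged.
#'
#' @param samplesheet sample sheet carrying `true_age_months` (or
#'   `age_months`).
#' @param growth_params list with `Linf`, `K`, `t0`.
#' @param cv_Linf coefficient of variation of individual `Linf`.
#' @param sd_measure measurement SD, mm.
#' @param seed integer seed.
#' @return numeric vector of lengths (mm) with attribute `clamped` marking
#'   samples truncated at zero.
#' @export
simulate_sizes <- function(samplesheet,
                           growth_params = list(Linf = 46.2, K = 0.06, t0 = 3.288),
                           cv_Linf = 0, sd_measure = 0, seed = 1L) {
  ages <- samplesheet$true_age_months
  if (is.null(ages)) ages <- samplesheet$age_months
  if (any(is.na(ages))) stopf("ages must be known for all samples")
  with_seed(seed, {
    n <- length(ages)
    linf_i <- if (cv_Linf > 0) {
      sdlog <- sqrt(log(1 + cv_Linf^2))
      rlnorm(n, log(growth_params$Linf) - sdlog^2 / 2, sdlog)
    } else rep(growth_params$Linf, n)
    cl <- linf_i * (1 - exp(-growth_params$K * (ages - growth_params$t0)))
    if (sd_measure > 0) cl <- cl + rnorm(n, 0, sd_measure)
    clamped <- cl < 0
    cl[clamped] <- 0
    structure(cl, clamped = clamped)
  })
}

#' Simulate a full synthetic dataset, optionally writing it to disk
#'
#' Runs [make_panel()], [make_samplesheet()], [simulate_counts()] and
#' [simulate_sizes()] under the config's seed. If `out_dir` is given, writes
#' one Bismark-style coverage file per sample, a `samples.csv` sheet (ages
#' blanked for wild samples) and a `truth.json` ground-truth file.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `panel`, `samplesheet`, `counts`, `truth`, `sizes`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  panel <- make_panel(config)
  sheet <- make_samplesheet(config)
  sim <- simulate_counts(panel, sheet, config)
  sheet$carapace_length_mm <- simulate_sizes(
    sheet, config$growth_params, config$cv_Linf, config$sd_measure,
    seed = child_seed(config$seed, "sizes"))
  res <- list(panel = panel, samplesheet = sheet, counts = sim$counts,
              truth = sim$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cov_dir <- file.path(out_dir, "coverage")
    dir.create(cov_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(sheet))) {
      write_coverage_file(
        sample_counts(sim$counts, sheet$sample_id[i]),
        file.path(cov_dir, paste0(sheet$sample_id[i], ".cov")))
    }
    pub <- sheet[, c("sample_id", "age_months", "tissue", "sex", "cohort",
                     "batch", "carapace_length_mm")]
    write.csv(pub, file.path(out_dir, "samples.csv"), row.names = FALSE)
    truth_out <- sim$truth
    truth_out$true_methylation <- NULL  # keep truth.json small
    truth_out$panel <- panel
    jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
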