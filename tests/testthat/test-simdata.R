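test_that("make_panel hits the configured informative fraction exactly", {
  cases <- list(c(355, 0.60, 213), c(100, 0.5, 50), c(10, 0, 0), c(7, 1, 7))
  for (cs in cases) {
    cfg <- sim_config(n_loci = as.integer(cs[1]), frac_informative = cs[2],
                      seed = 11L)
    panel <- make_panel(cfg)
    expect_equal(sum(panel$slope_b != 0), cs[3])
  }
})

test_that("panel slopes carry both signs and positions are unique per region", {
  panel <- make_panel(sim_config(n_loci = 200L, seed = 3L))
  slopes <- panel$slope_b[panel$slope_b != 0]
  expect_gt(sum(slopes > 0), 0)
  expect_gt(sum(slopes < 0), 0)
  # hyper/hypo balanced to within one locus
  expect_lte(abs(sum(slopes > 0) - sum(slopes < 0)), 1)
  for (reg in unique(panel$region)) {
    pos <- panel$position[panel$region == reg]
    expect_false(any(duplicated(pos)))
  }
  expect_true(all(panel$intercept_a >= 0 & panel$intercept_a <= 100))
})

test_that("panel generation is deterministic given the seed", {
  cfg <- sim_config(n_loci = 50L, seed = 99L)
  expect_identical(make_panel(cfg), make_panel(cfg))
  cfg2 <- sim_config(n_loci = 50L, seed = 100L)
  expect_false(identical(make_panel(cfg), make_panel(cfg2)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_informative = 1.2), "fraction")
  expect_error(sim_config(n_loci = 0L), "positive")
  expect_error(sim_config(coverage_mean = -1), "positive")
  expect_error(sim_config(cohort_ages_months = c(0, 1), cohort_sizes = 5L),
               "equal length")
})

test_that("true_methylation follows the clamped linear trajectory", {
  expect_equal(true_methylation(list(intercept_a = 20, slope_b = 1), 30), 50)
  expect_equal(true_methylation(list(intercept_a = 95, slope_b = 1), 30), 100)
  expect_equal(true_methylation(list(intercept_a = 60, slope_b = -0.5), 200), 0)
  expect_equal(true_methylation(list(intercept_a = 20, slope_b = 1), 30,
                                individual_offset = 5), 55)
  expect_error(true_methylation(list(intercept_a = 20, slope_b = 1), -1),
               "non-negative")
})

test_that("simulated counts satisfy basic invariants", {
  d <- small_dataset(seed = 7L)
  counts <- d$ds$counts
  expect_true(all(counts$meth >= 0, na.rm = TRUE))
  expect_true(all(counts$unmeth >= 0, na.rm = TRUE))
  pct <- percent_methylation(counts$meth, counts$unmeth)
  expect_true(all(pct >= 0 & pct <= 100, na.rm = TRUE))
  expect_true(all(d$ds$truth$true_methylation >= 0 &
                    d$ds$truth$true_methylation <= 100))
})

test_that("identical seed and config give identical simulations", {
  cfg <- small_config(seed = 5L)
  a <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  b <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  expect_identical(a, b)
})

test_that("coverage sampling matches the configured mean", {
  # Monte-Carlo check of the count-sampling routine at large dispersion
  cfg <- sim_config(n_loci = 100L, cohort_ages_months = c(0, 10),
                    cohort_sizes = c(50L, 50L), n_wild = 0L,
                    coverage_mean = 7107, coverage_dispersion = 1e6,
                    missing_rate = 0, seed = 21L)
  sim <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  cov <- sim$counts$meth + sim$counts$unmeth
  expect_lt(abs(mean(cov) - 7107) / 7107, 0.02)
})

test_that("non-conversion inflates apparent methylation by (1 - rate) * 100", {
  cfg <- sim_config(n_loci = 200L, frac_informative = 0,
                    intercept_range = c(0, 0), sd_individual = 0,
                    cohort_ages_months = c(0, 10), cohort_sizes = c(20L, 20L),
                    n_wild = 0L, conversion_rate = 0.99, missing_rate = 0,
                    coverage_mean = 2000, seed = 13L)
  sim <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  pct <- percent_methylation(sim$counts$meth, sim$counts$unmeth)
  expect_lt(abs(mean(pct) - 1.0), 0.05)  # expect 1% apparent methylation
})

test_that("fully methylated loci are unaffected by conversion rate", {
  cfg <- sim_config(n_loci = 50L, frac_informative = 0,
                    intercept_range = c(100, 100), sd_individual = 0,
                    cohort_ages_months = c(0, 10), cohort_sizes = c(10L, 10L),
                    n_wild = 0L, conversion_rate = 0.9, missing_rate = 0,
                    coverage_mean = 500, seed = 13L)
  sim <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  expect_true(all(sim$counts$unmeth == 0))
})

test_that("empirical methylation converges to the truth at high coverage", {
  # binomial sd at coverage 1e5 is <= 0.16 percent, so over these 90 cells
  # the max |deviation| sits comfortably below 0.5 percent
  cfg <- sim_config(n_loci = 10L, conversion_rate = 1, missing_rate = 0,
                    sd_individual = 0, cohort_ages_months = c(0, 20, 40),
                    cohort_sizes = c(3L, 3L, 3L), n_wild = 0L,
                    coverage_mean = 1e5, coverage_mean_batch2 = 1e5,
                    coverage_dispersion = 1e4, seed = 17L)
  sim <- simulate_counts(make_panel(cfg), make_samplesheet(cfg), cfg)
  pct <- percent_methylation(sim$counts$meth, sim$counts$unmeth)
  expect_lt(max(abs(pct - sim$truth$true_methylation)), 0.5)
})

test_that("missing_rate withholds roughly the configured fraction of cells", {
  d <- small_dataset(seed = 9L, missing_rate = 0.05)
  frac <- mean(is.na(d$ds$counts$meth))
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("simulate_sizes follows the von Bertalanffy curve", {
  gp <- list(Linf = 46.2, K = 0.06, t0 = 3.288)
  sheet <- data.frame(true_age_months = c(3.288, 24.8, 1e6))
  cl <- simulate_sizes(sheet, gp, cv_Linf = 0, sd_measure = 0)
  expect_equal(cl[1], 0)
  expect_equal(cl[2], 46.2 * (1 - exp(-0.06 * (24.8 - 3.288))), tolerance = 1e-12)
  expect_equal(cl[3], 46.2, tolerance = 1e-9)
  # ages below t0 are truncated at 0 and flagged
  cl0 <- simulate_sizes(data.frame(true_age_months = 0), gp, 0, 0)
  expect_equal(unname(cl0[1]), 0)
  expect_true(attr(cl0, "clamped")[1])
})

test_that("batch-2 samples get batch-specific coverage and shift", {
  cfg <- small_config(seed = 30L, batch_shift = 10, frac_informative = 0,
                      intercept_range = c(50, 50), sd_individual = 0,
                      conversion_rate = 1)
  ds <- simulate_dataset(cfg)
  b2 <- ds$samplesheet$batch == 2
  expect_true(any(b2))
  pct <- percent_methylation(ds$counts$meth, ds$counts$unmeth)
  expect_gt(mean(pct[b2, ], na.rm = TRUE) - mean(pct[!b2, ], na.rm = TRUE), 8)
  # truth records the biology before the technical shift
  expect_equal(unique(as.vector(ds$truth$true_methylation)), 50)
})
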