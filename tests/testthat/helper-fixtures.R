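# Shared fixtures: small, fast synthetic configurations and toy builders.

# A small study: 5 cohorts, 40 known + 6 wild samples, 60 loci.
small_config <- function(seed = 42L, missing_rate = 0, ...) {
  sim_config(
    n_loci = 60L,
    cohort_ages_months = c(0, 2, 12, 25, 51),
    cohort_sizes = c(8L, 8L, 8L, 8L, 8L),
    n_wild = 6L,
    coverage_mean = 500,
    coverage_mean_batch2 = 800,
    missing_rate = missing_rate,
    seed = seed,
    ...
  )
}

# Simulate a QC'd known-age methylation matrix plus ages and truth.
small_dataset <- function(seed = 42L, ...) {
  cfg <- small_config(seed = seed, ...)
  ds <- simulate_dataset(cfg)
  qc <- apply_qc(ds$counts, min_reads = 1)
  known <- !is.na(ds$samplesheet$age_months)
  list(config = cfg, ds = ds, qc = qc,
       matrix = qc$matrix$values[known, , drop = FALSE],
       ages = ds$samplesheet$age_months[known],
       sheet = ds$samplesheet[known, , drop = FALSE],
       panel = ds$panel)
}

# Deterministic toy count table: counts[s, l] with given missing cells.
toy_count_table <- function(meth, unmeth) {
  n_l <- ncol(meth)
  loci <- data.frame(
    locus_id = paste0("18S_", seq_len(n_l)),
    region = "18S", position = seq_len(n_l), stringsAsFactors = FALSE)
  meth_count_table(meth, unmeth, loci, paste0("S", seq_len(nrow(meth))))
}

# Independent brute-force Holm oracle: explicit sort / multiply / cummax.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  out <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    out[ord[i]] <- running
  }
  out
}

# Closed-form OLS oracle via normal equations.
ols_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)
}
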