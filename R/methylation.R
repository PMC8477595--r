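#' Construct a per-CpG methylated/unmethylated count table
#'
#' The central count container: two samples x loci integer matrices of
#' methylated and unmethylated read counts. A cell that is `NA` in both
#' matrices is a missing datum (amplicon dropout); counts must otherwise be
#' non-negative integers.
#'
#' @param meth,unmeth samples x loci matrices of read counts (NA = missing).
#' @param loci data frame with `locus_id`, `region`, `position` describing
#'   the columns.
#' @param samples character vector of sample ids describing the rows.
#' @return object of class `MethylCountTable`.
#' @export
meth_count_table <- function(meth, unmeth, loci, samples) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth)))
    stopf("meth and unmeth matrices must have identical dimensions")
  if (nrow(meth) != length(samples) || ncol(meth) != nrow(loci))
    stopf("count matrices must be samples x loci")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stopf("read counts must be non-negative")
  if (any(is.na(meth) != is.na(unmeth)))
    stopf("a cell must be missing in both count matrices or neither")
  dimnames(meth) <- dimnames(unmeth) <- list(samples, loci$locus_id)
  structure(list(meth = meth, unmeth = unmeth, loci = loci,
                 samples = samples),
            class = "MethylCountTable")
}

#' @export
print.MethylCountTable <- function(x, ...) {
  cat(sprintf("MethylCountTable: %d samples x %d loci (%d missing cells)\n",
              length(x$samples), nrow(x$loci), sum(is.na(x$meth))))
  invisible(x)
}

#' Percent methylation from read counts
#'
#' Reads reporting C (methylated) divided by reads reporting C or T, times
#' 100. Zero total coverage is a missing datum (`NA`), not 0\%.
#'
#' @param count_meth,count_unmeth non-negative read counts (vectorised).
#' @return percent methylation in \[0, 100\], `NA` where coverage is zero.
#' @export
percent_methylation <- function(count_meth, count_unmeth) {
  if (any(count_meth < 0, na.rm = TRUE) || any(count_unmeth < 0, na.rm = TRUE))
    stopf("read counts must be non-negative")
  total <- count_meth + count_unmeth
  ifelse(total > 0, 100 * count_meth / total, NA_real_)
}

#' Bisulphite conversion rate from non-CpG cytosine counts
#'
#' Conversion rate = T reads / (C + T reads) x 100 at positions that are
#' unmethylated a priori. Samples below `threshold` are flagged.
#'
#' @param count_C,count_T reads retaining C / converted to T (vectorised).
#' @param threshold flagging threshold, percent.
#' @return percent conversion with logical attribute `flagged`; `NA` when
#'   total is zero.
#' @export
conversion_rate <- function(count_C, count_T, threshold = 99) {
  if (any(count_C < 0, na.rm = TRUE) || any(count_T < 0, na.rm = TRUE))
    stopf("counts must be non-negative")
  total <- count_C + count_T
  rate <- ifelse(total > 0, 100 * count_T / total, NA_real_)
  structure(rate, flagged = !is.na(rate) & rate < threshold)
}

#' Apply locus quality control and build the analysis matrix
#'
#' A locus is dropped if it is missing in any sample (reason `missing`,
#' checked first) or if any sample's coverage at it is below `min_reads`
#' (reason `low_coverage`). Retained loci are ordered by (region, position)
#' and converted to percent methylation.
#'
#' @param table a `MethylCountTable`.
#' @param min_reads minimum total reads per (sample, locus) cell.
#' @return list with `matrix` (a `MethylationMatrix`: `values`, `loci`,
#'   `samples`) and `report` (a `QCReport`: input/retained counts, per-locus
#'   drop reasons, per-sample coverage summaries).
#' @export
apply_qc <- function(table, min_reads = 10) {
  stopifnot(inherits(table, "MethylCountTable"))
  if (length(table$samples) < 1) stopf("need at least one sample")
  total <- table$meth + table$unmeth
  any_missing <- apply(is.na(total), 2, any)
  low_cov <- !any_missing & apply(total < min_reads, 2, any)
  keep <- !(any_missing | low_cov)
  if (!any(keep))
    stopf("QC removed every locus: empty methylation matrix")
  reason <- rep(NA_character_, ncol(total))
  reason[any_missing] <- "missing"
  reason[low_cov] <- "low_coverage"
  ord <- order(table$loci$region[keep], table$loci$position[keep])
  kept_idx <- which(keep)[ord]
  values <- percent_methylation(table$meth[, kept_idx, drop = FALSE],
                                table$unmeth[, kept_idx, drop = FALSE])
  matrix_obj <- structure(
    list(values = values,
         loci = table$loci[kept_idx, , drop = FALSE],
         samples = table$samples),
    class = "MethylationMatrix")
  report <- structure(
    list(n_loci_input = ncol(total),
         n_loci_retained = length(kept_idx),
         min_reads = min_reads,
         dropped = data.frame(
           locus_id = table$loci$locus_id[!keep],
           reason = reason[!keep],
           stringsAsFactors = FALSE),
         coverage_per_sample = data.frame(
           sample_id = table$samples,
           min_coverage = apply(total, 1, min, na.rm = TRUE),
           mean_coverage = rowMeans(total, na.rm = TRUE),
           stringsAsFactors = FALSE)),
    class = "QCReport")
  list(matrix = matrix_obj, report = report)
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d samples x %d loci\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Extract one sample's counts as a coverage-style data frame.
sample_counts <- function(table, sample_id) {
  i <- match(sample_id, table$samples)
  if (is.na(i)) stopf("unknown sample '%s'", sample_id)
  keep <- !is.na(table$meth[i, ])
  data.frame(
    region = table$loci$region[keep],
    position = table$loci$position[keep],
    count_methylated = as.integer(table$meth[i, keep]),
    count_unmethylated = as.integer(table$unmeth[i, keep]),
    stringsAsFactors = FALSE
  )
}

#' Write a Bismark-style coverage file
#'
#' Tab-separated, no header:
#' `chromosome start end percent_methylation count_methylated
#' count_unmethylated`, 1-based inclusive single-base intervals with the
#' rDNA region name as chromosome. The percent column is recomputed from the
#' counts and rounded to 6 decimals.
#'
#' @param counts data frame with `region`, `position`, `count_methylated`,
#'   `count_unmethylated`.
#' @param path output path.
#' @export
write_coverage_file <- function(counts, path) {
  if (any(counts$count_methylated < 0) || any(counts$count_unmethylated < 0))
    stopf("read counts must be non-negative")
  pct <- round(percent_methylation(counts$count_methylated,
                                   counts$count_unmethylated), 6)
  out <- data.frame(counts$region, counts$position, counts$position,
                    pct, counts$count_methylated, counts$count_unmethylated)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage file
#'
#' Parses the 6-column dialect written by [write_coverage_file()]. Malformed
#' rows raise an error naming the line; a percent column inconsistent with
#' the counts by more than 0.01 triggers a warning.
#'
#' @param path file path.
#' @return data frame with `region`, `position`, `count_methylated`,
#'   `count_unmethylated`, `percent`.
#' @export
read_coverage_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warnf("empty coverage file: %s", path)
    return(data.frame(region = character(), position = integer(),
                      count_methylated = integer(),
                      count_unmethylated = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6)
  if (length(bad))
    stopf("malformed coverage row at line %d of %s", bad[1], path)
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(start) | is.na(end) | is.na(pct) | is.na(meth) |
                 is.na(unmeth) | start != end | meth < 0 | unmeth < 0)
  if (length(bad))
    stopf("malformed coverage row at line %d of %s", bad[1], path)
  recomputed <- percent_methylation(meth, unmeth)
  off <- which(!is.na(recomputed) & abs(recomputed - pct) > 0.01)
  if (length(off))
    warnf("%d rows of %s have percent inconsistent with counts (first at line %d)",
          length(off), path, off[1])
  data.frame(region = m[, 1], position = start, count_methylated = meth,
             count_unmethylated = unmeth, percent = pct,
             stringsAsFactors = FALSE)
}

#' Assemble a count table from a directory of coverage files
#'
#' Reads `<sample_id>.cov` for every row of the sample sheet and aligns all
#' samples on the union of (region, position) loci; loci absent from a
#' sample are missing cells.
#'
#' @param dir directory of coverage files.
#' @param samplesheet data frame with at least `sample_id`.
#' @return a `MethylCountTable`.
#' @export
read_coverage_dir <- function(dir, samplesheet) {
  per_sample <- lapply(samplesheet$sample_id, function(sid) {
    read_coverage_file(file.path(dir, paste0(sid, ".cov")))
  })
  all_loci <- unique(do.call(rbind, lapply(per_sample, function(d)
    d[, c("region", "position")])))
  all_loci <- all_loci[order(all_loci$region, all_loci$position), ]
  loci <- data.frame(
    locus_id = paste0(all_loci$region, "_", all_loci$position),
    region = all_loci$region, position = all_loci$position,
    stringsAsFactors = FALSE)
  n_s <- nrow(samplesheet); n_l <- nrow(loci)
  meth <- matrix(NA_integer_, n_s, n_l)
  unmeth <- matrix(NA_integer_, n_s, n_l)
  for (i in seq_len(n_s)) {
    d <- per_sample[[i]]
    j <- match(paste0(d$region, "_", d$position), loci$locus_id)
    meth[i, j] <- d$count_methylated
    unmeth[i, j] <- d$count_unmethylated
  }
  meth_count_table(meth, unmeth, loci, samplesheet$sample_id)
}

#' Export a methylation matrix as CSV
#'
#' Samples as rows, `region_position` locus ids as column headers.
#'
#' @param matrix_obj a `MethylationMatrix`.
#' @param path output path.
#' @export
write_methylation_matrix <- function(matrix_obj, path) {
  df <- data.frame(sample_id = matrix_obj$samples,
                   matrix_obj$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a methylation matrix CSV written by [write_methylation_matrix()]
#' @param path file path.
#' @return a `MethylationMatrix` (region/position recovered from locus ids).
#' @export
read_methylation_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  ids <- colnames(values)
  pos <- sub("^.*_", "", ids)
  structure(list(
    values = values,
    loci = data.frame(locus_id = ids,
                      region = sub("_[0-9]+$", "", ids),
                      position = as.integer(pos),
                      stringsAsFactors = FALSE),
    samples = df$sample_id), class = "MethylationMatrix")
}
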