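# Internal helpers shared across modules.

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps results < 2^31 and stable across platforms.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

# Extract the samples x loci numeric matrix from a MethylationMatrix or a
# plain matrix with dimnames.
meth_values <- function(x) {
  if (inherits(x, "MethylationMatrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stopf("expected a MethylationMatrix or numeric matrix, got %s", class(x)[1])
}
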