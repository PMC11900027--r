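# Internal helpers shared across modules.

# Round half away from zero is NOT what we want; printed concentrations use
# conventional commercial rounding: half up.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Lower median: for even n take the lower of the two middle order statistics.
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-stage seed expansion from one global seed; offsets keep
# every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 99991 * stage) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

# Row means / variances for a numeric matrix without extra dependencies.
row_vars <- function(m, means = rowMeans(m)) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  rowSums((m - means)^2) / (n - 1)
}

# Fixed-format numeric serialization (%.6g) so output files hash stably.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
}
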