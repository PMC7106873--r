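# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Condition constructors: subclassed errors so the CLI can map them to exit codes.
ldf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ldf_error", "error")))
}
config_error <- function(msg) ldf_stop(msg, "ldf_config_error")
data_error <- function(msg) ldf_stop(msg, "ldf_data_error")
numerical_error <- function(msg) ldf_stop(msg, "ldf_numerical_error")

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    config_error(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  }
  if (integer && x != round(x)) {
    config_error(sprintf("'%s' must be an integer, got %s", name, x))
  }
  invisible(x)
}

col_norms <- function(m) sqrt(colSums(m^2))

frob <- function(m) sqrt(sum(m^2))

# Stable content hash via serialization + md5 (base tools only).
hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
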