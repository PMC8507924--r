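# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from (base, index), kept < 2^31.
derive_seed <- function(base, index) {
  as.integer((as.double(base) %% 2147483629 * 48271 + index * 9973) %%
               2147483629)
}

# Truncated-normal draws by bounded redraw; truncation mass must be tiny for
# the calibrated defaults (see the methods vignette).
rtnorm_lower <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x[x < lower] <- lower
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
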