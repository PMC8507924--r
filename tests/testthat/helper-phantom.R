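# Down-scaled phantom fixtures for fast unit tests: same generative
# structure as the defaults, smaller tumors on a smaller grid.

small_volume_params <- function() {
  data.frame(roi = c("En", "Nec", "LMD_LrCBV", "HMD_LrCBV", "En_HrCBV",
                     "tumor"),
             mean = c(0.40, 0.50, 0.60, 0.20, 0.10, 1.60),
             sd = c(0.10, 0.12, 0.15, 0.08, 0.05, 0.50))
}

small_group_model <- function(group = "short", noise_sd = NULL) {
  group_model(group, volume_params = small_volume_params(),
              lmd_lrcbv_nec_mean = 0.08, lmd_lrcbv_nec_sd = 0.03,
              noise_sd = noise_sd)
}

small_spec <- function(seed = 1, n_short = 3, n_long = 2,
                       noise_sd = NULL) {
  phantom_spec(grid_shape = c(36L, 36L, 36L), n_short = n_short,
               n_long = n_long, seed = seed,
               group_models = list(short = small_group_model("short", noise_sd),
                                   long = small_group_model("long", noise_sd)))
}

zero_noise <- function() c(T1c = 0, T2 = 0, MD = 0, FA = 0, CBV = 0, CBF = 0)

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# thin aliases for package internals exercised directly by tests
mann_whitney_auc_test <- function(y, p) habitboost:::mann_whitney_auc(y, p)
derive_seed_test <- function(base, i) habitboost:::derive_seed(base, i)

# Cache expensive fixtures across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_subject <- function(seed = 42, noise_sd = NULL, group = "short") {
  key <- paste0("subj_", group, "_", seed, "_",
                paste(noise_sd, collapse = "-"))
  cached_fixture(key, generate_subject(small_spec(noise_sd = noise_sd),
                                       small_group_model(group, noise_sd),
                                       seed))
}

# Small labelled random feature table for learner/evaluation tests.
toy_table <- function(n = 24, p = 40, informative = 0, d = 1.5, seed = 7) {
  set.seed(seed)
  y <- rep(c("short", "long"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  if (informative > 0)
    x[, seq_len(informative)] <- x[, seq_len(informative)] +
      d * (y == "short")
  vecs <- lapply(seq_len(n), function(i) x[i, ])
  names(vecs) <- sprintf("sub-%03d", seq_len(n))
  assemble_feature_table(vecs, y)
}
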