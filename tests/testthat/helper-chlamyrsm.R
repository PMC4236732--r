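# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

# the default 42-run study-like design (optimization makes it mildly
# expensive, so it is cached)
study_design <- function() {
  if (is.null(.fixtures$design))
    .fixtures$design <- build_design(default_factors(), n_runs = 42,
                                     n_center = 7, seed = 0)
  .fixtures$design
}

# a small two-continuous-factor set for cheap encoding tests
two_factors <- function() {
  fs <- list(factor_spec("x", "continuous", "", 0, 10),
             factor_spec("z", "continuous", "", -5, 5))
  names(fs) <- c("x", "z")
  fs
}

# a plain data.frame design over arbitrary factors (uniform interior points),
# for tests that need geometry the optimizer would not produce
random_design <- function(factors, n, seed) {
  set.seed(seed)
  df <- data.frame(run_id = seq_len(n))
  for (f in factors) {
    df[[f$name]] <- if (f$kind == "ordinal")
      sample(f$levels, n, replace = TRUE)
    else stats::runif(n, f$low, f$high)
  }
  attr(df, "factors") <- factors
  df
}

expect_rel_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
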