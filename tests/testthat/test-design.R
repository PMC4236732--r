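test_that("candidate-effect enumeration matches the combinatorial count", {
  # F + C + F(F-1)/2 for several factor sets, against brute-force counting
  sets <- list(
    list(default_factors()[2], 2),                         # 1 continuous
    list(two_factors(), 5),                                # 2 continuous
    list(default_factors(), 19),                           # the study set
    list(c(default_factors(),
           list(iron = factor_spec("iron", "continuous", "uM", 0, 1))), 26)
  )
  for (s in sets) {
    factors <- s[[1]]
    eff <- enumerate_candidate_effects(factors)
    F_ <- length(factors)
    C_ <- sum(vapply(factors, function(f) f$kind == "continuous", TRUE))
    expect_length(eff, F_ + C_ + F_ * (F_ - 1) / 2)
    expect_equal(length(eff), s[[2]])
    # brute force: every unordered pair appears exactly once
    inters <- Filter(function(tm) tm$form == "interaction", eff)
    pairs <- unname(vapply(inters, function(tm)
      paste(sort(tm$factors), collapse = "|"), ""))
    expect_identical(sort(pairs), unique(sort(pairs)))
  }
})

test_that("enumeration order is deterministic and duplicates are rejected", {
  eff <- enumerate_candidate_effects(default_factors())
  labs <- unname(vapply(eff, `[[`, "", "label"))
  expect_identical(labs[1:5], c("light", "acetate", "co2", "nitrate",
                                "ammonium"))
  expect_identical(labs[6:9], c("light^2", "acetate^2", "nitrate^2",
                                "ammonium^2"))
  expect_identical(labs[10:19], sort(labs[10:19]))
  dup <- list(factor_spec("a", "continuous", "", 0, 1),
              factor_spec("a", "continuous", "", 0, 2))
  expect_error(enumerate_candidate_effects(dup), "duplicate")
})

test_that("the default design has the study's structure", {
  d <- study_design()
  expect_s3_class(d, "doe_design")
  expect_identical(nrow(d), 42L)
  expect_identical(sum(d$is_center), 7L)
  # center points: continuous factors at midpoints, CO2 at both levels
  ctr <- d[d$is_center, ]
  expect_true(all(ctr$light == 100 & ctr$acetate == 0.5 &
                    ctr$nitrate == 10 & ctr$ammonium == 7.5))
  expect_setequal(unique(ctr$co2), c(0.035, 1.5))
  # all values in range, ordinal only at its two levels
  for (f in default_factors()) {
    if (f$kind == "ordinal") expect_true(all(d[[f$name]] %in% f$levels))
    else expect_true(all(d[[f$name]] >= f$low & d[[f$name]] <= f$high))
  }
  # replicate labels: equal iff all factor values equal
  key <- do.call(paste, c(as.data.frame(d)[names(default_factors())],
                          sep = "/"))
  expect_identical(d$replicate_group, match(key, unique(key)))
})

test_that("design generation is seeded and reproducible", {
  fs <- default_factors()[c("light", "acetate", "nitrate")]
  d1 <- build_design(fs, n_runs = 16, n_center = 3, seed = 7)
  d2 <- build_design(fs, n_runs = 16, n_center = 3, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("a full-factorial request with no centers is the pure factorial", {
  d <- build_design(default_factors(), n_runs = 32, n_center = 0)
  expect_identical(nrow(d), 32L)
  expect_identical(sum(d$is_center), 0L)
  for (f in default_factors())
    expect_setequal(unique(d[[f$name]]), c(f$low, f$high))
  expect_identical(max(d$replicate_group), 32L)
})

test_that("too few runs raises an error naming the minimum", {
  expect_error(build_design(default_factors(), n_runs = 20, n_center = 7),
               "27")
})

test_that("main effects of the default design are near-orthogonal", {
  d <- study_design()
  ec <- effect_correlations(d)
  main <- ec$r[names(default_factors()), names(default_factors())]
  expect_lte(max(abs(main[upper.tri(main)])), 0.10)
})

test_that("effect correlations: identity, ordinal artifact, flags", {
  d <- study_design()
  ec <- effect_correlations(d, threshold = 0.50)
  expect_true(all(abs(diag(ec$r) - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(ec$r) <= 1 + 1e-12, na.rm = TRUE))
  # every continuous factor vs its CO2 interaction is flagged near 0.7
  flagged_pairs <- paste(ec$flagged$effect_1, ec$flagged$effect_2)
  for (f in c("light", "acetate", "nitrate", "ammonium")) {
    hit <- grepl(paste0("co2:?", f, "|", f, ":co2"), flagged_pairs) &
      grepl(paste0("\\b", f, "\\b"), flagged_pairs)
    expect_true(any(hit), label = paste("CO2 artifact flagged for", f))
  }
})

test_that("a balanced indicator times a mean-zero column correlates 1/sqrt(2)", {
  fs <- list(x = factor_spec("x", "continuous", "", -1, 1),
             g = factor_spec("g", "ordinal", "", levels = c(0, 1)))
  df <- data.frame(x = c(-1, 1, -1, 1), g = c(0, 0, 1, 1))
  attr(df, "factors") <- fs
  eff <- list(effect_term("linear", "x"),
              effect_term("interaction", c("x", "g")))
  ec <- effect_correlations(df, eff, factors = fs)
  expect_equal(abs(ec$r["x", "x:g"]), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("constant columns are reported undefined rather than NaN", {
  fs <- two_factors()
  df <- data.frame(x = c(1, 2, 3, 4), z = 0)
  attr(df, "factors") <- fs
  eff <- list(effect_term("linear", "x"), effect_term("linear", "z"))
  ec <- effect_correlations(df, eff, factors = fs)
  expect_identical(ec$undefined, "z")
  expect_true(is.na(ec$r["x", "z"]))
  expect_false(any(is.nan(ec$r)))
})

test_that("designs survive a CSV round trip", {
  d <- study_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  expect_identical(readLines(path, n = 1),
                   "run_id,light,acetate,co2,nitrate,ammonium")
  d2 <- read_design(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})
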