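make_problem <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind("(Intercept)" = 1,
             matrix(rnorm(n * k), n, k,
                    dimnames = list(NULL, paste0("x", seq_len(k)))))
  list(X = X, y = rnorm(n))
}

test_that("second-order columns vanish at a center row when means equal midpoints", {
  fs <- two_factors()
  # symmetric design: means equal midpoints (5, 0); last row is the center
  df <- data.frame(x = c(0, 10, 0, 10, 5), z = c(-5, -5, 5, 5, 0))
  spec <- model_spec("y", list(effect_term("quadratic", "x"),
                               effect_term("interaction", c("x", "z"))))
  mm <- build_model_matrix(df, spec, factors = fs)
  expect_equal(unname(mm$centering), c(5, 0), tolerance = 1e-12)
  expect_equal(unname(mm$X[5, -1]), c(0, 0), tolerance = 1e-12)
})

test_that("centering constants follow the rows actually fitted", {
  fs <- two_factors()
  df <- data.frame(x = c(1, 2, 3, 4, 10), z = c(0, 1, 2, 3, 4))
  spec <- model_spec("y", list(effect_term("quadratic", "x")))
  mm_all <- build_model_matrix(df, spec, factors = fs)
  mm_sub <- build_model_matrix(df, spec, fit_rows = 1:4, factors = fs)
  expect_equal(mm_all$centering[["x"]], 4)
  expect_equal(mm_sub$centering[["x"]], 2.5)
  # explicit constants take precedence
  spec2 <- model_spec("y", spec$terms, centering = c(x = 7))
  expect_equal(build_model_matrix(df, spec2, factors = fs)$centering[["x"]], 7)
})

test_that("OLS coefficients equal the explicit normal-equations oracle", {
  for (seed in 1:10) {
    k <- sample(1:5, 1)
    p <- make_problem(30, k, seed)
    fit <- fit_ols(p$X, p$y)
    oracle <- solve(t(p$X) %*% p$X, t(p$X) %*% p$y)  # brute-force inversion
    expect_rel_equal(c(fit$b0, fit$coefficients), as.numeric(oracle), 1e-8)
  }
})

test_that("degenerate fits behave: exact fit, intercept-only, singularity", {
  x <- 1:10
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_ols(X, 2 + 3 * x)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)

  y <- rnorm(10)
  fit0 <- fit_ols(matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(fit0$b0, mean(y))
  expect_equal(fit0$ss[["model"]], 0, tolerance = 1e-9)

  Xs <- cbind("(Intercept)" = 1, a = x, b = 2 * x)
  expect_error(fit_ols(Xs, y), "aliased.*b|singular")
})

test_that("sum-of-squares and degrees-of-freedom identities hold on random fits", {
  d <- study_design()
  spec <- model_spec("y", list(effect_term("linear", "acetate"),
                               effect_term("linear", "light"),
                               effect_term("quadratic", "acetate"),
                               effect_term("interaction",
                                           c("acetate", "ammonium"))))
  mm <- build_model_matrix(as.data.frame(d), spec,
                           factors = default_factors())
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(42, 10, 3)
    fit <- fit_ols(mm, y, design = d)
    expect_rel_equal(fit$ss[["total"]],
                     fit$ss[["model"]] + fit$ss[["error"]], 1e-8)
    expect_identical(fit$df[["total"]], fit$df[["model"]] + fit$df[["error"]])
    expect_lte(fit$mae_f, fit$rmse_f + 1e-12)
    expect_lte(fit$r2_adj, fit$r2)
    expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
    expect_rel_equal(fit$ss[["error"]],
                     fit$lof$ss_pure + fit$lof$ss_lof, 1e-8)
    for (p in c(fit$p_whole, fit$lof$p))
      if (!is.na(p)) { expect_gte(p, 0); expect_lte(p, 1) }
  }
})

test_that("the fit is invariant to the centering parameterization", {
  d <- as.data.frame(study_design())
  terms <- list(effect_term("linear", "acetate"),
                effect_term("quadratic", "acetate"),
                effect_term("interaction", c("acetate", "ammonium")),
                effect_term("linear", "ammonium"))
  set.seed(42)
  y <- rnorm(42, 5, 2)
  f1 <- fit_ols(build_model_matrix(d, model_spec("y", terms),
                                   factors = default_factors()), y)
  f2 <- fit_ols(build_model_matrix(d, model_spec("y", terms,
                                                 centering = c(acetate = 0,
                                                               ammonium = 0)),
                                   factors = default_factors()), y)
  expect_rel_equal(f1$fitted, f2$fitted, 1e-8)
  expect_rel_equal(f1$ss, f2$ss, 1e-8)
})

test_that("whole-model F satisfies its algebraic identities", {
  p <- make_problem(25, 1, 3)
  fit <- fit_ols(p$X, p$y)
  # single predictor: F equals the squared t statistic
  lmfit <- lm(p$y ~ p$X[, 2])
  tval <- summary(lmfit)$coefficients[2, "t value"]
  expect_equal(fit$f_whole, tval^2, tolerance = 1e-8)
  # F = (R2/k) / ((1-R2)/(n-k-1)) on a larger fit
  p2 <- make_problem(30, 4, 4)
  fit2 <- fit_ols(p2$X, p2$y)
  expect_equal(fit2$f_whole,
               (fit2$r2 / 4) / ((1 - fit2$r2) / (30 - 4 - 1)),
               tolerance = 1e-10)
})

test_that("effect ANOVA: single-term equivalence and orthogonal decomposition", {
  p <- make_problem(25, 1, 5)
  fit <- fit_ols(p$X, p$y)
  ea <- effect_anova(fit = fit, term = "x1")
  expect_equal(ea$p, fit$p_whole, tolerance = 1e-10)
  # mutually orthogonal columns: effect SS sum to the model SS
  n <- 16
  X <- cbind("(Intercept)" = 1,
             a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
             c = rep(c(-1, 1), each = 8))
  set.seed(6)
  y <- rnorm(n)
  fit <- fit_ols(X, y)
  ss <- sum(vapply(c("a", "b", "c"),
                   function(t) effect_anova(fit = fit, term = t)$ss, 0))
  expect_rel_equal(ss, fit$ss[["model"]], 1e-8)
})

test_that("lack of fit is unavailable without replicates and exact with them", {
  fs <- two_factors()
  # all runs distinct
  df <- data.frame(x = 1:8, z = seq(-4, 3))
  spec <- model_spec("y", list(effect_term("linear", "x")))
  mm <- build_model_matrix(df, spec, factors = fs)
  set.seed(7)
  y <- rnorm(8)
  fit <- fit_ols(mm, y)
  expect_false(lack_of_fit(df, spec, fit)$available)
  # replicated rows: pure error equals the within-group oracle
  df2 <- data.frame(x = c(1, 1, 2, 2, 3, 3, 4, 4), z = 0)
  mm2 <- build_model_matrix(df2, spec, factors = fs)
  y2 <- c(1.0, 1.4, 2.1, 1.9, 3.3, 2.9, 3.8, 4.4)
  fit2 <- fit_ols(mm2, y2)
  lof <- lack_of_fit(df2, spec, fit2)
  pure_oracle <- sum(tapply(y2, df2$x, function(v) sum((v - mean(v))^2)))
  expect_equal(lof$ss_pure, pure_oracle, tolerance = 1e-12)
  expect_equal(lof$ss_lof, fit2$ss[["error"]] - pure_oracle,
               tolerance = 1e-12)
  expect_identical(lof$df_pure, 4L)
  expect_identical(lof$df_lof, 4L - 1L - 1L + 0L)
  expect_true(lof$available)
})

test_that("beta-weights: Pearson identity, scale invariance, direct formula", {
  set.seed(8)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  X <- cbind("(Intercept)" = 1, x = x)
  b <- beta_weights(X, y)
  expect_equal(unname(b["x"]), cor(x, y), tolerance = 1e-10)
  # rescaling a column leaves beta unchanged
  X2 <- cbind("(Intercept)" = 1, x = 1000 * x)
  expect_equal(unname(beta_weights(X2, y)), unname(b), tolerance = 1e-10)
  # direct formula on orthogonal columns: beta_j = b_j sd(x_j) / sd(y)
  X3 <- cbind("(Intercept)" = 1,
              a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4))
  y3 <- rnorm(16)
  fit3 <- fit_ols(X3, y3)
  b3 <- beta_weights(X3, y3)
  expect_equal(unname(b3),
               unname(fit3$coefficients *
                        apply(X3[, -1], 2, sd) / sd(y3)),
               tolerance = 1e-10)
  expect_error(beta_weights(cbind("(Intercept)" = 1, k = rep(2, 16)), y3),
               "constant")
})

test_that("AICc matches a hand-computed oracle and dominates AIC", {
  # 5 points, 1 predictor, worked by hand from the definition
  x <- c(1, 2, 3, 4, 5); y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  fit <- fit_ols(cbind("(Intercept)" = 1, x = x), y)
  sse <- sum(fit$residuals^2)
  p <- 1 + 2
  aic_hand <- 5 * log(2 * pi * sse / 5) + 5 + 2 * p
  aicc_hand <- aic_hand + 2 * p * (p + 1) / (5 - p - 1)
  expect_equal(aicc(fit), aicc_hand, tolerance = 1e-10)
  # AICc > AIC whenever the penalty denominator is positive
  for (seed in 1:5) {
    pr <- make_problem(20, 3, 100 + seed)
    f <- fit_ols(pr$X, pr$y)
    sse <- f$ss[["error"]]
    aic <- 20 * log(2 * pi * sse / 20) + 20 + 2 * 5
    expect_gt(aicc(f), aic)
  }
  # adding a pure-noise column raises the median AICc
  set.seed(11)
  deltas <- replicate(200, {
    X <- cbind("(Intercept)" = 1, x = rnorm(20))
    y <- X[, 2] + rnorm(20)
    X2 <- cbind(X, junk = rnorm(20))
    aicc(fit_ols(X2, y)) - aicc(fit_ols(X, y))
  })
  expect_gt(median(deltas), 0)
})

test_that("AICc returns +Inf with a warning when the penalty blows up", {
  p <- make_problem(6, 3, 12)   # n - (k+2) - 1 = 0
  expect_warning(val <- fit_ols(p$X, p$y)$aicc, "denominator")
  expect_identical(val, Inf)
})

test_that("fit metrics: perfect fit and the standardized percentage", {
  x <- 1:12
  fit <- fit_ols(cbind("(Intercept)" = 1, x = x), 3 * x + 1)
  m <- fit_metrics(fit)
  expect_equal(m$rmse_f, 0, tolerance = 1e-9)
  expect_equal(m$mae_f, 0, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  set.seed(13)
  y <- rnorm(12, 10, 2)
  fit2 <- fit_ols(cbind("(Intercept)" = 1, x = x), y)
  m2 <- fit_metrics(fit2)
  expect_equal(m2$average_scale, mean(y) - min(y), tolerance = 1e-12)
  expect_equal(m2$rmse_f_pct, 100 * m2$rmse_f / m2$average_scale,
               tolerance = 1e-12)
  expect_identical(m2$rmse_f_pct_rounded, round(m2$rmse_f_pct))
})

test_that("fitted models predict new combinations consistently", {
  d <- study_design()
  spec <- model_spec("y", list(effect_term("linear", "acetate"),
                               effect_term("quadratic", "acetate")))
  set.seed(14)
  y <- rnorm(42, 8, 2)
  fit <- fit_ols(build_model_matrix(d, spec), y, design = d)
  nd <- data.frame(acetate = c(0.1, 0.9))
  manual <- fit$b0 + fit$coefficients[["acetate"]] * nd$acetate +
    fit$coefficients[["acetate^2"]] * (nd$acetate -
                                         fit$centering[["acetate"]])^2
  expect_equal(predict(fit, nd, factors = default_factors()), manual,
               tolerance = 1e-12)
})
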