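test_that("the registry holds the six response models at printed precision", {
  pm <- published_models()
  expect_named(pm, c("CR", "MA_CYT", "MA_ALT", "PHIPSII800", "NPQ800",
                     "P800"))
  expect_equal(pm$CR$intercept, 6.67)
  expect_equal(pm$CR$linear[["acetate"]], 9.01)
  expect_equal(pm$CR$interaction[[1]]$coef, -0.566)
  expect_equal(pm$CR$interaction[[1]]$center_a, 0.463)
  expect_equal(pm$CR$interaction[[1]]$center_b, 7.69)
  expect_equal(pm$MA_ALT$quadratic[[1]]$coef, -13.5)
  expect_equal(pm$MA_ALT$quadratic[[1]]$center, 0.488)
  expect_equal(pm$NPQ800$quadratic[[1]]$coef, -0.00109)
  expect_equal(pm$P800$quadratic[[2]]$coef, -0.608)
  expect_equal(pm$PHIPSII800$linear[["light"]], 0.00103)
})

test_that("model predictions match hand evaluations of the equations", {
  pm <- published_models()
  # intercept alone when light = 0
  expect_equal(predict(pm$PHIPSII800, data.frame(light = 0)), 0.308)
  # first measured validation point, worked by hand
  expect_equal(predict(pm$CR, data.frame(acetate = 0.58, light = 61,
                                         ammonium = 10)),
               9.04, tolerance = 0.01 / 9)
  # centered terms vanish at the fit-sample means
  expect_equal(predict(pm$MA_ALT, data.frame(acetate = 0.488, light = 107,
                                             ammonium = 7.32)),
               12.80, tolerance = 0.01 / 12.8)
  expect_error(predict(pm$CR, data.frame(acetate = 0.5, light = 100)),
               "ammonium")
  expect_warning(predict(pm$CR, data.frame(acetate = 5, light = 100,
                                           ammonium = 5)),
                 "range")
})

test_that("profiles: linear slope, quadratic optima at the study values", {
  pm <- published_models()
  # a purely linear profile is a straight line with the printed slope
  pc <- profile_curve(pm$MA_CYT, "acetate", grid_size = 11)
  slopes <- diff(pc$curve$y) / diff(pc$curve$x)
  expect_equal(unname(slopes), rep(7.58, 10), tolerance = 1e-10)
  expect_null(pc$vertex)
  expect_null(profile_curve(pm$PHIPSII800, "light")$vertex)
  # quadratic optima, rounded as printed
  v <- profile_curve(pm$MA_ALT, "acetate")$vertex
  expect_equal(round(v$location, 3), 0.623)
  expect_identical(v$curvature, "concave")
  v <- profile_curve(pm$P800, "nitrate")$vertex
  expect_equal(round(v$location, 1), 10.5)
  expect_identical(v$curvature, "concave")
  v <- profile_curve(pm$P800, "acetate")$vertex
  expect_equal(round(v$location, 3), 0.497)
  expect_identical(v$curvature, "convex")
  v <- profile_curve(pm$NPQ800, "nitrate")$vertex
  expect_equal(round(v$location, 1), 9.1)
  expect_equal(v$location, 9.09, tolerance = 0.005 / 9)
})

test_that("vertex closed form: symmetry, offset invariance, grid oracle", {
  expect_equal(vertex_location(-2, 0, 3.5)$location, 3.5)
  expect_identical(vertex_location(1, 0, 0)$curvature, "convex")
  expect_error(vertex_location(0, 1, 0), "zero")
  pm <- published_models()
  # adding a constant to the model leaves every vertex where it was
  shifted <- pm$MA_ALT; shifted$intercept <- shifted$intercept + 100
  expect_equal(profile_curve(shifted, "acetate")$vertex$location,
               profile_curve(pm$MA_ALT, "acetate")$vertex$location)
  # closed form agrees with a 1e5-point grid search to one grid step
  for (case in list(c("MA_ALT", "acetate"), c("P800", "nitrate"),
                    c("P800", "acetate"), c("NPQ800", "nitrate"))) {
    pc <- profile_curve(pm[[case[1]]], case[2], grid_size = 100001)
    opt <- if (pc$vertex$curvature == "concave") which.max(pc$curve$y)
           else which.min(pc$curve$y)
    step <- diff(pc$curve$x[1:2])
    expect_lt(abs(pc$curve$x[opt] - pc$vertex$location), step + 1e-12)
  }
})

test_that("interaction slices shift the optimum as printed", {
  pm <- published_models()
  sl <- interaction_slice(pm$MA_ALT, "acetate", "ammonium")
  expect_equal(round(sl[["ammonium=0"]]$vertex$location, 3), 0.727)
  expect_equal(round(sl[["ammonium=15"]]$vertex$location, 3), 0.514)
  expect_error(interaction_slice(pm$MA_ALT, "acetate", "nitrate"),
               "no interaction")
  # zero interaction coefficient: the two slices differ by a constant only
  m0 <- published_model("Y", 1, linear = c(x = 2, z = 3),
                        interaction = list(list(a = "x", b = "z", coef = 0,
                                                center_a = 0, center_b = 0)),
                        means = c(x = 0, z = 0))
  fs <- two_factors()
  sl0 <- interaction_slice(m0, "x", "z", at = c(-5, 5), factors = fs)
  gap <- sl0[[2]]$curve$y - sl0[[1]]$curve$y
  expect_equal(max(gap) - min(gap), 0, tolerance = 1e-12)
})

test_that("noiseless refits recover every published coefficient", {
  d <- study_design()
  pm <- published_models()
  for (m in pm) {
    spec <- as_model_spec(m)
    y <- predict(m, as.data.frame(d))
    fit <- fit_ols(build_model_matrix(d, spec), y)
    want <- c(m$intercept, m$linear,
              vapply(m$quadratic, `[[`, 0, "coef"),
              vapply(m$interaction, `[[`, 0, "coef"))
    expect_rel_equal(unname(c(fit$b0, fit$coefficients)), unname(want), 1e-6)
  }
})

test_that("fitted models convert to the structured form and back", {
  d <- study_design()
  spec <- model_spec("Y", list(effect_term("linear", "acetate"),
                               effect_term("linear", "co2"),
                               effect_term("quadratic", "acetate"),
                               effect_term("interaction", c("co2", "light")),
                               effect_term("linear", "light")))
  set.seed(33)
  y <- rnorm(42, 10, 2)
  fit <- fit_ols(build_model_matrix(d, spec), y, design = d)
  pmod <- as_published_model(fit, d)
  # the structured form predicts identically to the fit
  nd <- as.data.frame(d)[c(1, 10, 20, 40), ]
  expect_equal(predict(pmod, nd), predict(fit, nd), tolerance = 1e-10)
  # and its spec rebuilds the same centered terms
  spec2 <- as_model_spec(pmod)
  labs <- sort(vapply(spec2$terms, `[[`, "", "label"))
  expect_setequal(labs, vapply(spec$terms, `[[`, "", "label"))
})
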