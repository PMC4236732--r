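#' Construct a structured response-surface model
#'
#' A centered second-order polynomial in the environmental factors:
#' intercept + linear terms (uncentered) + quadratic terms
#' \code{coef * (x - center)^2} + interaction terms
#' \code{coef * (x_a - center_a) * (x_b - center_b)}.
#'
#' @param response Response name.
#' @param intercept Intercept (response units).
#' @param linear Named numeric vector of linear coefficients.
#' @param quadratic List of \code{list(factor, coef, center)}.
#' @param interaction List of
#'   \code{list(a, b, coef, center_a, center_b)} for two continuous factors;
#'   an interaction with a two-level ordinal factor instead carries
#'   \code{list(a, b, coef, center_b, ordinal = TRUE, high_level)} and
#'   contributes \code{coef * indicator(x_a == high_level) * (x_b -
#'   center_b)}.
#' @param ordinal Named list of indicator terms for two-level ordinal
#'   factors: \code{factor -> list(coef, high_level)}, contributing
#'   \code{coef * indicator(x == high_level)}.
#' @param means Named numeric vector of fit-sample factor means, used as the
#'   default fixed values when profiling one factor (for an ordinal factor,
#'   the level to fix it at).
#' @param n_fit Number of observations the model was fitted on.
#' @return An object of class \code{published_model}.
#' @export
published_model <- function(response, intercept, linear = numeric(),
                            quadratic = list(), interaction = list(),
                            ordinal = list(), means = numeric(),
                            n_fit = NA_integer_) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(linear)) stopifnot(!is.null(names(linear)))
  if (length(ordinal)) stopifnot(!is.null(names(ordinal)))
  structure(list(response = response, intercept = intercept,
                 linear = linear, quadratic = quadratic,
                 interaction = interaction, ordinal = ordinal,
                 means = means, n_fit = n_fit),
            class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  parts <- sprintf("%.4g", x$intercept)
  for (f in names(x$linear))
    parts <- c(parts, sprintf("%+.4g*%s", x$linear[[f]], f))
  for (q in x$quadratic)
    parts <- c(parts, sprintf("%+.4g*(%s-%.4g)^2", q$coef, q$factor, q$center))
  for (it in x$interaction)
    parts <- c(parts, if (isTRUE(it$ordinal))
      sprintf("%+.4g*1[%s=%.4g]*(%s-%.4g)", it$coef, it$a, it$high_level,
              it$b, it$center_b)
      else sprintf("%+.4g*(%s-%.4g)*(%s-%.4g)", it$coef,
                   it$a, it$center_a, it$b, it$center_b))
  for (f in names(x$ordinal))
    parts <- c(parts, sprintf("%+.4g*1[%s=%.4g]", x$ordinal[[f]]$coef, f,
                              x$ordinal[[f]]$high_level))
  cat(sprintf("<published_model> %s = %s\n", x$response,
              paste(parts, collapse = " ")))
  invisible(x)
}

model_factors <- function(model) {
  unique(c(names(model$linear), names(model$ordinal),
           vapply(model$quadratic, `[[`, "", "factor"),
           unlist(lapply(model$interaction, function(it) c(it$a, it$b)))))
}

#' The six published second-round response models
#'
#' Loads the packaged registry of the six response equations (dark
#' respiration CR, cytochromial and alternative-pathway maximal activities
#' MA_CYT and MA_ALT, PSII quantum yield PHIPSII800, non-photochemical
#' quenching NPQ800 and gross photosynthesis P800) with their coefficients
#' at full printed precision.
#'
#' @param path Registry file; defaults to the packaged
#'   \code{published_models.json}.
#' @return Named list of \code{\link{published_model}}s.
#' @export
published_models <- function(path = system.file("extdata",
                                                "published_models.json",
                                                package = "chlamyRSM")) {
  reg <- jsonlite::read_json(path)
  models <- lapply(reg$models, function(m)
    published_model(
      response = m$response, intercept = m$intercept,
      linear = unlist(m$linear),
      quadratic = lapply(m$quadratic, function(q)
        list(factor = q$factor, coef = q$coef, center = q$center)),
      interaction = lapply(m$interaction, function(it)
        list(a = it$a, b = it$b, coef = it$coef,
             center_a = it$center_a, center_b = it$center_b)),
      means = unlist(m$means), n_fit = m$n_fit))
  stats::setNames(models, vapply(models, `[[`, "", "response"))
}

#' Evaluate a published model at factor combinations
#'
#' @param object A \code{\link{published_model}}.
#' @param newdata Data.frame (or named list/vector) of factor values; every
#'   factor appearing in the model must be present. Values outside the study
#'   working ranges trigger a warning, not an error.
#' @param factors Factor list used for the range check.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.published_model <- function(object, newdata,
                                    factors = default_factors(), ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  need <- model_factors(object)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("missing factor value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in intersect(need, factor_names(factors))) {
    fs <- factors[[match(f, factor_names(factors))]]
    bad <- if (fs$kind == "ordinal") !newdata[[f]] %in% fs$levels
           else newdata[[f]] < fs$low | newdata[[f]] > fs$high
    if (any(bad, na.rm = TRUE))
      warning("values of '", f, "' outside the working ",
              if (fs$kind == "ordinal") "level set" else
                sprintf("range [%g, %g]", fs$low, fs$high), call. = FALSE)
  }
  y <- rep(object$intercept, nrow(newdata))
  for (f in names(object$linear)) y <- y + object$linear[[f]] * newdata[[f]]
  for (f in names(object$ordinal))
    y <- y + object$ordinal[[f]]$coef *
      (newdata[[f]] == object$ordinal[[f]]$high_level)
  for (q in object$quadratic)
    y <- y + q$coef * (newdata[[q$factor]] - q$center)^2
  for (it in object$interaction) {
    y <- y + if (isTRUE(it$ordinal))
      it$coef * (newdata[[it$a]] == it$high_level) *
        (newdata[[it$b]] - it$center_b)
    else it$coef * (newdata[[it$a]] - it$center_a) *
      (newdata[[it$b]] - it$center_b)
  }
  y
}

#' Closed-form vertex of a quadratic profile
#'
#' For a profile \code{y = b_eff * x + a * (x - center)^2 + const} the
#' stationary point is \code{center - b_eff / (2a)}: the maximum of a
#' concave (\code{a < 0}) or the minimum of a convex (\code{a > 0}) profile.
#' \code{b_eff} is the effective linear coefficient in the varying factor
#' after substituting the fixed values of the other factors into any
#' interaction terms.
#'
#' @param a Quadratic coefficient; must be nonzero.
#' @param b_eff Effective linear coefficient.
#' @param center Centering constant of the quadratic term.
#' @return List with \code{location}, \code{curvature}
#'   (\code{"concave"} or \code{"convex"}).
#' @export
vertex_location <- function(a, b_eff, center) {
  if (a == 0) stop("no vertex: quadratic coefficient is zero", call. = FALSE)
  list(location = center - b_eff / (2 * a),
       curvature = if (a < 0) "concave" else "convex")
}

# derivative pieces of a model profile in `factor` at fixed other values
profile_quadratic <- function(model, factor, fixed) {
  a <- 0; center <- NA_real_
  for (q in model$quadratic) if (q$factor == factor) {
    a <- q$coef; center <- q$center
  }
  b_eff <- if (factor %in% names(model$linear)) model$linear[[factor]] else 0
  for (it in model$interaction) {
    other <- if (it$a == factor) it$b else if (it$b == factor) it$a else NA
    if (is.na(other)) next
    b_eff <- b_eff + if (isTRUE(it$ordinal)) {
      # ordinal partner fixed at a level: its indicator scales the slope;
      # (profiles over the ordinal factor itself have no derivative)
      if (it$b == factor) it$coef * (fixed[[other]] == it$high_level) else 0
    } else {
      oc <- if (it$a == factor) it$center_b else it$center_a
      it$coef * (fixed[[other]] - oc)
    }
  }
  list(a = a, b_eff = b_eff, center = center)
}

#' Simulate the profile of one factor, the others held fixed
#'
#' Evaluates the model on a uniform grid over the factor's working range
#' with every other model factor fixed (by default at the model's
#' fit-sample means, the values the study used for its profile
#' simulations). When the factor carries a quadratic term the profile's
#' vertex (optimum location, value, curvature) is reported.
#'
#' @param model A \code{\link{published_model}}.
#' @param factor Name of the varying factor.
#' @param grid_size Number of grid points.
#' @param fixed Named values for the non-varying factors; defaults to
#'   \code{model$means}.
#' @param factors Factor list providing the grid range.
#' @return An object of class \code{profile_curve}: data.frame
#'   \code{curve} (grid value, prediction), \code{fixed} values, and
#'   \code{vertex} (or \code{NULL} for a purely linear profile).
#' @export
profile_curve <- function(model, factor, grid_size = 201,
                          fixed = NULL, factors = default_factors()) {
  need <- model_factors(model)
  if (!(factor %in% need))
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  if (is.null(fixed)) fixed <- model$means
  fixed <- fixed[setdiff(names(fixed), factor)]
  miss <- setdiff(setdiff(need, factor), names(fixed))
  if (length(miss))
    stop("no fixed value for factor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.na(match(factor, factor_names(factors))))
    stop("unknown factor '", factor, "'", call. = FALSE)
  fs <- factors[[match(factor, factor_names(factors))]]
  grid <- if (fs$kind == "ordinal") fs$levels
          else seq(fs$low, fs$high, length.out = grid_size)
  nd <- as.data.frame(c(stats::setNames(list(grid), factor),
                        as.list(fixed)))
  pred <- predict(model, nd, factors = factors)
  pq <- profile_quadratic(model, factor, as.list(fixed))
  vert <- NULL
  if (pq$a != 0) {
    vert <- vertex_location(pq$a, pq$b_eff, pq$center)
    vert$value <- predict(model, as.data.frame(c(
      stats::setNames(list(vert$location), factor), as.list(fixed))),
      factors = factors)
  }
  structure(list(response = model$response, factor = factor,
                 curve = data.frame(x = grid, y = pred),
                 fixed = fixed, vertex = vert),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> %s vs %s (%d points; fixed: %s)\n",
              x$response, x$factor, nrow(x$curve),
              paste(sprintf("%s = %.4g", names(x$fixed), x$fixed),
                    collapse = ", ")))
  if (!is.null(x$vertex))
    cat(sprintf("  vertex: %s at %s = %.4g (value %.4g)\n",
                x$vertex$curvature, x$factor, x$vertex$location,
                x$vertex$value))
  invisible(x)
}

#' Interaction slices: one factor profiled at two values of its partner
#'
#' Profiles \code{factor} with \code{conditioning_factor} fixed successively
#' at two values (by default the minimum and maximum of its working range),
#' all remaining factors at the model's fit-sample means. The two factors
#' must share an interaction term in the model.
#'
#' @param model A \code{\link{published_model}}.
#' @param factor Varying factor.
#' @param conditioning_factor Partner factor fixed per slice.
#' @param at Numeric length-2 vector of conditioning values.
#' @param grid_size Number of grid points per slice.
#' @param factors Factor list providing ranges.
#' @return List of two \code{\link{profile_curve}}s, named by the
#'   conditioning values.
#' @export
interaction_slice <- function(model, factor, conditioning_factor, at = NULL,
                              grid_size = 201, factors = default_factors()) {
  shared <- any(vapply(model$interaction, function(it)
    setequal(c(it$a, it$b), c(factor, conditioning_factor)), TRUE))
  if (!shared)
    stop("'", factor, "' and '", conditioning_factor,
         "' share no interaction term in the model", call. = FALSE)
  if (is.null(at)) {
    fs <- factors[[match(conditioning_factor, factor_names(factors))]]
    at <- c(fs$low, fs$high)
  }
  stopifnot(length(at) == 2L)
  out <- lapply(at, function(v) {
    fixed <- model$means
    fixed[conditioning_factor] <- v
    profile_curve(model, factor, grid_size = grid_size, fixed = fixed,
                  factors = factors)
  })
  stats::setNames(out, paste0(conditioning_factor, "=", at))
}

#' Convert between fitted and structured model representations
#'
#' \code{as_published_model} turns a fitted \code{doe_fit} (with its
#' specification and realized centering) into the structured polynomial
#' form, recording the fit-sample factor means so it can be profiled like a
#' published model. \code{as_model_spec} does the reverse: it extracts the
#' term list and centering constants of a \code{published_model} so the
#' model can be refitted on data.
#'
#' @param fit A \code{doe_fit} fitted from a \code{model_spec}.
#' @param design The design the fit used (for the fit-sample means).
#' @param factors Factor list.
#' @return A \code{\link{published_model}} or a \code{\link{model_spec}}.
#' @export
as_published_model <- function(fit, design, factors = attr(design, "factors")) {
  spec <- fit$spec
  if (is.null(spec)) stop("fit carries no model specification", call. = FALSE)
  df <- as.data.frame(design)[fit$fit_rows, , drop = FALSE]
  kinds <- vapply(factors, `[[`, "", "kind")
  lin <- numeric(); quad <- list(); inter <- list()
  for (tm in spec$terms) {
    b <- fit$coefficients[[tm$label]]
    if (tm$form == "linear") {
      lin[tm$factors] <- b
    } else if (tm$form == "quadratic") {
      quad[[length(quad) + 1L]] <- list(factor = tm$factors, coef = b,
                                        center = fit$centering[[tm$factors]])
    } else {
      fs <- tm$factors
      ord <- kinds[match(fs, factor_names(factors))] == "ordinal"
      if (any(ord)) {
        of <- fs[ord]; cf <- fs[!ord]
        inter[[length(inter) + 1L]] <- list(
          a = of, b = cf, coef = b, center_b = fit$centering[[cf]],
          ordinal = TRUE,
          high_level = factors[[match(of, factor_names(factors))]]$levels[2])
      } else {
        inter[[length(inter) + 1L]] <- list(
          a = fs[1], b = fs[2], coef = b,
          center_a = fit$centering[[fs[1]]],
          center_b = fit$centering[[fs[2]]])
      }
    }
  }
  ordl <- list()
  for (tm in spec$terms) {
    if (tm$form == "linear" &&
        kinds[match(tm$factors, factor_names(factors))] == "ordinal") {
      ordl[[tm$factors]] <- list(
        coef = unname(lin[tm$factors]),
        high_level = factors[[match(tm$factors,
                                    factor_names(factors))]]$levels[2])
      lin <- lin[setdiff(names(lin), tm$factors)]
    }
  }
  used <- unique(unlist(lapply(spec$terms, `[[`, "factors")))
  means <- numeric()
  for (f in used) {
    j <- match(f, factor_names(factors))
    means[f] <- if (kinds[j] == "continuous") mean(df[[f]])
    else {  # ordinal: fix profiles at the level most frequent in the sample
      lv <- factors[[j]]$levels
      if (sum(df[[f]] == lv[2]) > sum(df[[f]] == lv[1])) lv[2] else lv[1]
    }
  }
  published_model(spec$response, fit$b0, lin, quad, inter, ordl, means,
                  n_fit = fit$n)
}

#' @rdname as_published_model
#' @param model A \code{\link{published_model}}.
#' @export
as_model_spec <- function(model) {
  terms <- list(); centering <- numeric()
  for (f in names(model$linear))
    terms <- c(terms, list(effect_term("linear", f)))
  for (f in names(model$ordinal))
    terms <- c(terms, list(effect_term("linear", f)))
  for (q in model$quadratic) {
    terms <- c(terms, list(effect_term("quadratic", q$factor)))
    centering[q$factor] <- q$center
  }
  for (it in model$interaction) {
    terms <- c(terms, list(effect_term("interaction", c(it$a, it$b))))
    if (!isTRUE(it$ordinal)) centering[it$a] <- it$center_a
    centering[it$b] <- it$center_b
  }
  model_spec(model$response, terms,
             centering = if (length(centering)) centering else NULL)
}
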