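#' Ordinary least squares with the full diagnostic set
#'
#' Fits the encoded model by QR least squares and assembles the whole
#' diagnostic battery used throughout the analysis: the SS decomposition
#' (total = model + error, error = pure + lack-of-fit when replicates
#' exist), R2 and adjusted R2 (1 - error MS / total MS), fitting errors
#' RMSE_F and MAE_F with RMSE_F also expressed as a percentage of the
#' average scale (mean minus minimum of the fitted response values), AICc,
#' the whole-model F test, and per-term beta-weights and deprivation ANOVA
#' p-values. Coefficients are reported in the centered parameterization, so
#' they print exactly like the published equations.
#'
#' @param mm A \code{\link{build_model_matrix}} result (or a plain numeric
#'   matrix whose first column is the intercept).
#' @param y Numeric response vector aligned with the matrix rows.
#' @param diagnostics If \code{FALSE}, skip the per-term beta-weights and
#'   effect ANOVA (used internally where only the fit summary is needed).
#' @param design,lof Optional design (a \code{doe_design} or data.frame of
#'   factor values on the fit rows) enabling the lack-of-fit decomposition.
#' @return An object of class \code{doe_fit}.
#' @export
fit_ols <- function(mm, y, diagnostics = TRUE, design = NULL, lof = TRUE) {
  if (is.matrix(mm)) mm <- list(X = mm, centering = NULL, spec = NULL,
                                fit_rows = seq_len(nrow(mm)))
  X <- mm$X
  stopifnot(is.numeric(y), length(y) == nrow(X), !anyNA(y))
  n <- nrow(X); k <- ncol(X) - 1L
  if (n <= k + 1L)
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  z <- stats::lm.fit(X, y)
  if (z$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(z$coefficients)]
    stop("singular system; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- z$coefficients
  e <- as.numeric(z$residuals)
  fitted <- as.numeric(z$fitted.values)
  ss_total <- sum((y - mean(y))^2)
  ss_error <- sum(e^2)
  ss_model <- ss_total - ss_error
  df_model <- k; df_error <- n - k - 1L; df_total <- n - 1L
  ms_model <- if (df_model > 0) ss_model / df_model else NA_real_
  ms_error <- ss_error / df_error
  ms_total <- ss_total / df_total
  r2 <- if (ss_total > 0) ss_model / ss_total else NA_real_
  r2_adj <- if (ss_total > 0) 1 - ms_error / ms_total else NA_real_
  avg_scale <- mean(y) - min(y)
  rmse_f <- sqrt(ms_error)
  mae_f <- mean(abs(e))

  fit <- structure(list(
    b0 = unname(coefs[1]), coefficients = coefs[-1],
    residuals = e, fitted = fitted, y = y,
    n = n, k = k,
    ss = c(total = ss_total, model = ss_model, error = ss_error),
    df = c(total = df_total, model = df_model, error = df_error),
    ms = c(total = ms_total, model = ms_model, error = ms_error),
    r2 = r2, r2_adj = r2_adj,
    rmse_f = rmse_f, mae_f = mae_f,
    average_scale = avg_scale,
    rmse_f_pct = if (avg_scale > 0) 100 * rmse_f / avg_scale else NA_real_,
    aicc = aicc_value(n, k, ss_error),
    X = X, centering = mm$centering, spec = mm$spec,
    fit_rows = mm$fit_rows
  ), class = "doe_fit")

  wm <- whole_model_anova(fit)
  fit$f_whole <- wm$F; fit$p_whole <- wm$p

  # numerical identities asserted on every fit
  stopifnot(abs(ss_total - (ss_model + ss_error)) <=
              1e-8 * max(ss_total, 1),
            df_total == df_model + df_error,
            mae_f <= rmse_f * sqrt(n / max(df_error, 1)) + 1e-12)

  if (diagnostics && k > 0) {
    fit$beta <- beta_weights(mm, y, fit)
    ea <- effect_anova_all(fit)
    fit$effect_ss <- ea$ss; fit$effect_f <- ea$F; fit$effect_p <- ea$p
  }
  if (lof && !is.null(design)) fit$lof <- lack_of_fit(design, fit$spec, fit)
  fit
}

#' @export
print.doe_fit <- function(x, ...) {
  resp <- if (!is.null(x$spec)) x$spec$response else "y"
  cat(sprintf("<doe_fit> %s: n = %d, k = %d effects\n", resp, x$n, x$k))
  cat(sprintf("  R2 = %.3f, R2adj = %.3f, RMSE_F = %.4g (%s%% of average scale), AICc = %.2f\n",
              x$r2, x$r2_adj, x$rmse_f,
              if (is.na(x$rmse_f_pct)) "NA" else round(x$rmse_f_pct), x$aicc))
  if (!is.null(x$p_whole))
    cat(sprintf("  whole-model F = %.3f, p = %s\n", x$f_whole,
                format_p(x$p_whole)))
  if (!is.null(x$lof) && x$lof$available)
    cat(sprintf("  lack-of-fit F = %.3f, p = %s\n", x$lof$F,
                format_p(x$lof$p)))
  if (length(x$coefficients)) {
    tab <- data.frame(estimate = signif(x$coefficients, 4))
    if (!is.null(x$beta)) tab$beta <- signif(x$beta, 3)
    if (!is.null(x$effect_p)) tab$p <- vapply(x$effect_p, format_p, "")
    print(tab)
  }
  invisible(x)
}

#' Whole-model ANOVA F test
#'
#' F is the ratio of the model to the error mean square on (k, n-k-1)
#' degrees of freedom; p is the upper tail of the F distribution.
#'
#' @param fit A \code{doe_fit}.
#' @return List with \code{F}, \code{p}, and the degrees of freedom. With
#'   zero error degrees of freedom the p-value is \code{NA} and
#'   \code{available} is \code{FALSE}.
#' @export
whole_model_anova <- function(fit) {
  if (fit$df["error"] <= 0 || fit$ss["error"] <= 0)
    return(list(F = NA_real_, p = NA_real_, df1 = fit$df[["model"]],
                df2 = fit$df[["error"]], available = FALSE))
  if (fit$k == 0)
    return(list(F = NA_real_, p = NA_real_, df1 = 0,
                df2 = fit$df[["error"]], available = FALSE))
  F <- fit$ms[["model"]] / fit$ms[["error"]]
  list(F = F, p = stats::pf(F, fit$df[["model"]], fit$df[["error"]],
                            lower.tail = FALSE),
       df1 = fit$df[["model"]], df2 = fit$df[["error"]], available = TRUE)
}

#' Per-effect deprivation ANOVA
#'
#' The effect sum of squares is the increase in error SS when the model is
#' refitted without the effect's column (columns fixed: centering is not
#' redone), tested on 1 DF against the full model's error mean square.
#'
#' @param design Unused; kept for a uniform operation signature.
#' @param spec The model specification (defaults to the one in \code{fit}).
#' @param fit A \code{doe_fit}.
#' @param term An \code{\link{effect_term}} or its label.
#' @return List with \code{ss}, \code{F}, \code{p}.
#' @export
effect_anova <- function(design = NULL, spec = NULL, fit, term) {
  lab <- if (inherits(term, "effect_term")) term$label else term
  j <- match(lab, colnames(fit$X))
  if (is.na(j)) stop("term '", lab, "' not in the fitted model", call. = FALSE)
  z <- stats::lm.fit(fit$X[, -j, drop = FALSE], fit$y)
  ss_red <- sum(z$residuals^2)
  ss_eff <- ss_red - fit$ss[["error"]]
  F <- (ss_eff / 1) / fit$ms[["error"]]
  list(ss = ss_eff, F = F,
       p = stats::pf(F, 1, fit$df[["error"]], lower.tail = FALSE))
}

effect_anova_all <- function(fit) {
  labs <- colnames(fit$X)[-1]
  out <- lapply(labs, function(l) effect_anova(fit = fit, term = l))
  list(ss = stats::setNames(vapply(out, `[[`, 0, "ss"), labs),
       F = stats::setNames(vapply(out, `[[`, 0, "F"), labs),
       p = stats::setNames(vapply(out, `[[`, 0, "p"), labs))
}

#' Lack-of-fit ANOVA from replicate pure error
#'
#' Pure error SS is the within-replicate-group sum of squared deviations
#' from the group means (the error SS of a saturated model with one
#' parameter per distinct factor combination); lack-of-fit SS is the
#' remainder of the fit's error SS. F compares the lack-of-fit to the pure
#' error mean square.
#'
#' @param design Design rows the fit used: a \code{doe_design} (the fit's
#'   rows are selected via \code{fit$fit_rows}) or a data.frame of factor
#'   values already aligned with the fit rows.
#' @param spec Unused; kept for a uniform operation signature.
#' @param fit A \code{doe_fit}.
#' @return List with \code{ss_lof}, \code{ss_pure}, degrees of freedom,
#'   \code{F}, \code{p} and \code{available}; when no factor combination is
#'   replicated or the lack-of-fit DF is not positive the test is reported
#'   unavailable rather than raised as an error.
#' @export
lack_of_fit <- function(design, spec = NULL, fit) {
  df <- as.data.frame(design)
  facs <- attr(design, "factors")
  if (!is.null(facs)) df <- df[, factor_names(facs), drop = FALSE]
  if (nrow(df) != fit$n) df <- df[fit$fit_rows, , drop = FALSE]
  key <- do.call(paste, c(df, sep = "\r"))
  g <- length(unique(key))
  n <- fit$n
  gm <- stats::ave(fit$y, key)
  ss_pure <- sum((fit$y - gm)^2)
  df_pure <- n - g
  ss_lof <- fit$ss[["error"]] - ss_pure
  df_lof <- g - 1L - fit$k
  if (df_pure <= 0 || df_lof <= 0 || ss_pure <= 0)
    return(list(ss_lof = ss_lof, ss_pure = ss_pure, df_lof = df_lof,
                df_pure = df_pure, F = NA_real_, p = NA_real_,
                available = FALSE))
  F <- (ss_lof / df_lof) / (ss_pure / df_pure)
  list(ss_lof = ss_lof, ss_pure = ss_pure, df_lof = df_lof,
       df_pure = df_pure, F = F,
       p = stats::pf(F, df_lof, df_pure, lower.tail = FALSE),
       available = TRUE)
}

#' Standardized regression coefficients (beta-weights)
#'
#' Coefficients that would be obtained had every effect column and the
#' response been standardized to mean 0 and variance 1 (sample SD, n-1
#' denominator) before fitting. Constructed second-order columns are
#' standardized as columns, not rebuilt from standardized factors.
#'
#' @param mm Model matrix object or plain matrix (first column intercept).
#' @param y Response vector.
#' @param fit Unused; kept for a uniform operation signature.
#' @return Named numeric vector of beta-weights, one per effect column.
#' @export
beta_weights <- function(mm, y, fit = NULL) {
  X <- if (is.matrix(mm)) mm else mm$X
  Xe <- X[, -1, drop = FALSE]
  if (ncol(Xe) == 0) return(stats::setNames(numeric(0), character(0)))
  sds <- apply(Xe, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(Xe)[sds == 0], collapse = ", "),
         call. = FALSE)
  Z <- scale(Xe)
  ys <- (y - mean(y)) / stats::sd(y)
  z <- stats::lm.fit(cbind(1, Z), ys)
  stats::setNames(z$coefficients[-1], colnames(Xe))
}

# AICc under the Gaussian likelihood with MLE variance; the parameter count
# is k effect columns + intercept + variance.
aicc_value <- function(n, k, sse) {
  p <- k + 2
  if (sse <= 0) return(-Inf)
  aic <- n * log(2 * pi * sse / n) + n + 2 * p
  if (n - p - 1 <= 0) {
    warning("AICc penalty denominator <= 0 (n = ", n, ", parameters = ", p,
            "); returning +Inf", call. = FALSE)
    return(Inf)
  }
  aic + 2 * p * (p + 1) / (n - p - 1)
}

#' Corrected Akaike information criterion of a fit
#'
#' \code{AICc = n log(2 pi SSE/n) + n + 2p + 2p(p+1)/(n-p-1)} with
#' \code{p = k + 2} (intercept and error variance count as parameters).
#' Comparable only across models of the same response values.
#'
#' @param fit A \code{doe_fit}.
#' @return The AICc value; \code{+Inf} with a warning when the small-sample
#'   penalty denominator is not positive.
#' @export
aicc <- function(fit) aicc_value(fit$n, fit$k, fit$ss[["error"]])

#' Goodness-of-fit metrics of a fit
#'
#' @param fit A \code{doe_fit}.
#' @return List with \code{r2}, \code{r2_adj}, \code{rmse_f} (root mean
#'   square of the error MS), \code{mae_f}, \code{average_scale} (mean minus
#'   minimum of the response), \code{rmse_f_pct} (RMSE_F as percent of the
#'   average scale) and its whole-percent rounding \code{rmse_f_pct_rounded};
#'   percent metrics are \code{NA} when the average scale is not positive.
#' @export
fit_metrics <- function(fit) {
  pct <- fit$rmse_f_pct
  list(r2 = fit$r2, r2_adj = fit$r2_adj, rmse_f = fit$rmse_f,
       mae_f = fit$mae_f, average_scale = fit$average_scale,
       rmse_f_pct = pct,
       rmse_f_pct_rounded = if (is.na(pct)) NA_real_ else round(pct))
}

#' Predict from a fitted model on new factor combinations
#'
#' @param object A \code{doe_fit} carrying its \code{model_spec} and
#'   realized centering constants.
#' @param newdata Data.frame with the factor columns.
#' @param factors Factor list (defaults to the ones stored at fit time via
#'   the design attribute of \code{newdata}, else the study defaults).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.doe_fit <- function(object, newdata,
                            factors = attr(newdata, "factors"), ...) {
  if (is.null(object$spec))
    stop("fit carries no model specification; predict needs one", call. = FALSE)
  if (is.null(factors)) factors <- default_factors()
  df <- as.data.frame(newdata)
  Xe <- encode_effect_columns(df, object$spec$terms, object$centering, factors)
  as.numeric(cbind(1, Xe) %*% c(object$b0, object$coefficients))
}

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-4) return("<0.0001")
  sprintf("%.4f", p)
}
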