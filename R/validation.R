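#' k-fold cross-validation of a response model
#'
#' Rows with missing response are excluded, the remaining rows are split
#' into \code{k} near-equal folds (seeded random partition, or an explicit
#' assignment), and for each fold the model is refitted on the complement --
#' recomputing the centering constants on the training rows -- and the
#' held-out rows are predicted. Errors are summarized both pooled over all
#' held-out predictions and as the average of the per-fold values (the
#' study reports the averages).
#'
#' @param design A \code{doe_design}.
#' @param y Response vector aligned with the design rows.
#' @param spec A \code{\link{model_spec}} (any supplied centering constants
#'   are ignored: each training fit recenters on its own rows).
#' @param k Number of folds (>= 2); \code{k = n} is leave-one-out.
#' @param folds Optional explicit assignment: integer vector of fold labels
#'   in 1..k, one per non-missing row (in design row order).
#' @param seed Integer seed for the random partition.
#' @param factors Factor list; defaults to the design attribute.
#' @return An object of class \code{cv_report} with per-point errors,
#'   pooled and fold-averaged MAE/RMSE, per-training-model fit metrics and
#'   the fold assignment used.
#' @export
kfold_cv <- function(design, y, spec, k = 5, folds = NULL, seed = 0L,
                     factors = attr(design, "factors")) {
  stopifnot(k >= 2)
  rows <- which(!is.na(y))
  n <- length(rows)
  if (k > n) stop("k = ", k, " exceeds the ", n, " usable rows", call. = FALSE)
  if (is.null(folds)) {
    set.seed(as.integer(seed))
    folds <- sample(rep(seq_len(k), length.out = n))
  }
  stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
  spec <- model_spec(spec$response, spec$terms)  # drop fixed centering

  per_point <- list(); training <- list()
  for (fold in seq_len(k)) {
    test <- rows[folds == fold]
    train <- rows[folds != fold]
    if (length(train) <= length(spec$terms) + 1L)
      stop("fold ", fold, " leaves too few training rows (",
           length(train), ") for ", length(spec$terms), " effects",
           call. = FALSE)
    fit <- tryCatch(
      fit_ols(build_model_matrix(design, spec, train, factors), y[train],
              diagnostics = FALSE, design = design),
      error = function(e)
        stop("training fit for fold ", fold, " failed: ",
             conditionMessage(e), call. = FALSE))
    pred <- predict(fit, as.data.frame(design)[test, , drop = FALSE],
                    factors = factors)
    per_point[[fold]] <- data.frame(run_id = design$run_id[test],
                                    fold = fold, observed = y[test],
                                    predicted = pred,
                                    abs_error = abs(y[test] - pred))
    m <- fit_metrics(fit)
    training[[fold]] <- data.frame(fold = fold, n_train = length(train),
                                   r2 = m$r2, r2_adj = m$r2_adj,
                                   mae_f = m$mae_f, rmse_f = m$rmse_f)
  }
  pp <- do.call(rbind, per_point)
  fold_mae <- vapply(per_point, function(d) mean(d$abs_error), 0)
  fold_rmse <- vapply(per_point, function(d) sqrt(mean(d$abs_error^2)), 0)
  structure(list(
    mode = "cv", k = k, response = spec$response,
    per_point = pp, training = do.call(rbind, training),
    mae_pooled = mean(pp$abs_error),
    rmse_pooled = sqrt(mean(pp$abs_error^2)),
    mae_avg = mean(fold_mae), rmse_avg = mean(fold_rmse),
    fold_mae = fold_mae, fold_rmse = fold_rmse,
    folds = folds, rows = rows
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: k = %d over %d rows\n", x$response, x$k,
              nrow(x$per_point)))
  cat(sprintf("  MAE_CV = %.4g (pooled %.4g), RMSE_CV = %.4g (pooled %.4g)\n",
              x$mae_avg, x$mae_pooled, x$rmse_avg, x$rmse_pooled))
  cat(sprintf("  training (averages): R2 = %.3f, R2adj = %.3f, MAE_F = %.4g, RMSE_F = %.4g\n",
              mean(x$training$r2), mean(x$training$r2_adj),
              mean(x$training$mae_f), mean(x$training$rmse_f)))
  invisible(x)
}

#' Experimental validation of a model against measured combinations
#'
#' Predicts the response at each measured combination and summarizes the
#' deviations as MAE_EV (mean absolute error) and RMSE_EV (root-mean-square
#' error). Points with a missing measured value are skipped with a warning,
#' so a table mixing 6-point respiratory and 8-point photosynthetic
#' validation series can be passed as is.
#'
#' @param model A \code{\link{published_model}} (or any object with a
#'   \code{predict} method over the point columns).
#' @param points Data.frame with the factor columns and a measured-response
#'   column named after the model's response.
#' @return An object of class \code{ev_report} with per-point residuals and
#'   the MAE_EV / RMSE_EV summaries.
#' @export
experimental_validation <- function(model, points) {
  resp <- model$response
  if (!nrow(points)) stop("no validation points", call. = FALSE)
  if (!resp %in% names(points))
    stop("points table has no measured column '", resp, "'", call. = FALSE)
  measured <- points[[resp]]
  keep <- !is.na(measured)
  if (!all(keep))
    warning(sum(!keep), " point(s) without a measured ", resp,
            " value skipped", call. = FALSE)
  if (!any(keep)) stop("no measured values for '", resp, "'", call. = FALSE)
  pts <- points[keep, , drop = FALSE]
  pred <- predict(model, pts)
  res <- data.frame(point = if ("point" %in% names(pts)) pts$point
                    else which(keep),
                    measured = pts[[resp]], predicted = pred,
                    residual = pts[[resp]] - pred,
                    abs_error = abs(pts[[resp]] - pred))
  structure(list(mode = "ev", response = resp, n_points = nrow(res),
                 per_point = res,
                 mae_ev = mean(res$abs_error),
                 rmse_ev = sqrt(mean(res$abs_error^2))),
            class = "ev_report")
}

#' @export
print.ev_report <- function(x, ...) {
  cat(sprintf("<ev_report> %s: %d points, MAE_EV = %.4g, RMSE_EV = %.4g\n",
              x$response, x$n_points, x$mae_ev, x$rmse_ev))
  invisible(x)
}
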