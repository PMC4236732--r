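#' Configuration of the end-to-end study replica
#'
#' All randomness flows from one top-level seed, expanded per stage (design
#' construction, synthetic noise, cross-validation folds), so any stage can
#' be re-run reproducibly on its own.
#'
#' @param n_runs,n_center Design size and number of center points.
#' @param seed Top-level integer seed.
#' @param sigma Noise SDs passed to \code{\link{noise_model}}.
#' @param missing_runs Missing-value pattern passed to
#'   \code{\link{noise_model}}.
#' @param alpha Significance cutoff used throughout.
#' @param r2_floor,slack Round-2 stopping-rule parameters.
#' @param k Cross-validation folds.
#' @param ev Include the experimental validation of the published models
#'   against the packaged measured combinations.
#' @param design_file,responses_file Optional CSV paths; when supplied they
#'   replace the generated design and/or synthetic responses.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_runs = 42, n_center = 7, seed = 0L,
                            sigma = NULL, missing_runs = NULL,
                            alpha = 0.05, r2_floor = 0.60, slack = 0.05,
                            k = 5, ev = TRUE,
                            design_file = NULL, responses_file = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!is.null(sigma) && any(sigma < 0))
    stop("sigma must be nonnegative", call. = FALSE)
  for (f in c(design_file, responses_file))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  structure(list(n_runs = n_runs, n_center = n_center, seed = as.integer(seed),
                 sigma = sigma, missing_runs = missing_runs, alpha = alpha,
                 r2_floor = r2_floor, slack = slack, k = k, ev = ev,
                 design_file = design_file, responses_file = responses_file),
            class = "pipeline_config")
}

#' Save or load a pipeline configuration as JSON
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param path File path.
#' @return \code{load_config} returns the \code{pipeline_config}; saving and
#'   reloading restores an identical object.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sigma)) x$sigma <- as.list(x$sigma)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$sigma)) x$sigma <- unlist(x$sigma)
  if (!is.null(x$missing_runs))
    x$missing_runs <- lapply(x$missing_runs, function(v)
      as.integer(unlist(v)))
  scalars <- c("n_runs", "n_center", "seed", "alpha", "r2_floor", "slack",
               "k", "ev", "design_file", "responses_file")
  for (s in scalars) if (!is.null(x[[s]])) x[[s]] <- unlist(x[[s]])
  do.call(pipeline_config, x[!vapply(x, is.null, TRUE)])
}

#' Run the full design -> data -> selection -> simulation -> validation
#' pipeline
#'
#' Builds (or loads) the design, generates (or loads) the responses, runs
#' the two-round selection per response, profiles every factor of each final
#' model (reporting quadratic optima), cross-validates each final model, and
#' optionally scores the published models against the packaged measured
#' validation combinations.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param factors Factor list (the study factors by default).
#' @return An object of class \code{pipeline_bundle}.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         factors = default_factors()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- if (!is.null(config$design_file))
    read_design(config$design_file, factors)
  else build_design(factors, n_runs = config$n_runs,
                    n_center = config$n_center, seed = config$seed)

  noise_args <- list(seed = config$seed + 1L)
  if (!is.null(config$sigma)) noise_args$sigma <- config$sigma
  if (!is.null(config$missing_runs))
    noise_args$missing_runs <- config$missing_runs
  responses <- if (!is.null(config$responses_file))
    read_responses(config$responses_file)
  else generate_responses(design, published_models(),
                          do.call(noise_model, noise_args))

  selection <- run_two_round(design, responses,
                             config = list(alpha = config$alpha,
                                           r2_floor = config$r2_floor,
                                           slack = config$slack),
                             factors = factors)

  profiles <- list(); vertices <- list()
  for (r in selection$responses) {
    if (!length(r$fit2$spec$terms)) next
    pm <- tryCatch(as_published_model(r$fit2, design, factors),
                   error = function(e) NULL)
    if (is.null(pm)) next
    for (f in intersect(model_factors(pm), factor_names(factors))) {
      pc <- profile_curve(pm, f, factors = factors)
      profiles[[paste(r$response, f, sep = ".")]] <- pc
      if (!is.null(pc$vertex))
        vertices[[length(vertices) + 1L]] <- data.frame(
          response = r$response, factor = f,
          location = pc$vertex$location, value = pc$vertex$value,
          curvature = pc$vertex$curvature)
    }
  }
  vertices <- if (length(vertices)) do.call(rbind, vertices)
              else data.frame(response = character(), factor = character(),
                              location = numeric(), value = numeric(),
                              curvature = character())

  cv <- list()
  idx <- match(design$run_id, responses$run_id)
  for (r in selection$responses) {
    if (!length(r$fit2$spec$terms)) next
    cv[[r$response]] <- kfold_cv(design, responses[[r$response]][idx],
                                 r$fit2$spec, k = config$k,
                                 seed = config$seed + 2L, factors = factors)
  }

  ev <- NULL
  if (isTRUE(config$ev)) {
    pts <- validation_points()
    ev <- suppressWarnings(
      lapply(published_models(), experimental_validation, points = pts))
  }

  structure(list(config = config, design = design, responses = responses,
                 selection = selection, profiles = profiles,
                 vertices = vertices, cv = cv, ev = ev),
            class = "pipeline_bundle")
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle> %d runs, %d response(s), %d vertex/vertices\n",
              nrow(x$design), length(x$selection$responses),
              nrow(x$vertices)))
  invisible(x)
}

signif3 <- function(x) signif(x, 3)

#' Render a pipeline bundle as Markdown and JSON reports
#'
#' Writes \code{report.json} (a plain-data summary that reloads identically
#' with \code{\link{load_report}}) and \code{report.md}. Effects are listed
#' by ascending p-value with a star at p <= alpha; coefficients are printed
#' to 3 significant figures and p-values below 1e-4 as "<0.0001".
#'
#' @param bundle A \code{pipeline_bundle}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the summary list written to JSON.
#' @export
render_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- bundle$config$alpha

  summary_list <- list(
    config = unclass(bundle$config),
    design = list(n_runs = nrow(bundle$design),
                  n_center = sum(bundle$design$is_center),
                  n_replicate_groups = max(bundle$design$replicate_group)),
    models = lapply(bundle$selection$responses, function(r) list(
      response = r$response, n = r$n,
      round1 = round_summary(r$fit1),
      round2 = round_summary(r$fit2),
      effects = effects_rows(r$table),
      factors_final = as.list(r$factors_final))),
    vertices = df_rows(bundle$vertices),
    cv = lapply(bundle$cv, function(v) list(
      k = v$k, mae_cv = v$mae_avg, rmse_cv = v$rmse_avg,
      mae_cv_pooled = v$mae_pooled, rmse_cv_pooled = v$rmse_pooled,
      training_r2 = mean(v$training$r2),
      training_rmse_f = mean(v$training$rmse_f))),
    ev = if (is.null(bundle$ev)) NULL else lapply(bundle$ev, function(e)
      list(n_points = e$n_points, mae_ev = e$mae_ev, rmse_ev = e$rmse_ev))
  )
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  md <- c("# Two-round response-surface analysis report", "",
          sprintf("Design: %d runs, %d center points, %d replicate groups.",
                  nrow(bundle$design), sum(bundle$design$is_center),
                  max(bundle$design$replicate_group)), "",
          "## Final models (round 2)", "")
  for (r in bundle$selection$responses) {
    md <- c(md, sprintf("### %s (n = %d)", r$response, r$n),
            sprintf("R2 = %.2f, R2 adjusted = %.2f, RMSE_F = %s (%s%% of the average scale), AICc = %.2f",
                    r$fit2$r2, r$fit2$r2_adj, signif3(r$fit2$rmse_f),
                    if (is.na(r$fit2$rmse_f_pct)) "NA"
                    else round(r$fit2$rmse_f_pct), r$fit2$aicc),
            sprintf("Whole-model ANOVA: p = %s; lack-of-fit: %s",
                    format_p(r$fit2$p_whole),
                    if (!is.null(r$fit2$lof) && r$fit2$lof$available)
                      paste0("p = ", format_p(r$fit2$lof$p))
                    else "unavailable"), "")
    if (nrow(r$table)) {
      md <- c(md, "| # | effect | estimate | beta | p |",
              "|---|--------|----------|------|---|")
      for (i in seq_len(nrow(r$table)))
        md <- c(md, sprintf("| %d | %s | %s | %s | %s%s |", i,
                            r$table$term[i], signif3(r$table$estimate[i]),
                            signif3(r$table$beta[i]), format_p(r$table$p[i]),
                            if (r$table$p[i] <= alpha) "*" else ""))
    } else md <- c(md, "no effects retained")
    md <- c(md, "")
  }
  if (nrow(bundle$vertices)) {
    md <- c(md, "## Quadratic optima", "",
            "| response | factor | location | value | curvature |",
            "|----------|--------|----------|-------|-----------|")
    for (i in seq_len(nrow(bundle$vertices)))
      md <- c(md, sprintf("| %s | %s | %s | %s | %s |",
                          bundle$vertices$response[i], bundle$vertices$factor[i],
                          signif3(bundle$vertices$location[i]),
                          signif3(bundle$vertices$value[i]),
                          bundle$vertices$curvature[i]))
    md <- c(md, "")
  }
  if (length(bundle$cv)) {
    md <- c(md, "## Cross-validation (fold averages)", "",
            "| response | MAE_CV | RMSE_CV | training R2 | training RMSE_F |",
            "|----------|--------|---------|-------------|-----------------|")
    for (nm in names(bundle$cv)) {
      v <- bundle$cv[[nm]]
      md <- c(md, sprintf("| %s | %s | %s | %.2f | %s |", nm,
                          signif3(v$mae_avg), signif3(v$rmse_avg),
                          mean(v$training$r2), signif3(mean(v$training$rmse_f))))
    }
    md <- c(md, "")
  }
  if (!is.null(bundle$ev)) {
    md <- c(md, "## Experimental validation of the published models", "",
            "| response | points | MAE_EV | RMSE_EV |",
            "|----------|--------|--------|---------|")
    for (nm in names(bundle$ev)) {
      e <- bundle$ev[[nm]]
      md <- c(md, sprintf("| %s | %d | %s | %s |", nm, e$n_points,
                          signif3(e$mae_ev), signif3(e$rmse_ev)))
    }
    md <- c(md, "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(summary_list)
}

round_summary <- function(fit) {
  list(k = fit$k, r2 = fit$r2, r2_adj = fit$r2_adj, rmse_f = fit$rmse_f,
       mae_f = fit$mae_f, rmse_f_pct = fit$rmse_f_pct, aicc = fit$aicc,
       p_whole = fit$p_whole,
       lof_p = if (!is.null(fit$lof) && fit$lof$available) fit$lof$p
               else NULL)
}

effects_rows <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) list(
    term = tab$term[i], estimate = tab$estimate[i], beta = tab$beta[i],
    p = tab$p[i], significant = tab$significant[i]))
}

df_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' @rdname render_report
#' @param path Path of a \code{report.json} written by
#'   \code{render_report}.
#' @export
load_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
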