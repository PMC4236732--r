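#' Gaussian measurement-noise model for synthetic responses
#'
#' Homoscedastic Gaussian noise per response. The default standard
#' deviations are the fitted RMSE_F of the six second-round response models,
#' so synthetic data carry the error scale the study actually observed; the
#' default missing-value pattern reproduces the study's (dark respiration CR
#' unmeasurable on 2 runs, cytochromial activity MA_CYT on 1).
#'
#' @param sigma Named vector of noise SDs (response units).
#' @param missing_runs Named list of run ids blanked per response.
#' @param seed Integer seed used by \code{\link{generate_responses}}.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(sigma = c(CR = 2.9, MA_CYT = 3.5, MA_ALT = 3.0,
                                  PHIPSII800 = 0.068, NPQ800 = 0.084,
                                  P800 = 19.6),
                        missing_runs = list(CR = c(14L, 28L), MA_CYT = 26L),
                        seed = 0L) {
  stopifnot(is.numeric(sigma), all(sigma >= 0), !is.null(names(sigma)))
  structure(list(sigma = sigma, missing_runs = missing_runs,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# responses that are physically nonnegative and truncated at zero when
# simulated (chlorophyll-fluorescence indices)
NONNEGATIVE_RESPONSES <- c("PHIPSII800", "NPQ800")

#' Generate study-like response data from ground-truth models
#'
#' For every model, the response on each design run is the model prediction
#' plus independent Gaussian noise at the model's \code{sigma}; runs listed
#' in the missing pattern are blanked. The two fluorescence indices
#' (PHIPSII800, NPQ800) are truncated at zero, with the number of truncated
#' values recorded in the \code{"truncated"} attribute. Reproducible given
#' the noise-model seed.
#'
#' @param design A \code{doe_design} or data.frame with the factor columns
#'   and \code{run_id}.
#' @param models Named list of \code{\link{published_model}}s (or any models
#'   with a \code{predict} method over the design factors).
#' @param noise A \code{\link{noise_model}}; responses without a sigma get
#'   noiseless values.
#' @return Data.frame with \code{run_id} and one column per response.
#' @export
generate_responses <- function(design, models = published_models(),
                               noise = noise_model()) {
  df <- as.data.frame(design)
  if (is.null(df$run_id)) df$run_id <- seq_len(nrow(df))
  for (resp in names(noise$missing_runs)) {
    bad <- setdiff(noise$missing_runs[[resp]], df$run_id)
    if (length(bad))
      stop("missing_runs for '", resp, "' reference unknown run id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(noise$seed)
  out <- data.frame(run_id = df$run_id)
  truncated <- integer()
  for (m in models) {
    resp <- m$response
    pred <- predict(m, df)
    sigma <- if (resp %in% names(noise$sigma)) noise$sigma[[resp]] else 0
    y <- pred + stats::rnorm(length(pred), 0, sigma)
    if (resp %in% NONNEGATIVE_RESPONSES) {
      n_trunc <- sum(y < 0)
      if (n_trunc) y <- pmax(y, 0)
      truncated[resp] <- n_trunc
    }
    if (resp %in% names(noise$missing_runs))
      y[df$run_id %in% noise$missing_runs[[resp]]] <- NA_real_
    out[[resp]] <- y
  }
  attr(out, "truncated") <- truncated
  out
}

#' Generate a synthetic experimental-validation set
#'
#' Draws \code{n_points} new factor combinations uniformly over the working
#' ranges (the ordinal CO2 factor is fixed at its high level, as in the
#' study's validation cultures), simulates \code{n_replicates} measurements
#' per combination with noise proportional to the predicted response, and
#' returns per-point means and SDs in the layout of the packaged measured
#' validation table.
#'
#' @param n_points Number of combinations.
#' @param factors Factor list.
#' @param models Named list of models to predict from.
#' @param replicate_sd Named relative SD per response (fraction of the
#'   predicted value); unnamed single value recycled. Defaults to the
#'   study's replicate spreads: 19.7\% for NPQ800, 9\% otherwise.
#' @param n_replicates Replicates per combination.
#' @param seed Integer seed.
#' @return Data.frame with \code{point}, the factor columns, and per
#'   response its replicate mean and \code{_sd} columns.
#' @export
generate_validation_set <- function(n_points = 6, factors = default_factors(),
                                    models = published_models(),
                                    replicate_sd = c(default = 0.09,
                                                     NPQ800 = 0.197),
                                    n_replicates = 3, seed = 0L) {
  stopifnot(n_points >= 1, n_replicates >= 1)
  nms <- check_factor_list(factors)
  kinds <- vapply(factors, `[[`, "", "kind")
  set.seed(as.integer(seed))
  pts <- data.frame(point = seq_len(n_points))
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    pts[[f$name]] <- if (kinds[i] == "ordinal")
      rep(f$levels[2], n_points)
    else stats::runif(n_points, f$low, f$high)
  }
  rsd_of <- function(resp) {
    if (resp %in% names(replicate_sd)) replicate_sd[[resp]]
    else if ("default" %in% names(replicate_sd)) replicate_sd[["default"]]
    else replicate_sd[[1]]
  }
  for (m in models) {
    pred <- predict(m, pts, factors = factors)
    reps <- matrix(pred, n_points, n_replicates) *
      (1 + matrix(stats::rnorm(n_points * n_replicates, 0, rsd_of(m$response)),
                  n_points, n_replicates))
    pts[[m$response]] <- rowMeans(reps)
    pts[[paste0(m$response, "_sd")]] <- if (n_replicates == 1)
      rep(0, n_points) else apply(reps, 1, stats::sd)
  }
  pts
}

#' The measured validation combinations
#'
#' The eight new factor combinations (outside the design) whose responses
#' were measured in triplicate for experimental validation, with per-point
#' means and SDs. The respiratory responses were measured on the first six
#' points only.
#'
#' @return Data.frame with \code{point}, factor columns and mean/SD columns
#'   per response.
#' @export
validation_points <- function() {
  utils::read.csv(system.file("extdata", "table5.csv", package = "chlamyRSM"))
}

#' Read or write a response table as CSV
#'
#' Header \code{run_id} then one column per response; blank fields are
#' missing measurements.
#'
#' @param responses Data.frame with \code{run_id} and response columns.
#' @param path File path.
#' @return \code{read_responses} returns the data.frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"run_id" %in% names(tab))
    stop("response file lacks a run_id column", call. = FALSE)
  tab
}
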