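#' Specify a regression model for one response
#'
#' @param response Response name.
#' @param terms List of \code{\link{effect_term}}s.
#' @param centering Optional named numeric vector of centering constants (in
#'   factor units) for factors appearing in second-order terms. Constants not
#'   supplied are taken as the arithmetic mean of the factor over the rows
#'   actually fitted, so models fitted after dropping missing responses carry
#'   their own constants.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(response, terms, centering = NULL) {
  stopifnot(is.character(response), length(response) == 1L)
  terms <- if (inherits(terms, "effect_term")) list(terms) else terms
  stopifnot(all(vapply(terms, inherits, TRUE, "effect_term")))
  if (anyDuplicated(term_labels(terms)))
    stop("duplicate terms in model spec", call. = FALSE)
  if (!is.null(centering))
    stopifnot(is.numeric(centering), !is.null(names(centering)))
  structure(list(response = response, terms = terms, centering = centering),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s ~ %s\n", x$response,
              if (length(x$terms)) paste(term_labels(x$terms), collapse = " + ")
              else "1"))
  invisible(x)
}

# factors needing a centering constant: continuous factors appearing in any
# second-order term
centered_factor_names <- function(terms, factors) {
  kinds <- vapply(factors, `[[`, "", "kind")
  cont <- factor_names(factors)[kinds == "continuous"]
  need <- unique(unlist(lapply(terms, function(tm)
    if (tm$order == 2L) tm$factors else character())))
  intersect(need, cont)
}

effect_centering <- function(data, terms, factors, rows = seq_len(nrow(data)),
                             supplied = NULL) {
  need <- centered_factor_names(terms, factors)
  cen <- vapply(need, function(f) mean(data[[f]][rows]), 0)
  if (length(supplied)) {
    hit <- intersect(names(supplied), need)
    cen[hit] <- supplied[hit]
  }
  cen
}

# One column per effect term. Linear continuous terms enter uncentered;
# quadratics and interactions use centered factors; the two-level ordinal
# factor enters as an indicator of its high level, and its interactions as
# indicator * centered partner.
encode_effect_columns <- function(data, terms, centering, factors,
                                  rows = seq_len(nrow(data))) {
  kinds <- vapply(factors, `[[`, "", "kind")
  names(kinds) <- factor_names(factors)
  col_of <- function(f) {
    x <- data[[f]][rows]
    if (is.null(x)) stop("factor '", f, "' not found in data", call. = FALSE)
    x
  }
  ind_of <- function(f) {
    spec <- factors[[match(f, factor_names(factors))]]
    as.numeric(col_of(f) == spec$levels[2])
  }
  ctr <- function(f) col_of(f) - centering[[f]]
  cols <- lapply(terms, function(tm) {
    fs <- tm$factors
    switch(tm$form,
      linear = if (kinds[[fs]] == "ordinal") ind_of(fs) else col_of(fs),
      quadratic = {
        if (kinds[[fs]] == "ordinal")
          stop("quadratic term not defined for ordinal factor '", fs, "'",
               call. = FALSE)
        ctr(fs)^2
      },
      interaction = {
        ord <- kinds[fs] == "ordinal"
        if (all(ord))
          stop("interaction of two ordinal factors not supported", call. = FALSE)
        if (any(ord)) ind_of(fs[ord]) * ctr(fs[!ord])
        else ctr(fs[1]) * ctr(fs[2])
      })
  })
  if (!length(cols))
    return(matrix(numeric(0), length(rows), 0))
  X <- do.call(cbind, cols)
  colnames(X) <- term_labels(terms)
  X
}

#' Build the regression design matrix for a model specification
#'
#' Encodes every effect term of \code{spec} on the requested rows. Centering
#' constants for second-order terms are the arithmetic means of the factors
#' over \code{fit_rows} (so they adapt to the rows a response was actually
#' measured on), unless \code{spec$centering} fixes them.
#'
#' @param design A \code{doe_design} or data.frame with the factor columns.
#' @param spec A \code{\link{model_spec}}.
#' @param fit_rows Integer row indices to encode (default all rows).
#' @param factors Factor list; defaults to the design attribute.
#' @return List of class \code{model_matrix}: \code{X} (intercept column
#'   plus one column per term), realized \code{centering}, \code{fit_rows},
#'   \code{spec} and \code{factors}.
#' @export
build_model_matrix <- function(design, spec, fit_rows = seq_len(nrow(design)),
                               factors = attr(design, "factors")) {
  if (is.null(factors)) stop("no factor specifications supplied", call. = FALSE)
  if (!length(fit_rows)) stop("fit_rows is empty", call. = FALSE)
  df <- as.data.frame(design)
  centering <- effect_centering(df, spec$terms, factors, fit_rows,
                                supplied = spec$centering)
  Xe <- encode_effect_columns(df, spec$terms, centering, factors, fit_rows)
  if (length(spec$terms)) {
    const <- apply(Xe, 2, function(col) max(col) == min(col))
    if (any(const))
      stop("constant effect column(s) on fit rows: ",
           paste(colnames(Xe)[const], collapse = ", "), call. = FALSE)
  }
  X <- cbind("(Intercept)" = rep(1, length(fit_rows)), Xe)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient model matrix; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, centering = centering, fit_rows = fit_rows,
                 spec = spec, factors = factors),
            class = "model_matrix")
}
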