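#' Define an experimental factor
#'
#' A factor is either continuous over a working range \code{[low, high]} or a
#' two-level ordinal factor (used here for CO2, whose two gas regimes 0.035%
#' and 1.5% are categories rather than points on a continuum).
#'
#' @param name Factor name (unique within a factor set).
#' @param kind \code{"continuous"} or \code{"ordinal"}.
#' @param unit Unit string, for display only.
#' @param low,high Range bounds (continuous factors); must satisfy
#'   \code{low < high}.
#' @param levels Ordered numeric pair of level labels (ordinal factors).
#' @return An object of class \code{factor_spec}.
#' @export
factor_spec <- function(name, kind = c("continuous", "ordinal"), unit = "",
                        low = NULL, high = NULL, levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (is.null(low) || is.null(high) || !(low < high))
      stop("continuous factor '", name, "' needs low < high", call. = FALSE)
    levels <- NULL
  } else {
    if (is.null(levels) || length(levels) != 2L || !is.numeric(levels) ||
        levels[1] >= levels[2])
      stop("ordinal factor '", name, "' needs exactly 2 increasing numeric levels",
           call. = FALSE)
    low <- levels[1]; high <- levels[2]
  }
  structure(list(name = name, kind = kind, unit = unit,
                 low = low, high = high, levels = levels),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  rng <- if (x$kind == "continuous")
    sprintf("[%g, %g]", x$low, x$high)
  else
    sprintf("{%g, %g}", x$levels[1], x$levels[2])
  cat(sprintf("<factor> %s (%s, %s) %s\n", x$name, x$kind, x$unit, rng))
  invisible(x)
}

#' The five environmental factors of the bioenergetics study
#'
#' Light intensity (0--200 umol photons m^-2 s^-1), acetate (0--1 g/L),
#' CO2 regime (ordinal, 0.035% or 1.5%), nitrate (0--20 mM) and ammonium
#' (0--15 mM).
#'
#' @return A named list of \code{\link{factor_spec}} objects.
#' @export
default_factors <- function() {
  fs <- list(
    factor_spec("light",    "continuous", "umol.m-2.s-1", 0, 200),
    factor_spec("acetate",  "continuous", "g.L-1",        0, 1),
    factor_spec("co2",      "ordinal",    "%", levels = c(0.035, 1.5)),
    factor_spec("nitrate",  "continuous", "mM",           0, 20),
    factor_spec("ammonium", "continuous", "mM",           0, 15)
  )
  names(fs) <- vapply(fs, `[[`, "", "name")
  fs
}

factor_names <- function(factors) vapply(factors, `[[`, "", "name")

check_factor_list <- function(factors) {
  if (length(factors) < 1L) stop("need at least one factor", call. = FALSE)
  stopifnot(all(vapply(factors, inherits, TRUE, "factor_spec")))
  nms <- factor_names(factors)
  if (anyDuplicated(nms))
    stop("duplicate factor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  invisible(nms)
}

#' Construct an effect term
#'
#' An effect is a linear term in one factor, a quadratic term in one
#' continuous factor, or an interaction between two distinct factors.
#'
#' @param form \code{"linear"}, \code{"quadratic"} or \code{"interaction"}.
#' @param factors Character vector of one (linear, quadratic) or two
#'   (interaction) factor names.
#' @return An object of class \code{effect_term} with fields \code{form},
#'   \code{factors}, \code{order} (1 for linear, 2 otherwise) and a display
#'   \code{label}.
#' @export
effect_term <- function(form = c("linear", "quadratic", "interaction"),
                        factors) {
  form <- match.arg(form)
  factors <- as.character(factors)
  n_fac <- c(linear = 1L, quadratic = 1L, interaction = 2L)[[form]]
  if (length(factors) != n_fac)
    stop(form, " term needs ", n_fac, " factor name(s)", call. = FALSE)
  if (form == "interaction" && factors[1] == factors[2])
    stop("interaction needs two distinct factors", call. = FALSE)
  label <- switch(form,
                  linear      = factors,
                  quadratic   = paste0(factors, "^2"),
                  interaction = paste(factors, collapse = ":"))
  structure(list(form = form, factors = factors,
                 order = if (form == "linear") 1L else 2L, label = label),
            class = "effect_term")
}

#' @export
print.effect_term <- function(x, ...) {
  cat(sprintf("<effect> %s (%s)\n", x$label, x$form)); invisible(x)
}

term_labels <- function(terms) vapply(terms, `[[`, "", "label")

#' Parent linear terms of a second-order effect
#'
#' Effect heredity ties every quadratic or interaction term to the linear
#' term(s) of the factors it contains.
#'
#' @param term An \code{\link{effect_term}}.
#' @return A list of linear \code{effect_term}s (empty for linear terms).
#' @export
parent_terms <- function(term) {
  if (term$order == 1L) return(list())
  lapply(term$factors, function(f) effect_term("linear", f))
}

#' Enumerate all candidate effects for a factor set
#'
#' Returns every linear term, the quadratic of every continuous factor, and
#' every unordered pairwise interaction, in a deterministic order: linear
#' terms in input order, then quadratics in input order, then interactions
#' sorted lexicographically by label. For the five study factors (4
#' continuous + 1 two-level ordinal) this yields the 19 candidate effects
#' screened in round 1.
#'
#' @param factors List of \code{\link{factor_spec}}s.
#' @return List of \code{\link{effect_term}}s of length
#'   \eqn{F + C + F(F-1)/2} where \eqn{F} is the number of factors and
#'   \eqn{C} the number of continuous ones.
#' @export
enumerate_candidate_effects <- function(factors) {
  nms <- check_factor_list(factors)
  kinds <- vapply(factors, `[[`, "", "kind")
  lin <- lapply(nms, function(f) effect_term("linear", f))
  quad <- lapply(nms[kinds == "continuous"],
                 function(f) effect_term("quadratic", f))
  inter <- list()
  if (length(nms) >= 2L) {
    pairs <- utils::combn(nms, 2L, simplify = FALSE)
    inter <- lapply(pairs, function(p) effect_term("interaction", p))
    inter <- inter[order(term_labels(inter))]
  }
  c(lin, quad, inter)
}
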