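#' Generate a screening design: fractional-factorial backbone, replicated
#' center points, and correlation-optimized extra points
#'
#' The design has three layers, mirroring the structure of the 42-run study
#' design: (i) a regular two-level factorial (or fractional-factorial)
#' backbone on the factor extremes, (ii) \code{n_center} replicated center
#' points (continuous factors at range midpoints; the ordinal factor
#' alternates between its two levels as far as parity allows, so center
#' replicates exist at both CO2 regimes), and (iii) extra points drawn from
#' the factorial corners plus axial/edge points of the central-composite and
#' Box-Behnken kind. Extra points are placed greedily to maximize the
#' information (log-determinant of the cross-product) of the full
#' candidate-effect model matrix encoded on range-scaled factors -- the
#' criterion a computer-generated optimal screening design targets -- with a
#' seeded scan order breaking ties, so the same seed always reproduces the
#' same table. Duplicated extra points are allowed and, together with the
#' center replicates, supply the pure-error degrees of freedom for
#' lack-of-fit testing.
#'
#' @param factors List of \code{\link{factor_spec}}s.
#' @param n_runs Total number of runs.
#' @param n_center Number of center points.
#' @param extra_points Number of extra points; by default whatever remains
#'   after the backbone and center points. When \code{n_runs - n_center}
#'   equals the full factorial size and no extras are requested, the backbone
#'   is the pure full factorial.
#' @param seed Integer seed; the same seed always yields the identical table.
#' @return A \code{doe_design}: a data.frame with \code{run_id}, one column
#'   per factor, \code{replicate_group} (equal labels iff all factor values
#'   are equal) and \code{is_center}; the factor list is kept as an
#'   attribute.
#' @export
build_design <- function(factors, n_runs = 42, n_center = 7,
                         extra_points = NULL, seed = 0) {
  nms <- check_factor_list(factors)
  effects <- enumerate_candidate_effects(factors)
  n_min <- length(effects) + 1L + n_center
  if (n_runs < n_min)
    stop("n_runs = ", n_runs, " too small: need at least ", n_min,
         " runs (", length(effects), " candidate effects + intercept + ",
         n_center, " center points)", call. = FALSE)

  f <- length(factors)
  budget <- n_runs - n_center
  if (is.null(extra_points)) {
    # pure factorial when it exactly fills the budget, else prefer a half
    # fraction so extra points remain to inform curvature
    backbone_size <- if (budget == 2^f) 2^f
                     else 2^min(f - 1L, floor(log2(budget)))
    extra_points <- budget - backbone_size
  } else {
    backbone_size <- budget - extra_points
    if (backbone_size < 2 || log2(backbone_size) %% 1 != 0)
      stop("n_runs - n_center - extra_points must be a power of 2 (got ",
           backbone_size, ")", call. = FALSE)
  }

  lows  <- vapply(factors, `[[`, 0, "low")
  highs <- vapply(factors, `[[`, 0, "high")
  mids  <- (lows + highs) / 2
  kinds <- vapply(factors, `[[`, "", "kind")

  backbone <- fractional_factorial(f, backbone_size)
  backbone <- sweep(sweep((backbone + 1) / 2, 2, highs - lows, "*"), 2, lows, "+")
  colnames(backbone) <- nms

  center <- NULL
  if (n_center > 0) {
    center <- matrix(rep(mids, each = n_center), n_center, f,
                     dimnames = list(NULL, nms))
    for (j in which(kinds == "ordinal"))
      center[, j] <- rep(factors[[j]]$levels, length.out = n_center)
  }

  extras <- NULL
  if (extra_points > 0) {
    pool <- extra_point_pool(factors, lows, highs, mids, kinds)
    colnames(pool) <- nms
    # ordinal factors have no midpoint: offer every level of each
    for (j in which(kinds == "ordinal")) {
      lv <- factors[[j]]$levels
      pool <- do.call(rbind, lapply(lv, function(v) {
        p <- pool; p[, j] <- v; p
      }))
    }
    set.seed(as.integer(seed))
    chosen <- integer(0)
    score_with <- function(idx)
      design_information_score(rbind(backbone, center,
                                     pool[idx, , drop = FALSE]),
                               factors, effects)
    for (slot in seq_len(extra_points)) {
      best <- NULL; best_score <- -Inf
      for (i in sample.int(nrow(pool))) {   # seeded scan order breaks ties
        sc <- score_with(c(chosen, i))
        if (sc > best_score + 1e-9) { best_score <- sc; best <- i }
      }
      chosen <- c(chosen, best)
    }
    # exchange passes: swap each extra for the best pool point until stable
    cur_score <- score_with(chosen)
    for (pass in 1:10) {
      improved <- FALSE
      for (slot in seq_along(chosen)) {
        for (i in sample.int(nrow(pool))) {
          trial <- chosen; trial[slot] <- i
          sc <- score_with(trial)
          if (sc > cur_score + 1e-9) {
            chosen <- trial; cur_score <- sc; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    extras <- pool[chosen, , drop = FALSE]
  }

  tab <- as.data.frame(rbind(backbone, center, extras))
  rownames(tab) <- NULL
  key <- do.call(paste, c(tab, sep = "\r"))
  is_center_row <- rep(TRUE, nrow(tab))
  for (j in which(kinds == "continuous"))
    is_center_row <- is_center_row & tab[[j]] == mids[j]
  out <- cbind(run_id = seq_len(nrow(tab)), tab,
               replicate_group = match(key, unique(key)),
               is_center = is_center_row)
  structure(out, factors = factors, class = c("doe_design", "data.frame"))
}

# regular 2-level design in -1/+1 coding; n a power of 2, 2^(f-p) rows.
# Added factors are products of base-factor subsets (sizes >= 2, largest
# subsets first) so low-order aliasing is avoided where possible.
fractional_factorial <- function(f, n) {
  base <- as.integer(log2(n))
  if (base > f) stop("factorial size exceeds 2^f", call. = FALSE)
  g <- expand.grid(rep(list(c(-1, 1)), base))
  m <- as.matrix(g)
  p <- f - base
  if (p > 0) {
    subsets <- unlist(lapply(base:2, function(s)
      utils::combn(base, s, simplify = FALSE)), recursive = FALSE)
    if (p > length(subsets))
      stop("cannot build a 2^(", f, "-", p, ") fraction: too few generators",
           call. = FALSE)
    for (i in seq_len(p))
      m <- cbind(m, apply(m[, subsets[[i]], drop = FALSE], 1, prod))
  }
  unname(m[, seq_len(f), drop = FALSE])
}

# candidate extra points: factorial corners (every factor at an extreme),
# axial points (one continuous factor at an extreme, others centered) and
# edge points (two continuous factors at extremes, others centered)
extra_point_pool <- function(factors, lows, highs, mids, kinds) {
  cont <- which(kinds == "continuous")
  rows <- list()
  for (j in cont) for (v in c(lows[j], highs[j])) {
    pt <- mids; pt[j] <- v; rows[[length(rows) + 1L]] <- pt
  }
  if (length(cont) >= 2) {
    for (pr in utils::combn(cont, 2, simplify = FALSE))
      for (v1 in c(lows[pr[1]], highs[pr[1]]))
        for (v2 in c(lows[pr[2]], highs[pr[2]])) {
          pt <- mids; pt[pr[1]] <- v1; pt[pr[2]] <- v2
          rows[[length(rows) + 1L]] <- pt
        }
  }
  corners <- as.matrix(expand.grid(lapply(seq_along(factors), function(j)
    c(lows[j], highs[j]))))
  rows <- c(rows, lapply(seq_len(nrow(corners)),
                         function(i) corners[i, ]))
  if (!length(rows)) rows <- list(mids)
  out <- do.call(rbind, rows)
  colnames(out) <- names(lows)
  out
}

# Information score of a design: log-determinant of X'X for the full
# candidate-effect model encoded on factors range-scaled to [-1, 1]
# (ordinal levels are kept, so indicator encoding still applies). -Inf for
# a singular or degenerate matrix.
design_information_score <- function(tab, factors, effects) {
  scaled <- lapply(factors, function(fs) {
    if (fs$kind == "ordinal") fs
    else factor_spec(fs$name, "continuous", fs$unit, -1, 1)
  })
  names(scaled) <- factor_names(factors)
  df <- as.data.frame(tab)
  for (fs in factors) if (fs$kind == "continuous")
    df[[fs$name]] <- (df[[fs$name]] - fs$low) / (fs$high - fs$low) * 2 - 1
  centering <- effect_centering(df, effects, scaled)
  X <- cbind(1, encode_effect_columns(df, effects, centering, scaled))
  if (nrow(X) < ncol(X)) return(-Inf)
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

# logical mask of structurally confounded pairs: a continuous factor's
# linear term vs its interaction with an ordinal factor
confounded_pairs <- function(effects, factors) {
  kinds <- vapply(factors, `[[`, "", "kind")
  ord <- factor_names(factors)[kinds == "ordinal"]
  labs <- term_labels(effects)
  m <- matrix(FALSE, length(effects), length(effects),
              dimnames = list(labs, labs))
  for (i in seq_along(effects)) {
    tm <- effects[[i]]
    if (tm$form == "interaction" && any(tm$factors %in% ord)) {
      partner <- setdiff(tm$factors, ord)
      j <- which(labs == partner)
      if (length(j)) { m[i, j] <- TRUE; m[j, i] <- TRUE }
    }
  }
  m
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %d runs x %d factors (%d center points, %d replicate groups)\n",
              nrow(x), length(attr(x, "factors")), sum(x$is_center),
              max(x$replicate_group)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more runs\n")
  invisible(x)
}

#' Pairwise correlations between encoded effect columns
#'
#' Pearson correlations between every pair of encoded effect columns, with
#' pairs exceeding a threshold flagged. On a well-spread design the main
#' effects are near-orthogonal, but each continuous factor correlates around
#' 1/sqrt(2) with its own interaction with a balanced two-level ordinal
#' factor -- an artifact of the indicator encoding, not a design flaw.
#'
#' @param design A \code{doe_design} (or plain data.frame of factor columns
#'   with a factor list in \code{factors}).
#' @param effects List of \code{\link{effect_term}}s; defaults to all
#'   candidate effects.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @param factors Factor list; defaults to the design attribute.
#' @return List with the correlation matrix \code{r} (entries for constant
#'   columns are \code{NA} and listed in \code{undefined}), a data.frame
#'   \code{flagged} of pairs with \code{|r| > threshold}, and the threshold.
#' @export
effect_correlations <- function(design, effects = NULL, threshold = 0.50,
                                factors = attr(design, "factors")) {
  if (is.null(factors)) stop("no factor specifications supplied", call. = FALSE)
  if (is.null(effects)) effects <- enumerate_candidate_effects(factors)
  df <- as.data.frame(design)
  centering <- effect_centering(df, effects, factors)
  X <- encode_effect_columns(df, effects, centering, factors)
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  ut <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(effect_1 = colnames(r)[ut[, 2]],
                        effect_2 = rownames(r)[ut[, 1]],
                        r = r[ut], abs_r = abs(r[ut]))
  flagged <- flagged[order(-flagged$abs_r), ]
  rownames(flagged) <- NULL
  list(r = r, flagged = flagged, undefined = colnames(X)[sds == 0],
       threshold = threshold)
}

#' Read or write a design table as CSV
#'
#' The file has a header \code{run_id} followed by one column per factor
#' (the ordinal CO2 factor is stored as its numeric level), UTF-8 encoded
#' with '.' as decimal separator.
#'
#' @param design A \code{doe_design}.
#' @param path File path.
#' @param factors Factor list used to validate and annotate the table read.
#' @return \code{read_design} returns a \code{doe_design} with
#'   \code{replicate_group} and \code{is_center} recomputed.
#' @export
write_design <- function(design, path) {
  nms <- factor_names(attr(design, "factors"))
  utils::write.csv(as.data.frame(design)[, c("run_id", nms)], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, factors = default_factors()) {
  nms <- check_factor_list(factors)
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("run_id", nms), names(tab))
  if (length(missing_cols))
    stop("design file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (f in factors) {
    x <- tab[[f$name]]
    if (f$kind == "ordinal") {
      if (!all(x %in% f$levels))
        stop("ordinal factor '", f$name, "' has values outside its levels",
             call. = FALSE)
    } else if (any(x < f$low | x > f$high)) {
      stop("factor '", f$name, "' has values outside [", f$low, ", ",
           f$high, "]", call. = FALSE)
    }
  }
  vals <- tab[, nms, drop = FALSE]
  key <- do.call(paste, c(vals, sep = "\r"))
  mids <- vapply(factors, function(f) (f$low + f$high) / 2, 0)
  kinds <- vapply(factors, `[[`, "", "kind")
  is_center_row <- rep(TRUE, nrow(tab))
  for (j in which(kinds == "continuous"))
    is_center_row <- is_center_row & vals[[j]] == mids[j]
  out <- cbind(tab[, c("run_id", nms)],
               replicate_group = match(key, unique(key)),
               is_center = is_center_row)
  structure(out, factors = factors, class = c("doe_design", "data.frame"))
}
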