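#' Forward stepwise selection by minimum AICc with effect heredity
#'
#' Starting from the intercept-only model, the candidate whose addition
#' yields the lowest AICc is added greedily until no addition lowers the
#' criterion. Adding a second-order term implicitly brings any absent parent
#' linear term along (the "combine" heredity rule), and the AICc of the
#' combined addition is what is scored. Ties are broken in favour of the
#' lower-order term, then by candidate enumeration order.
#'
#' @param design A \code{doe_design} or data.frame of factor columns.
#' @param y Response vector aligned with the design rows; \code{NA} rows are
#'   dropped (centering constants are computed on the rows kept).
#' @param candidates List of \code{\link{effect_term}}s.
#' @param response Response name recorded in the resulting specification.
#' @param fit_rows Row subset to fit on; defaults to the non-missing rows.
#' @param factors Factor list; defaults to the design attribute.
#' @return A \code{selection_trace}: list with \code{steps} (one row per
#'   action: term label, AICc, R2, reason), \code{final_spec},
#'   \code{centering}, and \code{round = 1}.
#' @export
stepwise_forward <- function(design, y, candidates, response = "y",
                             fit_rows = NULL, factors = attr(design, "factors")) {
  if (is.null(factors)) stop("no factor specifications supplied", call. = FALSE)
  if (!length(candidates)) stop("no candidate effects", call. = FALSE)
  if (is.null(fit_rows)) fit_rows <- which(!is.na(y))
  yv <- y[fit_rows]
  n <- length(yv)
  if (n < 3) stop("too few rows to fit", call. = FALSE)

  df <- as.data.frame(design)
  centering <- effect_centering(df, candidates, factors, fit_rows)
  C <- encode_effect_columns(df, candidates, centering, factors, fit_rows)
  labs <- colnames(C)
  usable <- apply(C, 2, function(col) max(col) > min(col))

  # parents (by candidate index) each second-order candidate drags along
  parent_idx <- lapply(candidates, function(tm) {
    if (tm$order == 1L) return(integer(0))
    idx <- match(vapply(parent_terms(tm), `[[`, "", "label"), labs)
    idx[!is.na(idx)]
  })

  orders <- vapply(candidates, `[[`, 0L, "order")
  eval_order <- order(orders, seq_along(candidates))

  current <- integer(0)
  cur_sse <- sum((yv - mean(yv))^2)
  cur_aicc <- aicc_value(n, 0L, cur_sse)
  steps <- list(data.frame(action = "start", term = "(Intercept)",
                           aicc = cur_aicc, r2 = 0, reason = "intercept-only"))
  ss_total <- cur_sse
  repeat {
    best <- NULL
    for (ci in eval_order) {
      if (ci %in% current || !usable[ci]) next
      add <- setdiff(c(parent_idx[[ci]], ci), current)
      add <- add[usable[add]]
      cols <- c(current, add)
      if (n <= length(cols) + 1L) next
      X <- cbind(1, C[, cols, drop = FALSE])
      z <- suppressWarnings(stats::lm.fit(X, yv))
      if (z$rank < ncol(X)) next
      a <- aicc_value(n, length(cols), sum(z$residuals^2))
      if (is.null(best) || a < best$aicc) {
        best <- list(ci = ci, add = add, aicc = a,
                     sse = sum(z$residuals^2))
      }
    }
    if (is.null(best) || best$aicc >= cur_aicc) {
      if (is.null(best) && !length(current))
        warning("no candidate could be added (all singular or constant); ",
                "returning the empty model", call. = FALSE)
      break
    }
    current <- c(current, best$add)
    cur_aicc <- best$aicc
    steps[[length(steps) + 1L]] <- data.frame(
      action = "add", term = labs[best$ci], aicc = cur_aicc,
      r2 = if (ss_total > 0) 1 - best$sse / ss_total else NA_real_,
      reason = if (length(best$add) > 1L)
        paste("with parent(s):",
              paste(labs[setdiff(best$add, best$ci)], collapse = ", "))
      else "lowest AICc")
  }
  steps[[length(steps) + 1L]] <- data.frame(
    action = "stop", term = NA_character_, aicc = cur_aicc,
    r2 = steps[[length(steps)]]$r2,
    reason = "no addition lowers AICc")
  structure(list(steps = do.call(rbind, steps),
                 final_spec = model_spec(response, candidates[current]),
                 centering = centering, round = 1L, fit_rows = fit_rows),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> round %d, %d final term(s)\n", x$round,
              length(x$final_spec$terms)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Backward pruning by descending p-value with a lack-of-fit / R2 stopping
#' rule
#'
#' The term with the highest deprivation-ANOVA p-value is tentatively
#' removed; if the reduced fit shows a significant lack-of-fit test
#' (p <= alpha) or an R2 below the floor, the removal is rejected and
#' pruning stops. The floor is \code{r2_floor} when the starting model
#' reaches it, otherwise the starting R2 minus \code{slack} (so responses
#' that never fit well, like NPQ, are pruned against their own attainable
#' R2). Ties on p remove the higher-order term first. After pruning, linear
#' parents of any retained second-order term are restored, so the final
#' model respects effect heredity.
#'
#' @param design A \code{doe_design} or data.frame of factor columns.
#' @param y Response vector aligned with the design rows.
#' @param round1_spec \code{\link{model_spec}} from the forward round.
#' @param r2_floor R2 floor of the stopping rule.
#' @param slack Subtracted from the starting R2 when it is below the floor.
#' @param alpha Significance cutoff for the lack-of-fit test.
#' @param fit_rows Row subset; defaults to the non-missing rows.
#' @param factors Factor list; defaults to the design attribute.
#' @return A \code{selection_trace} with \code{round = 2}.
#' @export
backward_prune <- function(design, y, round1_spec, r2_floor = 0.60,
                           slack = 0.05, alpha = 0.05, fit_rows = NULL,
                           factors = attr(design, "factors")) {
  if (is.null(factors)) stop("no factor specifications supplied", call. = FALSE)
  if (is.null(fit_rows)) fit_rows <- which(!is.na(y))
  response <- round1_spec$response

  refit <- function(terms) {
    spec <- model_spec(response, terms, centering = round1_spec$centering)
    mm <- build_model_matrix(design, spec, fit_rows, factors)
    fit_ols(mm, y[fit_rows], diagnostics = TRUE, design = design)
  }

  terms <- round1_spec$terms
  if (!length(terms))
    return(structure(list(steps = data.frame(action = "stop", term = NA,
                                             aicc = NA_real_, r2 = NA_real_,
                                             lof_p = NA_real_,
                                             reason = "empty starting model"),
                          final_spec = round1_spec, round = 2L,
                          fit_rows = fit_rows),
                     class = "selection_trace"))
  fit <- refit(terms)
  floor_r2 <- if (!is.na(fit$r2) && fit$r2 >= r2_floor) r2_floor
              else max(fit$r2 - slack, 0)
  lof_p0 <- if (!is.null(fit$lof) && fit$lof$available) fit$lof$p else NA_real_
  steps <- list(data.frame(action = "start", term = NA_character_,
                           aicc = fit$aicc, r2 = fit$r2, lof_p = lof_p0,
                           reason = sprintf("R2 floor = %.3g", floor_r2)))
  add_step <- function(action, term, fit, reason) {
    lp <- if (!is.null(fit$lof) && fit$lof$available) fit$lof$p else NA_real_
    steps[[length(steps) + 1L]] <<- data.frame(
      action = action, term = term, aicc = fit$aicc, r2 = fit$r2,
      lof_p = lp, reason = reason)
  }

  while (length(terms)) {
    p <- fit$effect_p[term_labels(terms)]
    ord <- vapply(terms, `[[`, 0L, "order")
    victim <- order(-p, -ord)[1]
    kept <- terms[-victim]
    tent <- if (length(kept)) refit(kept) else {
      mm0 <- build_model_matrix(design, model_spec(response, list()),
                                fit_rows, factors)
      fit_ols(mm0, y[fit_rows], diagnostics = FALSE, design = design)
    }
    lof_ok <- is.null(tent$lof) || !tent$lof$available || tent$lof$p > alpha
    r2_ok <- !is.na(tent$r2) && tent$r2 >= floor_r2
    if (!lof_ok || !r2_ok) {
      add_step("stop", terms[[victim]]$label, fit, paste0(
        "removal of ", terms[[victim]]$label, " rejected: ",
        paste(c(if (!lof_ok) sprintf("lack-of-fit p = %.4g <= %.3g",
                                     tent$lof$p, alpha),
                if (!r2_ok) sprintf("R2 = %.3g < floor %.3g",
                                    tent$r2, floor_r2)),
              collapse = " and ")))
      break
    }
    add_step("remove", terms[[victim]]$label, tent,
             sprintf("highest p = %.4g", p[victim]))
    terms <- kept
    fit <- tent
    if (!length(terms)) {
      add_step("stop", NA_character_, fit, "model emptied")
      break
    }
  }

  # heredity repair: restore linear parents of retained second-order terms
  labs <- term_labels(terms)
  for (tm in terms) {
    for (pt in parent_terms(tm)) {
      if (!(pt$label %in% labs)) {
        terms <- c(terms, list(pt)); labs <- c(labs, pt$label)
        fit <- refit(terms)
        add_step("add", pt$label, fit,
                 paste("heredity: parent of", tm$label))
      }
    }
  }
  structure(list(steps = do.call(rbind, steps),
                 final_spec = model_spec(response, terms,
                                         centering = round1_spec$centering),
                 round = 2L, fit_rows = fit_rows),
            class = "selection_trace")
}

#' Run the two-round selection on every response
#'
#' Per response: missing rows are dropped and centering constants recomputed
#' on the rows kept; round 1 screens all candidate effects by AICc forward
#' stepwise with heredity; round 2 prunes the round-1 model by descending
#' p-value under the lack-of-fit / R2 stopping rule. The result carries, for
#' each response, both rounds' traces and fully diagnosed fits, a report
#' table of the final effects ordered by ascending p-value, and the set of
#' distinct environmental factors retained.
#'
#' @param design A \code{doe_design}.
#' @param responses Data.frame with \code{run_id} and one column per
#'   response; blanks are missing measurements.
#' @param config Named list overriding \code{alpha} (0.05), \code{r2_floor}
#'   (0.60), \code{slack} (0.05) and \code{min_rows} (10, below which a
#'   response is skipped with a warning).
#' @param factors Factor list; defaults to the design attribute.
#' @return An object of class \code{two_round_result}.
#' @export
run_two_round <- function(design, responses, config = list(),
                          factors = attr(design, "factors")) {
  cfg <- utils::modifyList(list(alpha = 0.05, r2_floor = 0.60, slack = 0.05,
                                min_rows = 10L), config)
  stopifnot("run_id" %in% names(responses))
  resp_names <- setdiff(names(responses), "run_id")
  if (!length(resp_names)) stop("no response columns", call. = FALSE)
  candidates <- enumerate_candidate_effects(factors)
  idx <- match(design$run_id, responses$run_id)

  out <- list()
  for (resp in resp_names) {
    y <- responses[[resp]][idx]
    fit_rows <- which(!is.na(y))
    if (length(fit_rows) < cfg$min_rows) {
      warning("response '", resp, "' has only ", length(fit_rows),
              " measured rows (< ", cfg$min_rows, "); skipped", call. = FALSE)
      next
    }
    constant <- stats::var(y[fit_rows]) == 0
    tr1 <- stepwise_forward(design, y, candidates, response = resp,
                            fit_rows = fit_rows, factors = factors)
    fit1 <- fit_spec(design, tr1$final_spec, y, fit_rows, factors)
    tr2 <- backward_prune(design, y, tr1$final_spec, r2_floor = cfg$r2_floor,
                          slack = cfg$slack, alpha = cfg$alpha,
                          fit_rows = fit_rows, factors = factors)
    fit2 <- fit_spec(design, tr2$final_spec, y, fit_rows, factors)
    out[[resp]] <- list(
      response = resp, n = length(fit_rows), constant = constant,
      round1 = tr1, fit1 = fit1, round2 = tr2, fit2 = fit2,
      table = effect_table(fit2, cfg$alpha),
      factors_final = sort(unique(unlist(lapply(tr2$final_spec$terms,
                                                `[[`, "factors")))))
  }
  structure(list(responses = out, config = cfg), class = "two_round_result")
}

# full-diagnostics fit of a spec (handles the empty model)
fit_spec <- function(design, spec, y, fit_rows, factors) {
  mm <- build_model_matrix(design, spec, fit_rows, factors)
  fit_ols(mm, y[fit_rows], diagnostics = length(spec$terms) > 0,
          design = design)
}

effect_table <- function(fit, alpha = 0.05) {
  if (fit$k == 0)
    return(data.frame(term = character(), estimate = numeric(),
                      beta = numeric(), p = numeric(),
                      significant = logical()))
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    beta = unname(fit$beta[names(fit$coefficients)]),
                    p = unname(fit$effect_p[names(fit$coefficients)]))
  tab <- tab[order(tab$p), ]
  tab$significant <- tab$p <= alpha
  rownames(tab) <- NULL
  tab
}

#' @export
print.two_round_result <- function(x, ...) {
  cat(sprintf("<two_round_result> %d response(s)\n", length(x$responses)))
  for (r in x$responses) {
    cat(sprintf("\n== %s (n = %d) ==\n", r$response, r$n))
    cat(sprintf("round 1: %d term(s), R2 = %.3f | round 2: %d term(s), R2 = %.3f\n",
                r$fit1$k, r$fit1$r2, r$fit2$k, r$fit2$r2))
    if (nrow(r$table)) {
      tab <- r$table
      tab$p <- vapply(tab$p, format_p, "")
      print(tab, row.names = FALSE)
    } else cat("no effects retained\n")
    cat("final factors:", if (length(r$factors_final))
      paste(r$factors_final, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}
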