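#' Evaluate an event expression numerically
#'
#' The value of an expression is the sum over its terms of the rational
#' coefficient times the product of the named parameters: `a`-entries for
#' causal-function events, prior entries for root-cause events; default
#' causes contribute factor 1.  Weighted expansion makes terms additive
#' (parent weights sum to 1), so no inclusion-exclusion is applied.  A
#' parameter that is actually needed but unknown raises a
#' missing-parameter error naming it; parameters not appearing in the
#' expression are never touched (self-reliance).
#'
#' @param expr a [ducg_expression].
#' @param model a [ducg_model()] supplying parameters.
#' @return a probability (numeric scalar).
#' @export
eval_expression <- function(expr, model) {
  total <- 0
  for (t in expr$terms) {
    v <- t$num / t$den
    for (ev in t$a) {
      arc <- model_arc(model, ev$parent, ev$child)
      if (is.null(arc))
        ducg_abort(paste0("no arc ", ev$parent, "->", ev$child), "ducg_internal_error")
      aval <- if (var_kind(ev$parent) == "D") arc$a[ev$k + 1L, 1L]
      else arc$a[ev$k + 1L, ev$j + 1L]
      if (is.na(aval))
        ducg_abort(paste0("missing parameter ",
                          param_name_a(ev$child, ev$k, ev$parent, ev$j)),
                   "ducg_missing_parameter",
                   parameter = param_name_a(ev$child, ev$k, ev$parent, ev$j))
      v <- v * aval
    }
    for (key in t$bd) {
      if (var_kind(key) == "D") next
      p <- lit_parse(key)
      b <- model$priors[[p$var]]
      bv <- if (is.null(b)) NA_real_ else b[p$state + 1L]
      if (is.na(bv) && p$state == 0L && !is.null(b) && !anyNA(b[-1L]))
        bv <- 1 - sum(b[-1L])
      if (is.na(bv))
        ducg_abort(paste0("missing parameter ", param_name_b(p$var, p$state)),
                   "ducg_missing_parameter",
                   parameter = param_name_b(p$var, p$state))
      v <- v * bv
    }
    total <- total + v
  }
  total
}

# Pr{H * E}: conjoin the hypothesis events onto every term of E's
# in-context expansion (idempotent when a term already contains them).
expr_with_hypothesis <- function(expr, hyp) {
  terms <- list()
  for (t in expr$terms) {
    for (v in names(hyp)) {
      t <- term_add_bd(t, v, hyp[[v]])
      if (is.null(t)) break
    }
    if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  }
  reduce_expression(new_expression(terms, context = expr$context))
}

#' Hypothesis state probabilities
#'
#' For each candidate context `k` the engine evaluates
#' `zeta_k = Pr{E}` (the prior probability of the evidence in that
#' context) and the per-context state probability
#' `h_k = Pr{H_k E} / Pr{E}`; the final weighted state probability is
#' proportional to `h_k * zeta_k`, normalized over the hypothesis space
#' (when every per-context `h` is 1 — the hypothesis is its context's
#' sole root cause — this is exactly the zeta-weighted normalization).
#'
#' @param contexts named list of `ducg_context` objects (names are the
#'   hypothesis event keys), e.g. from [build_hypothesis_space()].
#' @param evidence a [ducg_evidence()].
#' @param model a [ducg_model()].
#' @param expressions optional named list of precomputed in-context
#'   evidence expansions.
#' @return a data frame with columns `event`, `zeta`, `h_context`, `h`,
#'   plus attribute `expressions`.
#' @export
compute_state_probabilities <- function(contexts, evidence, model,
                                        expressions = NULL) {
  if (!length(contexts))
    ducg_abort("no contexts to evaluate", "ducg_usage_error")
  events <- names(contexts)
  zeta <- numeric(length(contexts))
  hctx <- numeric(length(contexts))
  exprs <- list()
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    ee <- expressions[[events[[i]]]] %||% expand_evidence_product(evidence, ctx)
    exprs[[events[[i]]]] <- ee
    zeta[[i]] <- eval_expression(ee, ctx$model)
    if (zeta[[i]] > 0) {
      he <- expr_with_hypothesis(ee, ctx$hyp)
      hctx[[i]] <- eval_expression(he, ctx$model) / zeta[[i]]
    }
  }
  if (all(zeta <= 0))
    ducg_abort("evidence has zero probability under every hypothesis",
               "ducg_degenerate_evidence")
  w <- hctx * zeta
  res <- data.frame(event = events, zeta = zeta, h_context = hctx,
                    h = w / sum(w))
  ord <- order(vapply(res$event, function(e) var_index(lit_parse(e)$var),
                      integer(1)),
               vapply(res$event, function(e) lit_parse(e)$state, integer(1)))
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "expressions") <- exprs
  res
}

#' Ranked independent probabilities of a composed hypothesis
#'
#' Quantifies, for each constituent of a composed (concurrent) hypothesis,
#' the confidence that it alone explains all the evidence: each
#' constituent's state probability is computed on its own individual
#' causality-tracking context, and the results are normalized to sum to 1.
#'
#' @param composed a `ducg_hypothesis` (or character vector of event keys).
#' @param contexts named list of the constituents' individual contexts.
#' @inheritParams compute_state_probabilities
#' @return named numeric vector (ordered by variable index, summing to 1).
#' @export
ranked_independent_probabilities <- function(composed, contexts, evidence,
                                             model, expressions = NULL) {
  events <- as.character(composed)
  ord <- order(vapply(events, function(e) var_index(lit_parse(e)$var), integer(1)))
  events <- events[ord]
  tab <- compute_state_probabilities(contexts[events], evidence, model,
                                     expressions = expressions)
  raw <- stats::setNames(tab$h_context * tab$zeta, tab$event)[events]
  raw / sum(raw)
}

#' Run the full differential-diagnostic reasoning pipeline
#'
#' Orchestrates simplification, causality tracking and pruning, exclusive
#' category resolution through dummy basic variables, concurrent
#' hypothesis composition, evidence expansion, probability evaluation and
#' ranking:
#' \enumerate{
#'   \item build the hypothesis space (candidates that can reach all
#'     abnormal evidence and jointly explain it);
#'   \item if the model declares category sets, resolve any exclusive
#'     category retaining several candidates by DBV state ranking, compose
#'     the surviving candidates into the maximal concurrent hypothesis,
#'     and compute the constituents' ranked independent probabilities;
#'   \item otherwise rank the candidates as alternative hypotheses by
#'     their zeta-weighted state probabilities.
#' }
#'
#' @inheritParams track_causality
#' @return an object of class `ducg_diagnosis`.
#' @export
diagnose <- function(model, evidence) {
  obs <- check_evidence(model, evidence)
  space <- build_hypothesis_space(model, obs)
  res <- structure(
    list(status = space$status, evidence = obs, hypothesis_space = space,
         state_probabilities = NULL, composed = NULL, composed_h = NULL,
         ranked = NULL, dbv = list(), model = model),
    class = "ducg_diagnosis"
  )
  if (space$status != "ok") return(res)
  if (!nrow(space$candidates)) {
    res$status <- "empty_hypothesis_space"
    return(res)
  }

  categorized <- length(model$categories$exclusive) > 0 ||
    length(model$categories$concurrent) > 0
  res$state_probabilities <-
    compute_state_probabilities(space$contexts, obs, model,
                                expressions = space$expressions)

  if (!categorized) {
    res$mode <- "alternatives"
    return(res)
  }

  # resolve exclusive categories with several surviving candidates
  cand <- space$candidates
  survivors <- character(0)
  for (cat in unique(cand$category[!is.na(cand$category) &
                                   startsWith(cand$category, "exclusive")])) {
    members <- cand$event[!is.na(cand$category) & cand$category == cat]
    if (length(members) == 1L) { survivors <- c(survivors, members); next }
    dbv <- build_dbv(members, model)
    dcontexts <- list()
    for (s in names(dbv$state_map)) {
      key <- lit_key(dbv$variable, as.integer(s))
      ctx <- track_causality(dbv$model, obs, stats::setNames(as.integer(s),
                                                             dbv$variable))
      if (!is.null(ctx)) dcontexts[[key]] <- ctx
    }
    dtab <- compute_state_probabilities(dcontexts, obs, dbv$model)
    dtab$original <- dbv$state_map[vapply(dtab$event, function(e)
      as.character(lit_parse(e)$state), character(1))]
    res$dbv[[cat]] <- list(variable = dbv$variable, table = dtab,
                           state_map = dbv$state_map)
    best <- dtab$original[order(-dtab$h,
                                vapply(dtab$original, function(e)
                                  var_index(lit_parse(e)$var), integer(1)))][1]
    survivors <- c(survivors, best)
  }
  survivors <- c(survivors,
                 cand$event[is.na(cand$category) | cand$category == "concurrent"])

  res$mode <- "composed"
  res$composed <- compose_concurrent_hypothesis(survivors)
  # the maximal concurrent hypothesis is the unique element of the final
  # hypothesis space; normalized over that space its state probability is 1
  res$composed_h <- 1
  res$ranked <- ranked_independent_probabilities(
    res$composed, space$contexts[as.character(res$composed)], obs, model,
    expressions = space$expressions)
  res
}

#' @export
print.ducg_diagnosis <- function(x, digits = 3, ...) {
  cat("<ducg_diagnosis> status:", x$status, "\n")
  if (x$status != "ok") return(invisible(x))
  if (!is.null(x$composed)) {
    cat("  composed hypothesis:", paste(unclass(x$composed), collapse = " * "),
        " (h =", format(round(x$composed_h, digits)), ")\n")
    cat("  ranked independent probabilities:\n")
    for (e in names(x$ranked))
      cat("    ", e, ": ", format(round(x$ranked[[e]], 4)), "\n", sep = "")
  } else {
    cat("  hypothesis state probabilities:\n")
    tab <- x$state_probabilities
    for (i in seq_len(nrow(tab)))
      cat("    ", tab$event[[i]], ": h = ", format(round(tab$h[[i]], digits)),
          " (zeta = ", format(tab$zeta[[i]], digits = 6), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.ducg_diagnosis <- function(x, ...) {
  if (is.null(x$state_probabilities))
    return(data.frame(event = character(0), zeta = numeric(0),
                      h_context = numeric(0), h = numeric(0)))
  tab <- x$state_probabilities
  attr(tab, "expressions") <- NULL
  tab
}

#' Assemble a machine-readable diagnosis report
#'
#' @param x a `ducg_diagnosis` from [diagnose()].
#' @param path optional path; when given, the report is written as JSON.
#' @return the report list, invisibly when written to a file.
#' @export
diagnosis_report <- function(x, path = NULL) {
  tab <- x$state_probabilities
  report <- list(
    schema_version = 1L,
    status = x$status,
    evidence = as.list(stats::setNames(as.integer(x$evidence), names(x$evidence))),
    candidates = if (!is.null(tab)) lapply(seq_len(nrow(tab)), function(i) list(
      event = tab$event[[i]], zeta = tab$zeta[[i]],
      h_context = tab$h_context[[i]], h = round(tab$h[[i]], 3),
      h_full = tab$h[[i]]
    )) else list(),
    composed_hypothesis = if (!is.null(x$composed))
      list(events = as.character(x$composed), h = x$composed_h),
    ranked_independent = if (!is.null(x$ranked))
      as.list(round(x$ranked, 4)),
    expressions = if (!is.null(tab))
      lapply(attr(tab, "expressions"), expr_canonical)
  )
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), path)
    return(invisible(report))
  }
  report
}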