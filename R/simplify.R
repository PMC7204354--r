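#' @name causality-tracking
#' @title Evidence-driven simplification and causality tracking
#'
#' @description
#' Given observed evidence, the engine prunes the causality graph before
#' any probability is computed.  Causality tracking starts from each
#' abnormal observation and walks its causal chains upstream toward the
#' candidate root cause.  A chain link survives only if the causal-function
#' entry for the required child/parent states is not an explicit zero
#' (unknown entries keep the chain viable), the parent state is compatible
#' with the observations, and the parent itself is grounded — i.e. it
#' eventually reaches the hypothesis root cause or a default-cause (D)
#' variable.  Abnormal events are never attributed to a parent's normal
#' state: state-0 columns are not consulted when explaining abnormality.
#'
#' A B-state event is a candidate hypothesis only if every abnormal
#' observation is grounded in its context, at least one observation
#' actually reaches the B event itself, and the in-context symbolic
#' expansion of the evidence has at least one surviving term (chains that
#' are individually viable can still force contradictory states on a
#' shared ancestor; such candidates cannot jointly explain the evidence).
#'
#' Within a context, arc weights are renormalized over the parents kept
#' for each child event: `r'_n = sum of r over kept parents`.
NULL

# Build a tracking context for a hypothesis (named integer vector of
# B variables -> states, usually length 1).  Contexts carry memoized
# grounding results and renormalized weights.
new_context <- function(model, observations, hypothesis) {
  ctx <- new.env(parent = emptyenv())
  ctx$model <- model
  ctx$obs <- observations
  ctx$hyp <- hypothesis
  ctx$memo <- new.env(parent = emptyenv())
  class(ctx) <- "ducg_context"
  ctx
}

#' @export
print.ducg_context <- function(x, ...) {
  cat("<ducg_context> hypothesis:",
      paste0(names(x$hyp), ",", x$hyp, collapse = " "), "\n")
  invisible(x)
}

# All products defining a gate state; state 0 (the remnant) is computed as
# the complement of the nonzero-state expressions over the full input
# assignment space.  Products that are supersets of other products are
# absorbed (X + XY = X).
gate_state_products <- function(model, gate_id, state) {
  g <- model$gates[[gate_id]]
  if (is.null(g))
    ducg_abort(paste0("no gate specification for ", gate_id), "ducg_validation_error")
  if (state > 0L) {
    prods <- g$state_exprs[[as.character(state)]] %||% list()
    return(absorb_products(prods))
  }
  # remnant: enumerate input assignments not matched by any nonzero state
  ns <- model$n_states[g$inputs]
  total <- prod(ns)
  if (total > 4096)
    ducg_abort(paste0("gate ", gate_id, " remnant enumeration too large"),
               "ducg_size_error")
  combos <- expand.grid(lapply(ns, function(n) 0:(n - 1L)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- g$inputs
  matched <- rep(FALSE, nrow(combos))
  for (s in names(g$state_exprs)) {
    for (p in g$state_exprs[[s]]) {
      hit <- rep(TRUE, nrow(combos))
      for (vn in names(p)) hit <- hit & combos[[vn]] == p[[vn]]
      matched <- matched | hit
    }
  }
  lapply(which(!matched), function(i) {
    v <- as.integer(combos[i, , drop = TRUE])
    names(v) <- g$inputs
    v
  })
}

absorb_products <- function(prods) {
  if (length(prods) < 2L) return(prods)
  keep <- rep(TRUE, length(prods))
  for (i in seq_along(prods)) {
    for (j in seq_along(prods)) {
      if (i == j || !keep[i] || !keep[j]) next
      pi <- prods[[i]]; pj <- prods[[j]]
      if (length(pj) <= length(pi) && i != j &&
          all(names(pj) %in% names(pi)) &&
          all(pi[names(pj)] == pj) && length(pj) < length(pi)) {
        keep[i] <- FALSE   # pi is a superset of pj: absorbed
      }
    }
  }
  prods[keep]
}

# Evaluate deterministically which gate state an input assignment yields.
gate_state_of <- function(model, gate_id, input_states) {
  g <- model$gates[[gate_id]]
  hits <- integer(0)
  for (s in names(g$state_exprs)) {
    for (p in g$state_exprs[[s]]) {
      if (all(input_states[names(p)] == p)) { hits <- c(hits, as.integer(s)); break }
    }
  }
  hits <- unique(hits)
  if (length(hits) > 1L)
    ducg_abort(paste0("gate ", gate_id, " state expressions overlap"),
               "ducg_validation_error")
  if (length(hits)) hits else 0L
}

# Grounding: can event (var, state) occur as part of a causal explanation
# in this context?  Returns list(ok, via_b): via_b marks that some viable
# branch reaches a hypothesis B event (as opposed to a default cause only).
ground_event <- function(ctx, var, state) {
  key <- lit_key(var, state)
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  model <- ctx$model
  kind <- var_kind(var)
  res <- if (kind == "B") {
    h <- ctx$hyp[var]
    list(ok = !is.na(h) && h == state, via_b = TRUE)
  } else if (kind == "D") {
    list(ok = state == 0L, via_b = FALSE)
  } else if (kind == "G") {
    ground_gate(ctx, var, state)
  } else {
    ground_x(ctx, var, state)
  }
  ctx$memo[[key]] <- res
  res
}

ground_gate <- function(ctx, var, state) {
  obs <- ctx$obs
  ok <- FALSE; via_b <- FALSE
  for (p in gate_state_products(ctx$model, var, state)) {
    p_ok <- TRUE; p_via <- FALSE
    for (vn in names(p)) {
      s <- p[[vn]]
      if (!is.na(obs[vn]) && obs[vn] != s) { p_ok <- FALSE; break }
      g <- ground_event(ctx, vn, s)
      if (!g$ok) { p_ok <- FALSE; break }
      if (g$via_b) p_via <- TRUE
    }
    if (p_ok) { ok <- TRUE; via_b <- via_b || p_via }
  }
  list(ok = ok, via_b = via_b)
}

ground_x <- function(ctx, var, state) {
  obs <- ctx$obs
  if (!is.na(obs[var]) && obs[var] != state) return(list(ok = FALSE, via_b = FALSE))
  if (state == 0L) {
    # a normal state is a condition, not an effect to be explained
    return(list(ok = TRUE, via_b = FALSE))
  }
  ok <- FALSE; via_b <- FALSE
  for (arc in model_arcs_into(ctx$model, var)) {
    br <- viable_branches(ctx, arc, state)
    if (length(br)) {
      ok <- TRUE
      if (any(vapply(br, function(b) b$via_b, logical(1)))) via_b <- TRUE
    }
  }
  list(ok = ok, via_b = via_b)
}

# Viable (parent state j) branches of one arc for child state k != 0.
viable_branches <- function(ctx, arc, k) {
  model <- ctx$model
  obs <- ctx$obs
  parent <- arc$parent
  pk <- var_kind(parent)
  js <- if (pk == "D") {
    0L
  } else if (pk == "B") {
    h <- ctx$hyp[parent]
    if (is.na(h)) integer(0) else h
  } else if (!is.na(obs[parent])) {
    # abnormal events are never caused by an observed-normal parent
    if (obs[parent] == 0L) integer(0) else obs[parent]
  } else {
    seq_len(model$n_states[[parent]] - 1L)
  }
  out <- list()
  for (j in js) {
    aval <- if (pk == "D") arc$a[k + 1L, 1L] else arc$a[k + 1L, j + 1L]
    if (!is.na(aval) && aval == 0) next    # explicit zero eliminates the state
    g <- ground_event(ctx, parent, j)
    if (!g$ok) next
    out[[length(out) + 1L]] <- list(j = j, via_b = g$via_b)
  }
  out
}

# Kept parents and renormalized rational weights for a child event (n, k).
context_parents <- function(ctx, var, state) {
  arcs <- model_arcs_into(ctx$model, var)
  kept <- list()
  for (arc in arcs) {
    br <- viable_branches(ctx, arc, state)
    if (length(br)) kept[[length(kept) + 1L]] <- list(arc = arc, branches = br)
  }
  if (!length(kept)) return(kept)
  r_sum <- sum(vapply(kept, function(x) x$arc$r, numeric(1)))
  for (i in seq_along(kept)) kept[[i]]$w <- rat(kept[[i]]$arc$r, r_sum)
  kept
}

#' Track the causality context of a candidate root cause
#'
#' Traces every abnormal observation upstream toward the B-state event
#' `b_event` and returns the resulting context subgraph, with arc weights
#' renormalized over the parents retained in the context.  Returns `NULL`
#' when some abnormal observation cannot reach the hypothesis (nor a
#' default cause), or when none reaches the hypothesis at all — such a
#' B event cannot explain the evidence and is eliminated.
#'
#' @param model a [ducg_model()].
#' @param evidence a [ducg_evidence()].
#' @param b_event B-state event key such as `"B2,1"`, or `c(B2 = 1)`;
#'   a conjunction of several B-state events is allowed (a composed
#'   hypothesis).
#' @return a `ducg_context`, or `NULL` if the hypothesis is eliminated.
#' @export
track_causality <- function(model, evidence, b_event) {
  obs <- check_evidence(model, evidence)
  hyp <- parse_hypothesis(b_event)
  for (v in names(hyp)) {
    b <- model$priors[[v]]
    if (!is.null(b) && !is.na(b[hyp[[v]] + 1L]) && b[hyp[[v]] + 1L] == 0)
      return(NULL)                       # zero-prior events cannot occur
  }
  ctx <- new_context(model, obs, hyp)
  abn <- abnormal_evidence(obs)
  if (!length(abn)) return(NULL)
  any_via_b <- FALSE
  for (i in seq_along(abn)) {
    g <- ground_event(ctx, names(abn)[[i]], abn[[i]])
    if (!g$ok) return(NULL)
    if (g$via_b) any_via_b <- TRUE
  }
  if (!any_via_b) return(NULL)
  ctx
}

parse_hypothesis <- function(b_event) {
  if (is.character(b_event)) {
    parsed <- lapply(b_event, lit_parse)
    hyp <- vapply(parsed, function(p) p$state, integer(1))
    names(hyp) <- vapply(parsed, function(p) p$var, character(1))
  } else {
    hyp <- vapply(b_event, as.integer, integer(1))
    names(hyp) <- names(b_event)
  }
  for (v in names(hyp)) {
    if (var_kind(v) != "B")
      ducg_abort(paste0("hypothesis event on non-B variable ", v), "ducg_usage_error")
  }
  hyp
}

# Walk the context from the abnormal evidence, collecting kept variables,
# arcs, per-child-event weights and forced states.
context_subgraph <- function(ctx) {
  model <- ctx$model
  abn <- abnormal_evidence(ctx$obs)
  kept_arcs <- character(0)
  weights <- list()
  states_seen <- list()
  visited <- character(0)
  visit <- function(var, state) {
    key <- lit_key(var, state)
    if (key %in% visited) return(invisible(NULL))
    visited <<- c(visited, key)
    states_seen[[var]] <<- union(states_seen[[var]], state)
    kind <- var_kind(var)
    if (kind %in% c("B", "D")) return(invisible(NULL))
    if (kind == "G") {
      for (p in gate_state_products(model, var, state)) {
        ok <- all(vapply(names(p), function(vn) {
          !(!is.na(ctx$obs[vn]) && ctx$obs[vn] != p[[vn]]) &&
            ground_event(ctx, vn, p[[vn]])$ok
        }, logical(1)))
        if (ok) for (vn in names(p)) visit(vn, p[[vn]])
      }
      return(invisible(NULL))
    }
    if (state == 0L) return(invisible(NULL))
    kept <- context_parents(ctx, var, state)
    wtab <- list()
    for (kp in kept) {
      arc_lab <- paste0(kp$arc$parent, "->", var)
      kept_arcs <<- union(kept_arcs, arc_lab)
      wtab[[kp$arc$parent]] <- kp$w
      for (b in kp$branches) visit(kp$arc$parent, b$j)
    }
    weights[[lit_key(var, state)]] <<- wtab
    invisible(NULL)
  }
  for (i in seq_along(abn)) visit(names(abn)[[i]], abn[[i]])
  vars <- unique(vapply(strsplit(visited, ",", fixed = TRUE),
                        function(p) p[[1]], character(1)))
  forced <- ctx$obs
  for (v in names(states_seen)) {
    if (is.na(forced[v]) && length(states_seen[[v]]) == 1L &&
        var_kind(v) != "D")
      forced[v] <- states_seen[[v]]
  }
  list(
    hypothesis = ctx$hyp,
    kept_variables = sort(vars),
    kept_arcs = sort(kept_arcs),
    renormalized_weights = weights,
    forced_states = forced[!is.na(forced)]
  )
}

#' Renormalized context weights
#'
#' @param ctx a `ducg_context` from [track_causality()].
#' @return list with `kept_variables`, `kept_arcs`,
#'   `renormalized_weights` (per child event, numeric weights by parent)
#'   and `forced_states`.
#' @export
context_summary <- function(ctx) {
  sg <- context_subgraph(ctx)
  sg$renormalized_weights <- lapply(sg$renormalized_weights, function(w)
    vapply(w, rat_value, numeric(1)))
  sg
}

#' Build the candidate hypothesis space
#'
#' Enumerates every B-state event (nonzero state, prior not explicitly
#' zero) whose causality tracking succeeds and whose in-context symbolic
#' evidence expansion has at least one surviving term, and groups the
#' candidates by the model's category sets.
#'
#' @inheritParams track_causality
#' @return an object of class `ducg_hypothesis_space` with elements
#'   `candidates` (data frame: event, variable, state, category),
#'   `contexts`, `expressions`, and `status` (`"ok"` or
#'   `"no_abnormal_evidence"`).
#' @export
build_hypothesis_space <- function(model, evidence) {
  obs <- check_evidence(model, evidence)
  abn <- abnormal_evidence(obs)
  empty <- data.frame(event = character(0), variable = character(0),
                      state = integer(0), category = character(0))
  if (!length(abn)) {
    return(structure(list(candidates = empty, contexts = list(),
                          expressions = list(),
                          status = "no_abnormal_evidence"),
                     class = "ducg_hypothesis_space"))
  }
  bvars <- model$variables$id[model$variables$kind == "B"]
  rows <- list(); contexts <- list(); exprs <- list()
  for (v in bvars) {
    for (s in seq_len(model$n_states[[v]] - 1L)) {
      b <- model$priors[[v]]
      if (!is.null(b) && !is.na(b[s + 1L]) && b[s + 1L] == 0) next
      ctx <- track_causality(model, obs, stats::setNames(s, v))
      if (is.null(ctx)) next
      ee <- expand_evidence_product(obs, ctx)
      if (!length(ee$terms)) next
      key <- lit_key(v, s)
      contexts[[key]] <- ctx
      exprs[[key]] <- ee
      rows[[key]] <- data.frame(event = key, variable = v, state = s,
                                category = event_category(model, key))
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(cand) <- NULL
  structure(list(candidates = cand, contexts = contexts,
                 expressions = exprs, status = "ok"),
            class = "ducg_hypothesis_space")
}

event_category <- function(model, key) {
  for (i in seq_along(model$categories$exclusive)) {
    if (key %in% model$categories$exclusive[[i]]) return(paste0("exclusive", i))
  }
  if (key %in% model$categories$concurrent) return("concurrent")
  NA_character_
}

#' @export
print.ducg_hypothesis_space <- function(x, ...) {
  cat("<ducg_hypothesis_space> status:", x$status, "\n")
  if (nrow(x$candidates)) {
    cat("  candidates:", paste(x$candidates$event, collapse = ", "), "\n")
  } else cat("  no candidates\n")
  invisible(x)
}

#' Simplify a causality graph under evidence
#'
#' Returns a copy of the model in which everything that cannot take part
#' in explaining the abnormal evidence is removed: arcs whose causal
#' entries are explicit zeros for the required states, parent states
#' excluded by observations, variables with no tracked path to any
#' abnormal observation, and gate branches contradicting the
#' observations.  The copy carries attributes `allowed_states` (per
#' variable, the states that can still occur in some explanation) and
#' `evidence`.
#'
#' @inheritParams track_causality
#' @return a simplified `ducg_model` (possibly with no arcs when nothing
#'   explains any abnormal observation).
#' @export
simplify_graph <- function(model, evidence) {
  obs <- check_evidence(model, evidence)
  space <- build_hypothesis_space(model, obs)
  kept_arcs <- character(0)
  kept_vars <- character(0)
  allowed <- lapply(stats::setNames(nm = model$variables$id), function(v) integer(0))
  for (key in names(space$contexts)) {
    ctx <- space$contexts[[key]]
    sg <- context_subgraph(ctx)
    kept_arcs <- union(kept_arcs, sg$kept_arcs)
    kept_vars <- union(kept_vars, sg$kept_variables)
    p <- lit_parse(key)
    allowed[[p$var]] <- union(allowed[[p$var]], p$state)
    for (v in names(sg$forced_states))
      allowed[[v]] <- union(allowed[[v]], sg$forced_states[[v]])
  }
  kept_vars <- union(kept_vars, names(obs))
  for (v in names(obs)) allowed[[v]] <- union(allowed[[v]], obs[[v]])
  m <- model
  m$arcs <- Filter(function(a) paste0(a$parent, "->", a$child) %in% kept_arcs,
                   model$arcs)
  keep_var <- model$variables$id %in% kept_vars
  m$variables <- model$variables[keep_var, ]
  m$gates <- Filter(function(g) g$gate %in% kept_vars, model$gates)
  m$gates <- lapply(m$gates, function(g) {
    g$state_exprs <- lapply(g$state_exprs, function(prods)
      Filter(function(p) {
        all(vapply(names(p), function(vn)
          is.na(obs[vn]) || obs[vn] == p[[vn]], logical(1)))
      }, prods))
    g
  })
  m$priors <- model$priors[names(model$priors) %in% kept_vars]
  m <- index_model(m)
  attr(m, "allowed_states") <- lapply(allowed[kept_vars[kept_vars %in% names(allowed)]],
                                      sort)
  attr(m, "evidence") <- obs
  attr(m, "simplified") <- TRUE
  m
}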