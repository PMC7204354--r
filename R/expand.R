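#' @name event-expansion
#' @title Weighted logic event expansion
#'
#' @description
#' An abnormal event `X(n,k)` expands into the weighted sum over its kept
#' parents `i` and their admissible states `j` of
#' `(r'_{n;i} / r'_n) A(n,k; i,j) V(i,j)`, recursively, until only
#' root-cause (B) and default-cause (D) events remain.  In a diagnostic
#' context, observed parents are fixed to their observed state, B
#' variables to the hypothesis state, gate variables are substituted by
#' their state expressions (products contradicting an observation vanish),
#' and parent-state-0 branches are never used to explain abnormality.
#' Normal-state literals arising inside gate products are conditions: if
#' observed normal they are satisfied silently; if unobserved they expand
#' over all parent states.
#'
#' The expansion works on whole terms: every term carries the set of
#' literals still to be expanded, each literal is expanded exactly once
#' per term (idempotence), and the states implied by the accumulated
#' events must stay consistent (exclusion) or the term vanishes.
NULL

# mode "context": diagnostic expansion inside a tracking context.
# mode "full":    unrestricted expansion of a single event over all parent
#                 states with global weights (used for autonormalization).
expand_terms <- function(model, ctx, init_literals, mode = "context") {
  obs <- if (mode == "context") ctx$obs else
    stats::setNames(integer(0), character(0))
  seed <- new_term()
  seed$assign <- obs[!is.na(obs)]
  pending <- list()
  for (l in init_literals) pending[[lit_key(l$var, l$state)]] <- l
  work <- list(list(term = seed, pending = pending, done = character(0)))
  finished <- list()

  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    if (!length(item$pending)) {
      finished[[length(finished) + 1L]] <- item$term
      next
    }
    key <- names(item$pending)[[1]]
    lit <- item$pending[[1]]
    item$pending[[1]] <- NULL
    item$done <- c(item$done, key)
    branches <- expand_one_literal(model, ctx, item, lit, mode)
    for (b in branches) work[[length(work) + 1L]] <- b
  }
  reduce_expression(new_expression(finished,
                                   context = if (mode == "context") ctx$hyp))
}

expand_one_literal <- function(model, ctx, item, lit, mode) {
  var <- lit$var; state <- lit$state
  kind <- var_kind(var)
  term <- item$term

  if (kind == "B") {
    if (mode == "context") {
      h <- ctx$hyp[var]
      if (is.na(h) || h != state) return(list())   # incompatible with hypothesis
    }
    t <- term_add_bd(term, var, state)
    if (is.null(t)) return(list())
    item$term <- t
    return(list(item))
  }
  if (kind == "D") {
    t <- term_add_bd(term, var, 0L)
    if (is.null(t)) return(list())
    item$term <- t
    return(list(item))
  }
  if (kind == "G") {
    return(expand_gate_literal(model, ctx, item, var, state, mode))
  }

  # X literal
  if (mode == "context") {
    o <- ctx$obs[var]
    if (!is.na(o) && o == 0L && state == 0L) {
      return(list(item))                 # observed normal: satisfied, no factor
    }
    if (!is.na(o) && o != state) return(list())
  }
  expand_x_literal(model, ctx, item, var, state, mode)
}

expand_gate_literal <- function(model, ctx, item, var, state, mode) {
  out <- list()
  obs <- if (mode == "context") ctx$obs else stats::setNames(integer(0), character(0))
  for (p in gate_state_products(model, var, state)) {
    ok <- TRUE
    br <- item
    for (vn in names(p)) {
      s <- p[[vn]]
      if (!is.na(obs[vn]) && obs[vn] != s) { ok <- FALSE; break }
      t <- term_set_state(br$term, vn, s)
      if (is.null(t)) { ok <- FALSE; break }
      br$term <- t
      lk <- lit_key(vn, s)
      if (!lk %in% br$done && is.null(br$pending[[lk]]))
        br$pending[[lk]] <- list(var = vn, state = s)
    }
    if (ok) out[[length(out) + 1L]] <- br
  }
  out
}

expand_x_literal <- function(model, ctx, item, var, state, mode) {
  if (mode == "context" && state != 0L) {
    kept <- context_parents(ctx, var, state)
    if (!length(kept)) return(list())
    plan <- lapply(kept, function(kp) list(
      arc = kp$arc, w = kp$w,
      js = vapply(kp$branches, function(b) b$j, integer(1))
    ))
  } else {
    arcs <- model_arcs_into(model, var)
    if (!length(arcs)) return(list())
    r_sum <- sum(vapply(arcs, function(a) a$r, numeric(1)))
    obs <- if (mode == "context") ctx$obs else stats::setNames(integer(0), character(0))
    plan <- lapply(arcs, function(arc) {
      pk <- var_kind(arc$parent)
      js <- if (pk == "D") 0L
      else if (mode == "context" && pk == "B") {
        h <- ctx$hyp[arc$parent]
        if (is.na(h)) integer(0) else h
      } else if (mode == "context" && !is.na(obs[arc$parent])) obs[[arc$parent]]
      else 0:(model$n_states[[arc$parent]] - 1L)
      list(arc = arc, w = rat(arc$r, r_sum), js = js)
    })
  }
  out <- list()
  for (pp in plan) {
    arc <- pp$arc
    for (j in pp$js) {
      aval <- if (var_kind(arc$parent) == "D") arc$a[state + 1L, 1L]
      else arc$a[state + 1L, j + 1L]
      if (!is.na(aval) && aval == 0) next
      br <- item
      t <- term_scale(br$term, pp$w)
      t <- term_add_a(t, var, state, arc$parent, j)
      if (is.null(t)) next
      br$term <- t
      pk <- var_kind(arc$parent)
      lk <- if (pk == "D") lit_key(arc$parent, 0L) else lit_key(arc$parent, j)
      if (!lk %in% br$done && is.null(br$pending[[lk]]))
        br$pending[[lk]] <- list(var = arc$parent, state = j)
      out[[length(out) + 1L]] <- br
    }
  }
  out
}

#' Expand a single event in a causality context
#'
#' @param x_event event key such as `"X5,1"` (or `c(X5 = 1)`).
#' @param ctx a `ducg_context` from [track_causality()], or a
#'   [ducg_model()] for an unrestricted expansion over all parent states
#'   (used e.g. to check autonormalization).
#' @return a [ducg_expression].
#' @export
expand_event <- function(x_event, ctx) {
  lit <- if (is.character(x_event)) lit_parse(x_event) else
    list(var = names(x_event)[[1]], state = as.integer(x_event[[1]]))
  if (inherits(ctx, "ducg_model")) {
    return(expand_terms(ctx, NULL, list(lit), mode = "full"))
  }
  expand_terms(ctx$model, ctx, list(lit), mode = "context")
}

#' Expand the abnormal-evidence product in a causality context
#'
#' The evidence product is the conjunction of all abnormal observations;
#' every observation is expanded jointly within one term set, so shared
#' ancestors are expanded once (idempotence) and contradictory chains
#' cancel (exclusion).
#'
#' @param evidence a [ducg_evidence()].
#' @param ctx a `ducg_context` from [track_causality()].
#' @return a [ducg_expression].
#' @export
expand_evidence_product <- function(evidence, ctx) {
  obs <- check_evidence(ctx$model, evidence)
  abn <- abnormal_evidence(obs)
  lits <- lapply(seq_along(abn), function(i)
    list(var = names(abn)[[i]], state = abn[[i]]))
  expand_terms(ctx$model, ctx, lits, mode = "context")
}

#' Merge mutually exclusive candidates into a dummy basic variable
#'
#' Mutually exclusive candidate root causes (members of one exclusive
#' category) are converted into states of a single dummy basic variable
#' (DBV): state `s` of the DBV stands for the `s`-th candidate event, the
#' DBV inherits each candidate's causal columns
#' (`a[, s] = candidate's column for its event state`; candidates without
#' an arc to a child contribute an explicit-zero column), arc weights merge
#' as `r_{n;v} = sum of r_{n;i}` over candidates with a nonzero causal
#' function on that child, and the DBV prior puts the candidate priors on
#' states `1..m` with the remainder on state 0.  Exclusion between the
#' original events becomes the inherent exclusion between states of one
#' variable.
#'
#' @param candidates character vector of B-state event keys, all members
#'   of the same exclusive category, length >= 2.
#' @param model a [ducg_model()].
#' @return list with `model` (the transformed `ducg_model`), `variable`
#'   (the DBV id), and `state_map` (named character: DBV state -> original
#'   event key).
#' @export
build_dbv <- function(candidates, model) {
  if (length(candidates) < 2L)
    ducg_abort("a DBV needs at least two candidates", "ducg_usage_error")
  cats <- vapply(candidates, function(e) event_category(model, e) %||% NA_character_,
                 character(1))
  if (anyNA(cats) || length(unique(cats)) != 1L || !startsWith(cats[[1]], "exclusive"))
    ducg_abort("DBV candidates must all belong to one exclusive category",
               "ducg_usage_error")
  parsed <- lapply(candidates, lit_parse)
  members <- vapply(parsed, function(p) p$var, character(1))
  mstates <- vapply(parsed, function(p) p$state, integer(1))
  idx <- max(model$variables$index) + 1L
  dbv <- paste0("B", idx)
  m <- length(candidates)

  # children of any member
  children <- unique(unlist(lapply(model$arcs, function(a)
    if (a$parent %in% members) a$child)))
  new_arcs <- Filter(function(a) !a$parent %in% members, model$arcs)
  for (ch in children) {
    ns_child <- model$n_states[[ch]]
    a_new <- matrix(NA_real_, nrow = ns_child, ncol = m + 1L)
    r_new <- 0
    for (s in seq_len(m)) {
      arc <- model_arc(model, members[[s]], ch)
      if (is.null(arc)) {
        a_new[, s + 1L] <- c(1, rep(0, ns_child - 1L))  # no causal effect
      } else {
        col <- arc$a[, mstates[[s]] + 1L]
        a_new[, s + 1L] <- col
        nonzero <- any(is.na(col)) || any(col[-1L] != 0)
        if (nonzero) r_new <- r_new + arc$r
      }
    }
    if (r_new == 0) r_new <- 1
    new_arcs[[length(new_arcs) + 1L]] <-
      normalize_arc(ducg_arc(dbv, ch, a_new, r = r_new))
  }

  v <- model$variables[!model$variables$id %in% members, ]
  v <- rbind(v, normalize_variables(list(ducg_variable(dbv, m + 1L))))
  priors <- model$priors[!names(model$priors) %in% members]
  pm <- vapply(seq_len(m), function(s) model$priors[[members[[s]]]][mstates[[s]] + 1L],
               numeric(1))
  priors[[dbv]] <- c(if (anyNA(pm)) NA_real_ else 1 - sum(pm), pm)
  categories <- model$categories
  categories$exclusive <- lapply(categories$exclusive, function(set)
    setdiff(set, candidates))
  categories$exclusive <- Filter(length, categories$exclusive)

  mm <- structure(list(variables = v, arcs = new_arcs, gates = model$gates,
                       priors = priors, categories = categories,
                       meta = model$meta),
                  class = "ducg_model")
  mm <- index_model(mm)
  list(model = mm, variable = dbv,
       state_map = stats::setNames(candidates, as.character(seq_len(m))))
}

#' Compose the maximal concurrent hypothesis
#'
#' When the surviving candidates are mutually consistent (at most one per
#' exclusive category; concurrent or cross-category events may co-occur),
#' the ultimate hypothesis is their conjunction: the maximal set of basic
#' events that together interpret the evidence — never a proper subset.
#'
#' @param space a `ducg_hypothesis_space` from [build_hypothesis_space()],
#'   or a character vector of candidate event keys.
#' @return character vector of event keys (sorted by variable index),
#'   class `ducg_hypothesis`.
#' @export
compose_concurrent_hypothesis <- function(space) {
  events <- if (is.character(space)) space else space$candidates$event
  if (!length(events))
    ducg_abort("empty hypothesis space", "ducg_usage_error")
  if (!is.character(space)) {
    cats <- space$candidates$category
    excl <- cats[!is.na(cats) & startsWith(cats, "exclusive")]
    if (anyDuplicated(excl))
      ducg_abort(paste0("multiple candidates left in one exclusive category; ",
                        "resolve with a DBV ranking first"), "ducg_usage_error")
  }
  ord <- order(vapply(events, function(e) var_index(lit_parse(e)$var), integer(1)))
  structure(events[ord], class = "ducg_hypothesis")
}

#' @export
print.ducg_hypothesis <- function(x, ...) {
  cat("<ducg_hypothesis> ", paste(unclass(x), collapse = " * "), "\n", sep = "")
  invisible(x)
}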