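#' @name ducg_expression
#' @title Symbolic weighted event expressions
#'
#' @description
#' The engine manipulates evidence symbolically as sums of products over
#' atomic events: causal-function events `A(child,k; parent,j)`, root-cause
#' events `B(i,j)` and default-cause events `D(i)`.  Each product term
#' carries an exact rational coefficient (the product of renormalized
#' weight ratios picked up during expansion) and an implied state
#' assignment for every variable its events mention.  Two events naming
#' the same variable in different states annihilate the term; events form
#' a set, so repeated events are idempotent; identical event sets are
#' merged by summing coefficients.
#'
#' @details
#' `expr_canonical()` renders an expression in a canonical textual form
#' (terms and events sorted, coefficients as reduced fractions) using the
#' field's notation, e.g. `"1/2 A5,1;2,1 B2,1"`.  Canonical forms are
#' stable across runs and suitable for exact structural comparison.
NULL

new_term <- function(num = 1, den = 1, a = list(), bd = character(0),
                     assign = integer(0)) {
  list(num = num, den = den, a = a, bd = bd, assign = assign)
}

term_coef <- function(term) c(num = term$num, den = term$den)

# Add an A event to a term; returns NULL if the implied states conflict
# (Rule: V_{i,j} V_{i,j'} = 0 for j != j') and the unchanged term if the
# event is already present (idempotence).
term_add_a <- function(term, child, k, parent, j) {
  key <- a_key(child, k, parent, j)
  if (!is.null(term$a[[key]])) return(term)
  term <- term_set_state(term, child, k)
  if (is.null(term)) return(NULL)
  if (var_kind(parent) != "D") {
    term <- term_set_state(term, parent, j)
    if (is.null(term)) return(NULL)
  }
  term$a[[key]] <- list(child = child, k = k, parent = parent,
                        j = if (var_kind(parent) == "D") NA_integer_ else j)
  term
}

term_add_bd <- function(term, var, state) {
  key <- bd_key(var, state)
  if (!key %in% term$bd) {
    if (var_kind(var) != "D") {
      term <- term_set_state(term, var, state)
      if (is.null(term)) return(NULL)
    }
    term$bd <- c(term$bd, key)
  }
  term
}

term_set_state <- function(term, var, state) {
  cur <- term$assign[var]
  if (!is.na(cur)) {
    if (cur != state) return(NULL)
    return(term)
  }
  term$assign[var] <- as.integer(state)
  term
}

term_scale <- function(term, w) {
  cf <- rat_mul(c(term$num, term$den), w)
  term$num <- cf[[1]]; term$den <- cf[[2]]
  term
}

term_event_key <- function(term) {
  paste(paste(sort(names(term$a)), collapse = "*"),
        paste(sort(term$bd), collapse = "*"), sep = "|")
}

new_expression <- function(terms = list(), context = NULL) {
  structure(list(terms = terms, context = context), class = "ducg_expression")
}

#' @rdname ducg_expression
#' @param terms list of terms (internal representation).
#' @param x,expr a `ducg_expression`.
#' @export
reduce_expression <- function(expr) {
  terms <- expr$terms
  if (!length(terms)) return(expr)
  keys <- vapply(terms, term_event_key, character(1))
  merged <- list()
  for (i in seq_along(terms)) {
    k <- keys[[i]]
    if (is.null(merged[[k]])) {
      merged[[k]] <- terms[[i]]
    } else {
      cf <- rat_add(term_coef(merged[[k]]), term_coef(terms[[i]]))
      merged[[k]]$num <- cf[[1]]; merged[[k]]$den <- cf[[2]]
    }
  }
  merged <- Filter(function(t) abs(t$num) > 0, merged)
  expr$terms <- unname(merged)
  expr
}

term_display <- function(term) {
  cf <- term_coef(term)
  a_str <- character(0)
  if (length(term$a)) {
    ord <- order(vapply(term$a, a_sort_key, character(1)))
    a_str <- vapply(term$a[ord], a_display, character(1))
  }
  bd_str <- character(0)
  if (length(term$bd)) {
    # default-cause (D) events are certain and stay implicit in the notation
    shown <- term$bd[vapply(term$bd, var_kind, character(1)) != "D"]
    if (length(shown))
      bd_str <- shown[order(vapply(shown, bd_sort_key, character(1)))]
  }
  body <- paste(c(a_str, bd_str), collapse = " ")
  if (abs(cf[[1]] - cf[[2]]) < 1e-12) body
  else paste(rat_format(cf), body)
}

#' @rdname ducg_expression
#' @return `expr_canonical()` returns a single string; `expr_terms()`
#'   returns the per-term canonical strings.
#' @export
expr_canonical <- function(expr) {
  s <- expr_terms(expr)
  if (!length(s)) return("0")
  paste(sort(s), collapse = " + ")
}

#' @rdname ducg_expression
#' @export
expr_terms <- function(expr) {
  vapply(expr$terms, term_display, character(1))
}

#' @export
print.ducg_expression <- function(x, ...) {
  cat("<ducg_expression> ", length(x$terms), " term(s)\n", sep = "")
  for (s in expr_terms(x)) cat("  ", s, "\n", sep = "")
  invisible(x)
}

#' @rdname ducg_expression
#' @param e1,e2 expressions to multiply.
#' @details `expr_multiply()` forms the logical product of two expressions.
#' Event sets union (idempotence of atomic events), terms whose implied
#' variable states conflict vanish (exclusion), and duplicated event sets
#' merge with summed coefficients.  Conditional absorption applies: when a
#' factor re-expands a child event that a term already explains through a
#' different cause, the term absorbs the whole factor — the weighted
#' expansion of a child sums to the child event itself, so multiplying by
#' it changes nothing.  The product of an expression with itself is
#' therefore the expression again.
#' @export
expr_multiply <- function(e1, e2) {
  out <- list()
  for (t1 in e1$terms) {
    # children of t1 with their explaining arcs
    t1_causes <- list()
    for (ev in t1$a) {
      ck <- lit_key(ev$child, ev$k)
      t1_causes[[ck]] <- c(t1_causes[[ck]], a_key(ev$child, ev$k, ev$parent, ev$j))
    }
    absorbed <- FALSE
    for (t2 in e2$terms) {
      for (ev in t2$a) {
        ck <- lit_key(ev$child, ev$k)
        known <- t1_causes[[ck]]
        if (!is.null(known) && !a_key(ev$child, ev$k, ev$parent, ev$j) %in% known) {
          absorbed <- TRUE
          break
        }
      }
      if (absorbed) break
    }
    if (absorbed) {
      # conditional absorption: the factor is an alternative-cause expansion
      # of a child t1 already explains; t1 passes through unchanged
      out[[length(out) + 1L]] <- t1
      next
    }
    for (t2 in e2$terms) {
      t <- t1
      ok <- TRUE
      for (ev in t2$a) {
        t <- term_add_a(t, ev$child, ev$k, ev$parent, ev$j)
        if (is.null(t)) { ok <- FALSE; break }
      }
      if (!ok) next
      for (key in t2$bd) {
        p <- if (var_kind(key) == "D") list(var = key, state = 0L) else lit_parse(key)
        t <- term_add_bd(t, p$var, p$state)
        if (is.null(t)) { ok <- FALSE; break }
      }
      if (!ok) next
      t <- term_scale(t, term_coef(t2))
      out[[length(out) + 1L]] <- t
    }
  }
  reduce_expression(new_expression(out, context = e1$context))
}

#' @rdname ducg_expression
#' @param model a [ducg_model()] supplying the exclusive category sets.
#' @details `apply_exclusions()` eliminates every term containing two
#' root-cause events from the same exclusive category (mutually exclusive
#' diseases cannot co-occur in one explanation).
#' @export
apply_exclusions <- function(expr, model) {
  if (!length(model$categories$exclusive)) return(expr)
  keep <- vapply(expr$terms, function(t) {
    for (set in model$categories$exclusive) {
      if (sum(t$bd %in% set) >= 2L) return(FALSE)
    }
    TRUE
  }, logical(1))
  expr$terms <- expr$terms[keep]
  expr
}
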