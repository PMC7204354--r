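#' @name oracle
#' @title Exact joint-enumeration oracle
#'
#' @description
#' A brute-force reference implementation of the generative reading of the
#' weighted expansion: root causes are drawn from their priors, default
#' causes always occur, gates are deterministic functions of their inputs
#' (state 0 is the remnant), and each observable takes state `k` with
#' probability `sum_i (r_{n;i}/r_n) a_{n,k;i,j_i}` given its parents'
#' states `j_i`.  The full joint distribution over small, fully
#' parameterized models validates simplification, expansion and posterior
#' computation by exhaustive summation — it shares no code path with the
#' symbolic engine.
NULL

topological_order <- function(model) {
  ids <- model$variables$id
  edges <- character(0)
  for (arc in model$arcs) edges <- c(edges, arc$parent, arc$child)
  for (g in model$gates) for (inp in g$inputs) edges <- c(edges, inp, g$gate)
  if (!length(edges)) return(ids)
  gr <- igraph::make_graph(edges, directed = TRUE)
  ord <- names(igraph::topo_sort(gr, mode = "out"))
  c(ord, setdiff(ids, ord))
}

#' Enumerate the full joint distribution of a small model
#'
#' @param model a fully parameterized [ducg_model()].
#' @param max_assignments bound on the state-space size (default `1e6`).
#' @return a data frame with one column per variable (state indices) and a
#'   `probability` column summing to 1.
#' @export
enumerate_joint <- function(model, max_assignments = 1e6) {
  v <- model$variables
  free <- v$id[v$kind %in% c("B", "X")]
  ns <- model$n_states[free]
  size <- prod(ns)
  if (size > max_assignments)
    ducg_abort(paste0("state space has ", format(size),
                      " assignments (bound ", format(max_assignments), ")"),
               "ducg_size_error")
  grid <- expand.grid(lapply(ns, function(n) 0:(n - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  n <- nrow(grid)
  # deterministic variables
  for (id in topological_order(model)) {
    kind <- var_kind(id)
    if (kind == "D") grid[[id]] <- rep(0L, n)
    if (kind == "G") {
      g <- model$gates[[id]]
      st <- rep(0L, n)
      assigned <- rep(FALSE, n)
      for (s in names(g$state_exprs)) {
        match_s <- rep(FALSE, n)
        for (p in g$state_exprs[[s]]) {
          hit <- rep(TRUE, n)
          for (vn in names(p)) hit <- hit & grid[[vn]] == p[[vn]]
          match_s <- match_s | hit
        }
        if (any(match_s & assigned))
          ducg_abort(paste0("gate ", id, " state expressions overlap"),
                     "ducg_validation_error")
        st[match_s] <- as.integer(s)
        assigned <- assigned | match_s
      }
      grid[[id]] <- st
    }
  }
  prob <- rep(1, n)
  for (id in free) {
    kind <- var_kind(id)
    if (kind == "B") {
      b <- model$priors[[id]]
      if (is.na(b[[1]]) && !anyNA(b[-1L])) b[[1]] <- 1 - sum(b[-1L])
      if (anyNA(b))
        ducg_abort(paste0("missing prior entries for ", id),
                   "ducg_missing_parameter", parameter = id)
      prob <- prob * b[grid[[id]] + 1L]
    } else {
      arcs <- model_arcs_into(model, id)
      r_sum <- sum(vapply(arcs, function(a) a$r, numeric(1)))
      p <- rep(0, n)
      for (arc in arcs) {
        j <- if (var_kind(arc$parent) == "D") rep(0L, n) else grid[[arc$parent]]
        aval <- arc$a[cbind(grid[[id]] + 1L, j + 1L)]
        if (anyNA(aval))
          ducg_abort(paste0("missing a-entries on arc ", arc$parent, "->", id),
                     "ducg_missing_parameter",
                     parameter = paste0(arc$parent, "->", id))
        p <- p + (arc$r / r_sum) * aval
      }
      prob <- prob * p
    }
  }
  grid$probability <- prob
  grid
}

#' Exact posterior probabilities of root-cause states
#'
#' Conditions the enumerated joint on the full evidence (including
#' observed-normal states) and returns `Pr(B = j | evidence)` for every
#' B variable and state.
#'
#' @inheritParams enumerate_joint
#' @param evidence a [ducg_evidence()].
#' @param exclusive how to treat exclusive category sets:
#'   `"ignore"` enumerates the declared independent priors as-is;
#'   `"merge"` treats each exclusive category as a single multinomial
#'   choice (prior `b_i` for exactly member `i` occurring, the remainder
#'   for none, zero for any co-occurrence) — the prior semantics under
#'   which mutually exclusive diseases are elicited.
#' @return named numeric vector, names like `"B2,1"`, one entry per
#'   B variable state.
#' @export
posterior_b_states <- function(model, evidence, exclusive = c("ignore", "merge"),
                               max_assignments = 1e6) {
  exclusive <- match.arg(exclusive)
  obs <- check_evidence(model, evidence)
  joint <- enumerate_joint(model, max_assignments)
  prob <- joint$probability
  if (exclusive == "merge" && length(model$categories$exclusive)) {
    for (set in model$categories$exclusive) {
      parsed <- lapply(set, lit_parse)
      vars <- vapply(parsed, function(p) p$var, character(1))
      states <- vapply(parsed, function(p) p$state, integer(1))
      bi <- vapply(seq_along(vars), function(i)
        model$priors[[vars[[i]]]][states[[i]] + 1L], numeric(1))
      # replace the independent-prior factor with the multinomial one
      indep <- rep(1, nrow(joint))
      active <- rep(0L, nrow(joint))
      merged <- rep(1 - sum(bi), nrow(joint))
      ok <- rep(TRUE, nrow(joint))
      for (i in seq_along(vars)) {
        b <- model$priors[[vars[[i]]]]
        if (is.na(b[[1]])) b[[1]] <- 1 - sum(b[-1L])
        indep <- indep * b[joint[[vars[[i]]]] + 1L]
        is_event <- joint[[vars[[i]]]] == states[[i]]
        is_off <- joint[[vars[[i]]]] == 0L
        ok <- ok & (is_event | is_off)
        active <- active + is_event
        merged[is_event] <- bi[[i]]
      }
      merged[!ok | active > 1L] <- 0
      prob <- prob / indep * merged
    }
  }
  keep <- rep(TRUE, nrow(joint))
  for (vn in names(obs)) keep <- keep & joint[[vn]] == obs[[vn]]
  pe <- sum(prob[keep])
  if (pe <= 0)
    ducg_abort("evidence has probability zero under the model",
               "ducg_degenerate_evidence")
  out <- numeric(0)
  for (id in model$variables$id[model$variables$kind == "B"]) {
    for (s in 0:(model$n_states[[id]] - 1L)) {
      out[[lit_key(id, s)]] <-
        sum(prob[keep & joint[[id]] == s]) / pe
    }
  }
  out
}

#' Forward Monte-Carlo sampling from the generative model
#'
#' @inheritParams enumerate_joint
#' @param n number of samples.
#' @return data frame of sampled state indices, one column per variable.
#' @export
sample_forward <- function(model, n) {
  ord <- topological_order(model)
  out <- list()
  for (id in ord) {
    kind <- var_kind(id)
    if (kind == "D") { out[[id]] <- rep(0L, n); next }
    if (kind == "B") {
      b <- model$priors[[id]]
      if (is.na(b[[1]])) b[[1]] <- 1 - sum(b[-1L])
      out[[id]] <- sample.int(length(b), n, replace = TRUE, prob = b) - 1L
      next
    }
    if (kind == "G") {
      g <- model$gates[[id]]
      st <- rep(0L, n)
      for (s in names(g$state_exprs)) {
        for (p in g$state_exprs[[s]]) {
          hit <- rep(TRUE, n)
          for (vn in names(p)) hit <- hit & out[[vn]] == p[[vn]]
          st[hit] <- as.integer(s)
        }
      }
      out[[id]] <- st
      next
    }
    arcs <- model_arcs_into(model, id)
    r <- vapply(arcs, function(a) a$r, numeric(1))
    pick <- sample.int(length(arcs), n, replace = TRUE, prob = r / sum(r))
    st <- integer(n)
    ns <- model$n_states[[id]]
    for (ai in seq_along(arcs)) {
      rows <- which(pick == ai)
      if (!length(rows)) next
      arc <- arcs[[ai]]
      j <- if (var_kind(arc$parent) == "D") rep(0L, length(rows))
      else out[[arc$parent]][rows]
      for (jj in unique(j)) {
        sub <- rows[j == jj]
        col <- arc$a[, jj + 1L]
        st[sub] <- sample.int(ns, length(sub), replace = TRUE, prob = col) - 1L
      }
    }
    out[[id]] <- st
  }
  as.data.frame(out[model$variables$id])
}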