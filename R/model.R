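#' Construct a DUCG causality-graph model
#'
#' A DUCG model is a directed acyclic graph over four kinds of variables:
#' `B` (root causes with prior probabilities), `X` (observable effects),
#' `G` (logic gates combining their inputs), and `D` (always-occurring
#' default causes of an `X`).  State 0 of a `B` or `X` variable is the
#' normal state; nonzero states are abnormal.  Causal arcs into an `X`
#' carry an intensity weight `r` and a causal-function matrix `a` whose
#' entry `a[k+1, j+1]` is the probability that the parent in state `j`
#' causes the child into state `k`; `NA` marks an unknown parameter, which
#' is distinct from an explicit 0.
#'
#' @param variables list of [ducg_variable()] entries (or a data frame with
#'   columns `id` and `n_states`).
#' @param arcs list of [ducg_arc()] entries.
#' @param gates list of [ducg_gate()] entries.
#' @param priors named list mapping each B variable id to its prior state
#'   probability vector (state 0 first; `NA` allowed).
#' @param categories list with elements `exclusive` (a list of character
#'   vectors of B-state event keys such as `"B23,1"`, each vector one
#'   mutually exclusive set) and `concurrent` (a character vector of
#'   B-state events that may co-occur).
#' @param meta optional free-form metadata list, preserved on round-trip.
#' @param validate validate the model and fail on any diagnostic.
#' @return an object of class `ducg_model`.
#' @seealso [validate_model()], [load_model()], [save_model()]
#' @export
ducg_model <- function(variables, arcs = list(), gates = list(),
                       priors = list(), categories = list(),
                       meta = list(), validate = TRUE) {
  vars <- normalize_variables(variables)
  arcs <- lapply(arcs, normalize_arc)
  gates <- normalize_gates(gates)
  priors <- normalize_priors(priors)
  categories <- normalize_categories(categories)
  m <- structure(
    list(variables = vars, arcs = arcs, gates = gates,
         priors = priors, categories = categories, meta = meta),
    class = "ducg_model"
  )
  m <- index_model(m)
  if (validate) {
    diags <- validate_model(m)
    if (length(diags)) {
      ducg_abort(paste0("invalid DUCG model:\n  ",
                        paste(diags, collapse = "\n  ")),
                 "ducg_validation_error", diagnostics = diags)
    }
  }
  m
}

#' @rdname ducg_model
#' @param id variable id: kind letter followed by a positive integer
#'   (`"B1"`, `"X10"`, `"G12"`, `"D10"`).
#' @param n_states number of states including state 0.  D variables have
#'   exactly one state.
#' @param labels optional character vector of per-state labels.
#' @export
ducg_variable <- function(id, n_states, labels = NULL) {
  list(id = id, n_states = as.integer(n_states), labels = labels)
}

#' @rdname ducg_model
#' @param parent,child variable ids.  Arc children are always X variables;
#'   gate inputs are declared on the gate itself, not as arcs.
#' @param a causal-function matrix, `child n_states` rows by
#'   `parent n_states` columns (one column for a D parent); `NA` = unknown.
#' @param r nonnegative causal-intensity weight (default 1).
#' @export
ducg_arc <- function(parent, child, a, r = 1) {
  list(parent = parent, child = child, a = as.matrix(a), r = as.numeric(r))
}

#' @rdname ducg_model
#' @param gate gate variable id (kind G).
#' @param inputs character vector of input variable ids (purely logical:
#'   gate inputs carry no weight and no causal matrix).
#' @param state_exprs named list mapping each nonzero gate state (as a
#'   character key, e.g. `"1"`) to its defining sum-of-products: a list of
#'   products, each product a named integer vector of input states, e.g.
#'   `c(X9 = 1, X10 = 2)`.  State 0 is the implicit remnant (complement).
#' @export
ducg_gate <- function(gate, inputs, state_exprs) {
  list(gate = gate, inputs = inputs, state_exprs = state_exprs)
}

normalize_variables <- function(variables) {
  if (is.data.frame(variables)) {
    variables <- lapply(seq_len(nrow(variables)), function(i) {
      ducg_variable(variables$id[[i]], variables$n_states[[i]])
    })
  }
  ids <- vapply(variables, function(v) as.character(v$id), character(1))
  ns <- vapply(variables, function(v) as.integer(v$n_states), integer(1))
  labels <- lapply(variables, function(v) v$labels)
  data.frame(
    id = ids,
    kind = vapply(ids, var_kind, character(1)),
    index = vapply(ids, var_index, integer(1)),
    n_states = ns,
    labels = I(labels),
    row.names = NULL
  )
}

normalize_arc <- function(arc) {
  a <- arc$a
  if (!is.matrix(a)) a <- matrix(as.numeric(a), ncol = 1L)
  storage.mode(a) <- "double"
  list(parent = as.character(arc$parent), child = as.character(arc$child),
       a = a, r = as.numeric(arc$r %||% 1))
}

normalize_gates <- function(gates) {
  out <- list()
  for (g in gates) {
    exprs <- lapply(g$state_exprs, function(prods) {
      lapply(prods, function(p) {
        if (is.list(p)) {
          v <- vapply(p, function(l) as.integer(l$state), integer(1))
          names(v) <- vapply(p, function(l) as.character(l$var), character(1))
          v
        } else {
          storage.mode(p) <- "integer"
          p
        }
      })
    })
    out[[as.character(g$gate)]] <-
      list(gate = as.character(g$gate),
           inputs = as.character(g$inputs), state_exprs = exprs)
  }
  out
}

normalize_priors <- function(priors) {
  if (length(priors) && is.null(names(priors))) {
    nm <- vapply(priors, function(p) as.character(p$variable), character(1))
    priors <- lapply(priors, function(p) as.numeric(p$b))
    names(priors) <- nm
  }
  lapply(priors, as.numeric)
}

normalize_categories <- function(categories) {
  norm_events <- function(x) {
    vapply(x, function(e) {
      if (is.character(e)) e else paste0(e$var, ",", e$state)
    }, character(1))
  }
  list(
    exclusive = lapply(categories$exclusive %||% list(), norm_events),
    concurrent = if (length(categories$concurrent %||% character()))
      norm_events(categories$concurrent) else character(0)
  )
}

# Attach lookup tables: arcs by child and by (parent, child).
index_model <- function(m) {
  children <- vapply(m$arcs, function(a) a$child, character(1))
  m$arcs_by_child <- split(seq_along(m$arcs), children)
  keys <- vapply(m$arcs, function(a) paste0(a$parent, "->", a$child), character(1))
  m$arc_by_pair <- stats::setNames(seq_along(m$arcs), keys)
  m$n_states <- stats::setNames(m$variables$n_states, m$variables$id)
  m
}

model_var <- function(m, id) {
  i <- match(id, m$variables$id)
  if (is.na(i)) NULL else m$variables[i, ]
}

model_arcs_into <- function(m, child) {
  idx <- m$arcs_by_child[[child]]
  if (is.null(idx)) list() else m$arcs[idx]
}

model_arc <- function(m, parent, child) {
  i <- m$arc_by_pair[[paste0(parent, "->", child)]]
  if (is.null(i)) NULL else m$arcs[[i]]
}

#' Validate a DUCG model
#'
#' Checks every structural and numerical invariant of the representation
#' and reports violations without throwing: variable typing and state
#' counts, matrix dimensions, known a-matrix columns summing to 1, prior
#' vectors, graph acyclicity, parent rules per variable kind, gate
#' expressions, and category sets.
#'
#' @param model a [ducg_model()].
#' @return character vector of diagnostics; empty when the model is valid.
#' @export
validate_model <- function(model) {
  d <- character(0)
  v <- model$variables
  say <- function(...) d[[length(d) + 1L]] <<- paste0(...)

  if (anyDuplicated(v$id)) say("duplicate variable ids: ",
                               paste(unique(v$id[duplicated(v$id)]), collapse = ", "))
  for (i in seq_len(nrow(v))) {
    id <- v$id[[i]]; kind <- v$kind[[i]]; ns <- v$n_states[[i]]
    if (!kind %in% c("B", "X", "G", "D")) say(id, ": unknown variable kind")
    if (is.na(v$index[[i]]) || v$index[[i]] <= 0L) say(id, ": index must be a positive integer")
    if (kind %in% c("B", "X", "G") && ns < 2L) say(id, ": needs at least 2 states")
    if (kind == "D" && ns != 1L) say(id, ": D variables have exactly one state")
  }
  ids <- v$id
  nstate <- stats::setNames(v$n_states, ids)

  seen_pairs <- character(0)
  for (arc in model$arcs) {
    lab <- paste0(arc$parent, "->", arc$child)
    if (!arc$parent %in% ids) { say("arc ", lab, ": undeclared parent"); next }
    if (!arc$child %in% ids) { say("arc ", lab, ": undeclared child"); next }
    if (var_kind(arc$child) != "X")
      say("arc ", lab, ": arc children must be X variables (B/D have no parents; gate inputs are declared on the gate)")
    if (lab %in% seen_pairs) say("arc ", lab, ": duplicated")
    seen_pairs <- c(seen_pairs, lab)
    if (is.na(arc$r) || arc$r < 0) say("arc ", lab, ": weight r must be nonnegative")
    a <- arc$a
    nr <- nstate[[arc$child]] %||% NA_integer_
    nc <- if (var_kind(arc$parent) == "D") 1L else nstate[[arc$parent]] %||% NA_integer_
    if (!is.na(nr) && !is.na(nc) && (nrow(a) != nr || ncol(a) != nc)) {
      say("arc ", lab, ": a-matrix is ", nrow(a), "x", ncol(a),
          " but should be ", nr, "x", nc)
      next
    }
    bad <- !is.na(a) & (a < 0 | a > 1)
    if (any(bad)) say("arc ", lab, ": a-entries outside [0,1]")
    for (j in seq_len(ncol(a))) {
      col <- a[, j]
      if (!anyNA(col) && abs(sum(col) - 1) > 1e-9)
        say("arc ", lab, ": column for parent state ", j - 1L,
            " sums to ", format(sum(col)), " (should be 1)")
    }
  }

  for (id in ids[v$kind == "X"]) {
    if (is.null(model$arcs_by_child[[id]]))
      say(id, ": X variable has no parent (needs an arc or a default cause)")
  }

  for (g in model$gates) {
    if (!g$gate %in% ids) { say("gate ", g$gate, ": undeclared"); next }
    if (var_kind(g$gate) != "G") say("gate ", g$gate, ": not a G variable")
    for (inp in g$inputs) if (!inp %in% ids) say("gate ", g$gate, ": undeclared input ", inp)
    for (s in names(g$state_exprs)) {
      si <- suppressWarnings(as.integer(s))
      if (is.na(si) || si <= 0L || si >= (nstate[[g$gate]] %||% Inf))
        say("gate ", g$gate, ": state expression for invalid state ", s)
      for (p in g$state_exprs[[s]]) {
        for (k in seq_along(p)) {
          vn <- names(p)[[k]]
          if (!vn %in% g$inputs) {
            say("gate ", g$gate, ": literal references ", vn, ", not a declared input")
          } else if (p[[k]] < 0L || p[[k]] >= nstate[[vn]]) {
            say("gate ", g$gate, ": literal ", vn, ",", p[[k]], " out of state range")
          }
        }
      }
    }
    if (!any(vapply(model$arcs, function(a) a$parent == g$gate, logical(1))))
      say("gate ", g$gate, ": has no outgoing arc")
  }

  for (id in ids[v$kind == "B"]) {
    b <- model$priors[[id]]
    if (is.null(b)) { say(id, ": missing prior vector"); next }
    if (length(b) != nstate[[id]]) { say(id, ": prior length != n_states"); next }
    if (any(!is.na(b) & (b < 0 | b > 1))) say(id, ": prior entries outside [0,1]")
    nz <- b[-1L]
    if (!anyNA(nz) && sum(nz) > 1 + 1e-9)
      say(id, ": nonzero-state priors sum to ", format(sum(nz)), " (> 1)")
  }
  extra <- setdiff(names(model$priors), ids[v$kind == "B"])
  for (id in extra) say(id, ": prior given for a non-B or undeclared variable")

  cat_seen <- character(0)
  all_excl <- character(0)
  for (ci in seq_along(model$categories$exclusive)) {
    for (e in model$categories$exclusive[[ci]]) {
      p <- lit_parse(e)
      if (!p$var %in% ids || var_kind(p$var) != "B")
        say("category event ", e, ": not a declared B variable")
      else if (p$state < 1L || p$state >= nstate[[p$var]])
        say("category event ", e, ": state out of range or zero")
      if (e %in% cat_seen) say("category event ", e, ": appears in more than one exclusive set")
      cat_seen <- c(cat_seen, e)
    }
    all_excl <- c(all_excl, model$categories$exclusive[[ci]])
  }
  for (e in model$categories$concurrent) {
    p <- lit_parse(e)
    if (!p$var %in% ids || var_kind(p$var) != "B")
      say("category event ", e, ": not a declared B variable")
    if (e %in% all_excl) say("category event ", e, ": in both an exclusive set and the concurrent set")
  }

  # acyclicity over arcs plus gate-input edges
  edges <- character(0)
  for (arc in model$arcs)
    if (arc$parent %in% ids && arc$child %in% ids)
      edges <- c(edges, arc$parent, arc$child)
  for (g in model$gates)
    for (inp in g$inputs) if (inp %in% ids && g$gate %in% ids)
      edges <- c(edges, inp, g$gate)
  if (length(edges)) {
    gr <- igraph::make_graph(edges, directed = TRUE)
    if (!igraph::is_dag(gr)) {
      comp <- igraph::components(gr, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      say("graph contains a cycle through: ", paste(sort(cyc), collapse = ", "))
    }
  }
  d
}

#' @export
print.ducg_model <- function(x, ...) {
  tab <- table(factor(x$variables$kind, levels = c("B", "X", "G", "D")))
  cat("<ducg_model> ", nrow(x$variables), " variables (",
      paste0(names(tab), ":", as.integer(tab), collapse = " "), "), ",
      length(x$arcs), " arcs, ", length(x$gates), " gate(s)\n", sep = "")
  ncat <- length(x$categories$exclusive)
  if (ncat || length(x$categories$concurrent))
    cat("  categories: ", ncat, " exclusive set(s), ",
        length(x$categories$concurrent), " concurrent event(s)\n", sep = "")
  invisible(x)
}

# ---- evidence ---------------------------------------------------------------

#' Construct or read an evidence set
#'
#' Evidence maps observed X variables to their observed state index.
#' Variables not present are unknown; an explicit 0 is an observed-normal
#' finding (it constrains the reasoning but is not part of the abnormal
#' evidence product).
#'
#' @param ... named states (`X3 = 1, X7 = 2`), or a single named
#'   vector/list.
#' @return an object of class `ducg_evidence` (named integer vector).
#' @export
ducg_evidence <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && (is.na(names(args)[1]) || names(args)[1] == ""))) {
    args <- as.list(args[[1]])
  }
  ev <- vapply(args, as.integer, integer(1))
  structure(ev, class = "ducg_evidence")
}

#' @export
print.ducg_evidence <- function(x, ...) {
  cat("<ducg_evidence> ",
      paste0(names(x), "=", as.integer(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

check_evidence <- function(model, evidence) {
  ev <- as.integer(evidence)
  names(ev) <- names(evidence)
  for (i in seq_along(ev)) {
    id <- names(ev)[[i]]
    if (!id %in% model$variables$id)
      ducg_abort(paste0("evidence references undeclared variable ", id),
                 "ducg_validation_error")
    if (var_kind(id) != "X")
      ducg_abort(paste0("evidence on non-X variable ", id),
                 "ducg_validation_error")
    ns <- model$n_states[[id]]
    if (ev[[i]] < 0L || ev[[i]] >= ns)
      ducg_abort(paste0("evidence state ", ev[[i]], " out of range for ", id),
                 "ducg_validation_error")
  }
  ev
}

abnormal_evidence <- function(evidence) {
  ev <- as.integer(evidence)
  names(ev) <- names(evidence)
  ev[ev != 0L]
}

# ---- JSON serialization -----------------------------------------------------

#' Read and write DUCG models and evidence as JSON
#'
#' The on-disk format has top-level keys `variables`, `arcs`, `gates`,
#' `priors`, `categories` (see the JSON schema shipped in
#' `system.file("schema", "ducg-model.schema.json", package = "ducg")`).
#' Matrices are stored dense, row-major, with `null` for unknown entries;
#' round-trips are lossless, and unknown (`null`) entries are never coerced
#' to 0.  Evidence files are plain JSON objects `{"X7": 2, "X8": 1}`.
#'
#' @param path file path.
#' @param model a [ducg_model()].
#' @param validate validate after reading.
#' @return `load_model()` returns a `ducg_model`; `read_evidence()` returns
#'   a `ducg_evidence`; the writers return the path invisibly.
#' @export
load_model <- function(path, validate = TRUE) {
  if (!file.exists(path))
    ducg_abort(paste0("model file not found: ", path), "ducg_io_error")
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  variables <- lapply(js$variables, function(v)
    ducg_variable(v$id, v$n_states,
                  labels = if (!is.null(v$labels)) unlist(v$labels)))
  arcs <- lapply(js$arcs, function(a) {
    rows <- lapply(a$a, function(row)
      vapply(row, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)))
    ducg_arc(a$parent, a$child, do.call(rbind, rows), r = a$r %||% 1)
  })
  gates <- lapply(js$gates, function(g) {
    exprs <- lapply(g$state_exprs, function(prods) lapply(prods, function(p) {
      v <- vapply(p, function(l) as.integer(l$state), integer(1))
      names(v) <- vapply(p, function(l) as.character(l$var), character(1))
      v
    }))
    ducg_gate(g$gate, unlist(g$inputs), exprs)
  })
  priors <- lapply(js$priors, function(p)
    vapply(p$b, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)))
  names(priors) <- vapply(js$priors, function(p) as.character(p$variable), character(1))
  categories <- list(
    exclusive = lapply(js$categories$exclusive %||% list(),
                       function(s) vapply(s, as.character, character(1))),
    concurrent = vapply(js$categories$concurrent %||% list(),
                        as.character, character(1))
  )
  ducg_model(variables, arcs, gates, priors, categories,
             meta = js$meta %||% list(), validate = validate)
}

#' @rdname load_model
#' @export
save_model <- function(model, path) {
  v <- model$variables
  js <- list(
    format = "ducg-model", version = 1L,
    variables = lapply(seq_len(nrow(v)), function(i) {
      out <- list(id = v$id[[i]], n_states = v$n_states[[i]])
      if (!is.null(v$labels[[i]])) out$labels <- as.list(v$labels[[i]])
      out
    }),
    arcs = lapply(model$arcs, function(a) list(
      parent = a$parent, child = a$child, r = a$r,
      a = lapply(seq_len(nrow(a$a)), function(i) as.list(a$a[i, ]))
    )),
    gates = lapply(unname(model$gates), function(g) list(
      gate = g$gate, inputs = as.list(g$inputs),
      state_exprs = lapply(g$state_exprs, function(prods) lapply(prods, function(p)
        lapply(seq_along(p), function(k) list(var = names(p)[[k]], state = p[[k]]))))
    )),
    priors = lapply(names(model$priors), function(id)
      list(variable = id, b = as.list(model$priors[[id]]))),
    categories = list(
      exclusive = lapply(model$categories$exclusive, as.list),
      concurrent = as.list(model$categories$concurrent)
    )
  )
  if (length(model$meta)) js$meta <- model$meta
  json <- jsonlite::toJSON(js, auto_unbox = TRUE, null = "null", na = "null",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname load_model
#' @export
read_evidence <- function(path) {
  if (!file.exists(path))
    ducg_abort(paste0("evidence file not found: ", path), "ducg_io_error")
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ducg_evidence(stats::setNames(vapply(js, as.integer, integer(1)), names(js)))
}

#' @rdname load_model
#' @param evidence a [ducg_evidence()].
#' @export
write_evidence <- function(evidence, path) {
  writeLines(jsonlite::toJSON(as.list(stats::setNames(as.integer(evidence),
                                                      names(evidence))),
                              auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
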