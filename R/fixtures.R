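#' The fully parameterized worked-example causality graph
#'
#' A small diagnostic causality graph with two root causes (B1, B2), nine
#' observables, one logic gate (G12, whose state 1 is
#' `X9,1 X10,2 + X10,1`) and one default cause (D10 -> X10).  All
#' causal-intensity weights are 1; the parameter matrices contain unknown
#' entries (`NA`) wherever the value is irrelevant to the diagnostic
#' questions the graph is used for — self-reliant chaining inference never
#' needs them.
#'
#' Structure: B1 -> X8; B2 -> X5, X8; X8 -> X4, X6, X7; X7 -> X3;
#' X4 -> X5; X6 -> X9; D10 -> X10; X9, X10 -> G12 -> X11.
#'
#' @return a validated [ducg_model()].
#' @export
figure1_model <- function() {
  na <- NA_real_
  variables <- list(
    ducg_variable("B1", 2), ducg_variable("B2", 3),
    ducg_variable("X3", 2), ducg_variable("X4", 2), ducg_variable("X5", 2),
    ducg_variable("X6", 3), ducg_variable("X7", 3), ducg_variable("X8", 2),
    ducg_variable("X9", 2), ducg_variable("X10", 3), ducg_variable("D10", 1),
    ducg_variable("X11", 3), ducg_variable("G12", 2)
  )
  arcs <- list(
    ducg_arc("X7", "X3", rbind(c(na, na, na), c(na, 0, 0.5))),
    ducg_arc("X8", "X4", rbind(c(na, na), c(na, 0.6))),
    ducg_arc("B2", "X5", rbind(c(na, na, na), c(na, 0.2, 0))),
    ducg_arc("X4", "X5", rbind(c(na, na), c(na, 0.8))),
    ducg_arc("X8", "X6", rbind(c(na, na), c(na, 0.6), c(na, 0))),
    ducg_arc("X8", "X7", rbind(c(na, na), c(na, 0), c(na, 0.9))),
    ducg_arc("B1", "X8", rbind(c(na, na), c(na, 0.9))),
    ducg_arc("B2", "X8", rbind(c(na, na, na), c(na, 0.6, 0))),
    ducg_arc("X6", "X9", rbind(c(na, na, na), c(na, 0.6, 0))),
    ducg_arc("D10", "X10", matrix(c(na, 0.2, 0.8), ncol = 1)),
    ducg_arc("G12", "X11", rbind(c(na, na), c(na, 0), c(na, 0.9)))
  )
  gates <- list(
    ducg_gate("G12", c("X9", "X10"),
              list("1" = list(c(X9 = 1L, X10 = 2L), c(X10 = 1L))))
  )
  priors <- list(B1 = c(na, 0.02), B2 = c(na, 0.02, 0.04))
  ducg_model(variables, arcs, gates, priors)
}

#' The worked-example evidence set
#'
#' Seven abnormal observations; everything else is unknown.
#'
#' @return a [ducg_evidence()]:
#'   `X3=1, X5=1, X7=2, X8=1, X9=1, X10=2, X11=2`.
#' @export
worked_example_evidence <- function() {
  ducg_evidence(X3 = 1, X5 = 1, X7 = 2, X8 = 1, X9 = 1, X10 = 2, X11 = 2)
}

#' Configuration for the synthetic model generator
#'
#' @param seed integer seed; generation is a pure function of the
#'   configuration.
#' @param n_b,n_x,n_gates variable counts.
#' @param max_states maximum number of states for B and X variables
#'   (each variable draws between 2 and `max_states`).
#' @param edge_density probability weight for extra parents beyond the
#'   first (every X has at least one parent).
#' @param unknown_fraction fraction of parameters to blank out as unknown;
#'   only entries that diagnostic reasoning over abnormal evidence can
#'   never need (state-0 columns and the state-0 prior entry) are eligible,
#'   so generated problems stay solvable.
#' @param inert_normal when `TRUE` (default) a parent's normal state never
#'   causes an abnormal child state: every state-0 column is
#'   `(1, 0, ..., 0)`.  This matches the diagnostic reading of causality
#'   and makes the symbolic engine's semantics coincide with full Bayesian
#'   conditioning on the subclass used for oracle-equivalence checks.
#' @param exclusive_pair put the first two B variables' state-1 events
#'   into one exclusive category.
#' @return a `ducg_generator_config` list.
#' @export
ducg_generator_config <- function(seed, n_b = 2, n_x = 6, n_gates = 0,
                                  max_states = 3, edge_density = 0.5,
                                  unknown_fraction = 0,
                                  inert_normal = TRUE,
                                  exclusive_pair = FALSE) {
  stopifnot(n_b >= 1, n_x >= 1, max_states >= 2,
            edge_density >= 0, edge_density <= 1,
            unknown_fraction >= 0, unknown_fraction <= 1)
  structure(list(seed = as.integer(seed), n_b = n_b, n_x = n_x,
                 n_gates = n_gates, max_states = max_states,
                 edge_density = edge_density,
                 unknown_fraction = unknown_fraction,
                 inert_normal = inert_normal,
                 exclusive_pair = exclusive_pair),
            class = "ducg_generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random valid model
#'
#' Draws a random DAG (B variables first, then X variables each picking
#' parents among the earlier variables, then optional gates over earlier
#' X variables with randomly partitioned state expressions), random
#' positive causal columns normalized to 1, and small positive priors.
#' Every generated model passes [validate_model()]; generation is
#' deterministic per configuration.
#'
#' @param config a [ducg_generator_config()].
#' @return a validated [ducg_model()].
#' @export
generate_model <- function(config) {
  stopifnot(inherits(config, "ducg_generator_config"))
  with_seed(config$seed, generate_model_impl(config))
}

generate_model_impl <- function(config) {
  n_b <- config$n_b; n_x <- config$n_x
  rand_states <- function() {
    if (config$max_states == 2L) 2L
    else sample(2:config$max_states, 1L)
  }
  b_ids <- paste0("B", seq_len(n_b))
  x_ids <- paste0("X", n_b + seq_len(n_x))
  variables <- c(
    lapply(b_ids, function(id) ducg_variable(id, rand_states())),
    lapply(x_ids, function(id) ducg_variable(id, rand_states()))
  )
  nstates <- stats::setNames(
    vapply(variables, function(v) v$n_states, integer(1)),
    vapply(variables, function(v) v$id, character(1)))

  rand_col <- function(k) { g <- stats::rexp(k) + 0.2; g / sum(g) }
  make_a <- function(child, parent) {
    nr <- nstates[[child]]; nc <- nstates[[parent]]
    a <- matrix(0, nr, nc)
    if (config$inert_normal) a[, 1] <- c(1, rep(0, nr - 1L))
    else a[, 1] <- rand_col(nr)
    for (j in 2:nc) a[, j] <- rand_col(nr)
    a
  }

  arcs <- list()
  gates <- list()
  gate_ids <- character(0)
  pool <- b_ids
  for (t in seq_along(x_ids)) {
    id <- x_ids[[t]]
    avail <- if (t == 1L) b_ids else pool
    extra <- stats::rbinom(1L, min(2L, length(avail) - 1L), config$edge_density)
    parents <- sample(avail, 1L + extra)
    for (p in parents)
      arcs[[length(arcs) + 1L]] <- ducg_arc(p, id, make_a(id, p))
    pool <- c(pool, id)
    # occasionally insert a gate over two earlier X variables
    if (length(gates) < config$n_gates && t >= 2L) {
      gid <- paste0("G", n_b + n_x + length(gates) + 1L)
      inputs <- sample(x_ids[seq_len(t)], 2L)
      combos <- expand.grid(lapply(nstates[inputs], function(n) 0:(n - 1L)),
                            KEEP.OUT.ATTRS = FALSE)
      names(combos) <- inputs
      lab <- sample(c(0L, 1L), nrow(combos), replace = TRUE, prob = c(0.6, 0.4))
      if (!any(lab == 1L)) lab[nrow(combos)] <- 1L
      if (!any(lab == 0L)) lab[1L] <- 0L
      prods <- lapply(which(lab == 1L), function(i) {
        v <- as.integer(combos[i, , drop = TRUE]); names(v) <- inputs; v
      })
      gates[[length(gates) + 1L]] <- ducg_gate(gid, inputs, list("1" = prods))
      variables[[length(variables) + 1L]] <- ducg_variable(gid, 2L)
      nstates[[gid]] <- 2L
      gate_ids <- c(gate_ids, gid)
      pool <- c(pool, gid)
    }
  }
  # give any childless gate a dedicated X child
  for (gid in gate_ids) {
    has_child <- any(vapply(arcs, function(a) a$parent == gid, logical(1)))
    if (!has_child) {
      id <- paste0("X", n_b + n_x + length(gate_ids) + var_index(gid))
      variables[[length(variables) + 1L]] <- ducg_variable(id, 2L)
      nstates[[id]] <- 2L
      arcs[[length(arcs) + 1L]] <- ducg_arc(gid, id, make_a(id, gid))
    }
  }

  priors <- lapply(stats::setNames(nm = b_ids), function(id) {
    k <- nstates[[id]]
    b0 <- stats::runif(1, 0.85, 0.95)
    rest <- rand_col(k - 1L) * (1 - b0)
    c(b0, rest)
  })
  categories <- list()
  if (config$exclusive_pair && n_b >= 2L)
    categories <- list(exclusive = list(c("B1,1", "B2,1")))

  m <- ducg_model(variables, arcs, gates, priors, categories)

  if (config$unknown_fraction > 0) {
    for (i in seq_along(m$arcs)) {
      if (stats::runif(1) < config$unknown_fraction)
        m$arcs[[i]]$a[, 1] <- NA_real_      # never consulted for abnormal chains
    }
    for (id in names(m$priors)) {
      if (stats::runif(1) < config$unknown_fraction)
        m$priors[[id]][1] <- NA_real_
    }
    m <- index_model(m)
  }
  m
}

#' Generate a solvable random evidence set
#'
#' Forward-samples the model until an assignment with at least
#' `n_abnormal` abnormal X states is found, then observes those variables
#' (guaranteeing the evidence has positive probability).
#'
#' @param model a fully parameterized [ducg_model()].
#' @param seed integer seed.
#' @param n_abnormal minimum number of abnormal observations.
#' @param max_tries sampling attempts before giving up.
#' @return a [ducg_evidence()] of abnormal observations.
#' @export
generate_evidence <- function(model, seed, n_abnormal = 2, max_tries = 2000) {
  with_seed(seed, {
    xs <- model$variables$id[model$variables$kind == "X"]
    for (i in seq_len(max_tries)) {
      draw <- sample_forward(model, 1)
      abn <- xs[vapply(xs, function(id) draw[[id]][1] != 0L, logical(1))]
      if (length(abn) >= n_abnormal) {
        take <- abn[seq_len(n_abnormal)]
        return(ducg_evidence(stats::setNames(
          vapply(take, function(id) as.integer(draw[[id]][1]), integer(1)),
          take)))
      }
    }
    ducg_abort("could not sample evidence with the requested abnormality",
               "ducg_size_error")
  })
}

#' A small demonstration model for BPPV subtype differentiation
#'
#' A ~30-variable causality graph using the published variable identities
#' of the benign-paroxysmal-positional-vertigo differential-diagnosis
#' domain: root causes B23-B33 (canal subtypes PSCC/LSCC/ASCC/MSCC,
#' etiologies secondary/idiopathic, mechanisms canalithiasis/
#' cupulolithiasis, and atypical forms subjective/persistent/recurrent),
#' the four category sets (canal, etiology and mechanism categories are
#' mutually exclusive; atypical forms are concurrent), a shared
#' pathophysiology cascade, demographic findings driven by default causes,
#' and positional-test findings whose causal columns differentiate the
#' subtypes.
#'
#' All numeric parameters are invented PLACEHOLDERS: the clinical model's
#' parameters are not published.  Only structural outcomes (candidate
#' sets, hypothesis composition, normalization) are meaningful; the
#' probabilities themselves are illustrative.
#'
#' @return a validated [ducg_model()] (with `meta$placeholder_parameters
#'   = TRUE`).
#' @export
bppv_demo_model <- function() {
  na <- NA_real_
  b_ids <- paste0("B", 23:33)
  b_labels <- c("PSCC-BPPV", "LSCC-BPPV", "ASCC-BPPV", "MSCC-BPPV",
                "secondary BPPV", "idiopathic BPPV", "canalithiasis BPPV",
                "cupulolithiasis BPPV", "subjective BPPV",
                "persistent BPPV", "recurrent BPPV")
  variables <- c(
    lapply(seq_along(b_ids), function(i)
      ducg_variable(b_ids[[i]], 2, labels = c("absent", b_labels[[i]]))),
    list(
      ducg_variable("X1", 2, labels = c("normal", "otoconia debris displaced")),
      ducg_variable("X4", 2, labels = c("absent", "illusion of movement")),
      ducg_variable("X21", 3),
      ducg_variable("X24", 4),
      ducg_variable("X184", 5), ducg_variable("X185", 3),
      ducg_variable("X207", 2), ducg_variable("X208", 2),
      ducg_variable("X209", 5),
      ducg_variable("X222", 4), ducg_variable("X223", 2),
      ducg_variable("X224", 2), ducg_variable("X225", 2),
      ducg_variable("X226", 2),
      ducg_variable("X229", 3), ducg_variable("X230", 3),
      ducg_variable("X236", 2),
      ducg_variable("D184", 1), ducg_variable("D185", 1)
    )
  )

  col2 <- function(p) c(1 - p, p)
  arcs <- list()
  # shared pathophysiology: every root cause can displace otoconia debris
  for (b in b_ids)
    arcs[[length(arcs) + 1L]] <- ducg_arc(b, "X1", cbind(c(1, 0), col2(0.8)))
  cascade <- function(child, col) {
    arcs[[length(arcs) + 1L]] <<- ducg_arc("X1", child, cbind(c(1, rep(0, length(col) - 1L)), col))
  }
  cascade("X4", c(0.1, 0.9))
  cascade("X21", c(0.2, 0.3, 0.5))
  cascade("X24", c(0.2, 0.2, 0.2, 0.4))
  cascade("X207", c(0.85, 0.15))
  cascade("X208", c(0.85, 0.15))
  cascade("X236", c(0.6, 0.4))
  # demographics are driven by default causes
  arcs[[length(arcs) + 1L]] <-
    ducg_arc("D184", "X184", matrix(c(0.1, 0.15, 0.2, 0.25, 0.3), ncol = 1))
  arcs[[length(arcs) + 1L]] <-
    ducg_arc("D185", "X185", matrix(c(0.2, 0.35, 0.45), ncol = 1))
  # positional provocation (X209): state 3 ~ pitch-plane (Dix-Hallpike),
  # state 4 ~ roll-plane (supine roll); explicit zeros differentiate canals
  x209 <- list(B23 = c(0.2, 0.1, 0.1, 0.6, 0),
               B24 = c(0.2, 0.1, 0.1, 0, 0.6),
               B28 = c(0.2, 0.1, 0.1, 0.3, 0.3),
               B29 = c(0.2, 0.1, 0.1, 0.3, 0.3),
               B30 = c(0.3, 0.05, 0.05, 0.3, 0.3),
               B32 = c(0.3, 0.1, 0.1, 0.5, 0))
  for (b in names(x209))
    arcs[[length(arcs) + 1L]] <-
      ducg_arc(b, "X209", cbind(c(1, rep(0, 4)), x209[[b]]))
  # Dix-Hallpike findings (X222-X226)
  x222 <- list(B23 = c(0.1, 0.1, 0.1, 0.7), B28 = c(0.2, 0.2, 0.2, 0.4),
               B29 = c(0.1, 0.15, 0.15, 0.6), B32 = c(0.2, 0.2, 0.2, 0.4))
  for (b in names(x222))
    arcs[[length(arcs) + 1L]] <-
      ducg_arc(b, "X222", cbind(c(1, 0, 0, 0), x222[[b]]))
  dh2 <- list(B23 = 0.8, B28 = 0.6, B29 = 0.7, B32 = 0.5)
  for (ch in c("X223", "X224", "X225", "X226"))
    for (b in names(dh2))
      arcs[[length(arcs) + 1L]] <-
        ducg_arc(b, ch, cbind(c(1, 0), col2(dh2[[b]])))
  # supine-roll findings (X229, X230)
  roll <- list(B24 = c(0.1, 0.2, 0.7), B28 = c(0.2, 0.3, 0.5),
               B30 = c(0.1, 0.1, 0.8))
  for (ch in c("X229", "X230"))
    for (b in names(roll))
      arcs[[length(arcs) + 1L]] <-
        ducg_arc(b, ch, cbind(c(1, 0, 0), roll[[b]]))

  priors <- list(
    B23 = c(na, 0.020), B24 = c(na, 0.008), B25 = c(na, 0.002),
    B26 = c(na, 0.001), B27 = c(na, 0.005), B28 = c(na, 0.030),
    B29 = c(na, 0.015), B30 = c(na, 0.004), B31 = c(na, 0.002),
    B32 = c(na, 0.003), B33 = c(na, 0.004)
  )
  categories <- list(
    exclusive = list(
      c("B23,1", "B24,1", "B25,1", "B26,1"),   # affected canal
      c("B27,1", "B28,1"),                     # etiology
      c("B29,1", "B30,1")                      # mechanism
    ),
    concurrent = c("B31,1", "B32,1", "B33,1")  # atypical forms
  )
  ducg_model(variables, arcs, list(), priors, categories,
             meta = list(
               description = paste(
                 "Demonstration model for BPPV subtype differentiation.",
                 "PLACEHOLDER parameters: the clinical model's parameters",
                 "are not published; only structural outcomes are meaningful."),
               placeholder_parameters = TRUE
             ))
}

#' Demonstration evidence sets for the BPPV demo model
#'
#' Two observation vectors shaped like the published clinical cases (a
#' roll-provoked presentation and a pitch-provoked presentation); on the
#' demo model they reproduce the published hypothesis compositions
#' structurally.
#'
#' @param case 1 or 2.
#' @return a [ducg_evidence()].
#' @export
bppv_demo_evidence <- function(case = 1) {
  if (case == 1) {
    ducg_evidence(X4 = 1, X21 = 2, X24 = 3, X184 = 4, X185 = 2, X209 = 4,
                  X229 = 2, X230 = 2, X207 = 0, X208 = 0, X236 = 0)
  } else if (case == 2) {
    ducg_evidence(X4 = 1, X21 = 2, X24 = 3, X184 = 4, X185 = 2, X207 = 0,
                  X208 = 0, X209 = 3, X222 = 3, X223 = 1, X224 = 1,
                  X225 = 1, X226 = 1, X236 = 0)
  } else {
    ducg_abort("case must be 1 or 2", "ducg_usage_error")
  }
}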