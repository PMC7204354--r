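test_that("expression evaluation reproduces the worked example's context priors", {
  m <- figure1_model()
  ev <- worked_example_evidence()

  e_b1 <- expand_evidence_product(ev, track_causality(m, ev, "B1,1"))
  # product of the printed entries: 0.5*0.9*0.9*0.8*0.6*0.6*0.8*0.6*0.9*0.02
  expect_equal(eval_expression(e_b1, m), 0.0010077696, tolerance = 1e-12)

  e_b2 <- expand_evidence_product(ev, track_causality(m, ev, "B2,1"))
  expect_equal(eval_expression(e_b2, m), 0.0004758912, tolerance = 1e-12)
  expect_equal(eval_expression(e_b2, m),
               0.5 * 0.000279936 + 0.5 * 0.0006718464, tolerance = 1e-12)

  # empty expression and a bare root-cause event
  expect_identical(eval_expression(ducg:::new_expression(), m), 0)
  t <- ducg:::term_add_bd(ducg:::new_term(), "B1", 1L)
  expect_equal(eval_expression(ducg:::new_expression(list(t)), m), 0.02)
})

test_that("a needed unknown parameter raises a missing-parameter error naming it", {
  m <- figure1_model()
  t <- ducg:::term_add_a(ducg:::new_term(), "X4", 1L, "X8", 0L)  # a4,1;8,0 = "-"
  err <- tryCatch(eval_expression(ducg:::new_expression(list(t)), m),
                  ducg_missing_parameter = function(e) e)
  expect_s3_class(err, "ducg_missing_parameter")
  expect_match(conditionMessage(err), "a4,1;8,0")
  # a genuinely unknown prior entry (the state-0 remnant is derivable and
  # does not count as missing)
  t0 <- ducg:::term_add_bd(ducg:::new_term(), "B1", 0L)
  expect_equal(eval_expression(ducg:::new_expression(list(t0)), m), 0.98)
  m2 <- m
  m2$priors$B2[2] <- NA_real_
  t2 <- ducg:::term_add_bd(ducg:::new_term(), "B2", 1L)
  err2 <- tryCatch(eval_expression(ducg:::new_expression(list(t2)), m2),
                   ducg_missing_parameter = function(e) e)
  expect_match(conditionMessage(err2), "b2,1")
})

test_that("state probabilities reproduce the worked example and its invariants", {
  m <- figure1_model()
  ev <- worked_example_evidence()
  res <- diagnose(m, ev)
  tab <- as.data.frame(res)
  expect_equal(tab$event, c("B1,1", "B2,1"))
  expect_equal(round(tab$h, 3), c(0.679, 0.321))
  expect_equal(tab$zeta, c(0.0010077696, 0.0004758912), tolerance = 1e-12)
  expect_prob_equal(sum(tab$h), 1)
  expect_true(all(tab$h >= 0 & tab$h <= 1))
  # final h proportional to the in-context joint Pr{H E}
  joint <- tab$h_context * tab$zeta
  expect_prob_equal(tab$h, joint / sum(joint))
})

test_that("degenerate and trivial hypothesis spaces are handled", {
  m <- toy_dead_chain()
  expect_equal(diagnose(m, ducg_evidence(X3 = 1))$status,
               "empty_hypothesis_space")
  expect_equal(diagnose(m, ducg_evidence(X2 = 0))$status,
               "no_abnormal_evidence")

  # single candidate: h = 1
  res <- diagnose(m, ducg_evidence(X2 = 1))
  expect_equal(as.data.frame(res)$h, 1)

  # symmetric two-cause toy: h = 1/2, 1/2
  sym <- toy_two_cause(b1 = 0.02, b2 = 0.02, a3 = c(0.6, 0.6), a4 = c(0.5, 0.5))
  rs <- diagnose(sym, ducg_evidence(X3 = 1, X4 = 1))
  expect_prob_equal(as.data.frame(rs)$h, c(0.5, 0.5))
})

test_that("ranked independent probabilities normalize per-constituent context weights", {
  m <- bppv_demo_model()
  for (case in 1:2) {
    res <- diagnose(m, bppv_demo_evidence(case))
    expect_prob_equal(sum(res$ranked), 1)
    # equals zeta_i / sum(zeta_i) over the individual tracking graphs
    tab <- as.data.frame(res)
    keep <- tab$event %in% as.character(res$composed)
    zr <- tab$zeta[keep] / sum(tab$zeta[keep])
    expect_prob_equal(unname(res$ranked[tab$event[keep]]), zr)
  }
  # single-constituent hypothesis
  single <- diagnose(toy_dead_chain(), ducg_evidence(X2 = 1))
  sp <- single$hypothesis_space
  ranked <- ranked_independent_probabilities(
    compose_concurrent_hypothesis("B1,1"), sp$contexts,
    ducg_evidence(X2 = 1), toy_dead_chain())
  expect_identical(unname(ranked), 1)
})

test_that("three concurrent constituents rank by brute-force per-context evidence priors", {
  # three B's in different exclusive categories, sharing all three findings
  col2 <- function(p) cbind(c(1, 0), c(1 - p, p))
  arcs <- list()
  ps <- list(B1 = c(0.6, 0.3, 0.8), B2 = c(0.2, 0.7, 0.5), B3 = c(0.4, 0.4, 0.4))
  for (b in names(ps)) for (k in 1:3)
    arcs[[length(arcs) + 1L]] <- ducg_arc(b, paste0("X", 3 + k), col2(ps[[b]][k]))
  m <- ducg_model(
    c(lapply(1:3, function(i) ducg_variable(paste0("B", i), 2)),
      lapply(1:3, function(k) ducg_variable(paste0("X", 3 + k), 2))),
    arcs, list(),
    list(B1 = c(NA, 0.01), B2 = c(NA, 0.02), B3 = c(NA, 0.005)),
    list(exclusive = list("B1,1", "B2,1", "B3,1"))
  )
  ev <- ducg_evidence(X4 = 1, X5 = 1, X6 = 1)
  res <- diagnose(m, ev)
  expect_equal(as.character(res$composed), c("B1,1", "B2,1", "B3,1"))
  # oracle: per-candidate context prior of E with the other causes pruned
  zeta <- vapply(names(ps), function(b)
    prod(ps[[b]]) * c(B1 = 0.01, B2 = 0.02, B3 = 0.005)[[b]], numeric(1))
  expect_prob_equal(unname(res$ranked), unname(zeta / sum(zeta)))
})

test_that("deleting parameters outside the expansions leaves the diagnosis bit-identical", {
  m0 <- figure1_model()
  m1 <- figure1_self_reliance_mutant()
  ev <- worked_example_evidence()
  r0 <- as.data.frame(diagnose(m0, ev))
  r1 <- as.data.frame(diagnose(m1, ev))
  expect_identical(r0$h, r1$h)
  expect_identical(r0$zeta, r1$zeta)
  for (h in c("B1,1", "B2,1")) {
    expect_identical(
      expr_canonical(expand_evidence_product(ev, track_causality(m1, ev, h))),
      expr_canonical(expand_evidence_product(ev, track_causality(m0, ev, h))))
  }
})
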