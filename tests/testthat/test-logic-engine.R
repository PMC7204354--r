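test_that("single-event expansions reproduce the worked example's context expressions", {
  m <- figure1_model()
  ev <- worked_example_evidence()
  ctx2 <- track_causality(m, ev, "B2,1")

  # X5,1 in the context of B2,1: two branches with weight 1/2 each
  e5 <- expand_event("X5,1", ctx2)
  expect_setequal(expr_terms(e5),
                  c("1/2 A5,1;2,1 B2,1",
                    "1/2 A4,1;8,1 A5,1;4,1 A8,1;2,1 B2,1"))

  # X11,2 routes through the gate; the X10,1 branch is killed by X10 = 2
  e11 <- expand_event("X11,2", ctx2)
  expect_equal(expr_terms(e11),
               "A6,1;8,1 A8,1;2,1 A9,1;6,1 A10,2;10D A11,2;12,1 B2,1")

  # X3,1 single chain
  e3 <- expand_event("X3,1", ctx2)
  expect_equal(expr_terms(e3), "A3,1;7,2 A7,2;8,1 A8,1;2,1 B2,1")
})

test_that("an X with one unobserved full-matrix parent expands with weight 1 over parent states", {
  m <- ducg_model(
    list(ducg_variable("B1", 3), ducg_variable("X2", 2)),
    list(ducg_arc("B1", "X2", cbind(c(0.7, 0.3), c(0.4, 0.6), c(0.2, 0.8)))),
    list(), list(B1 = c(0.9, 0.06, 0.04))
  )
  e <- expand_event("X2,1", m)   # unrestricted expansion over all states
  expect_setequal(expr_terms(e),
                  c("A2,1;1,0 B1,0", "A2,1;1,1 B1,1", "A2,1;1,2 B1,2"))
  expect_equal(eval_expression(e, m), 0.9 * 0.3 + 0.06 * 0.6 + 0.04 * 0.8)
})

test_that("the evidence product matches the worked example's expansions term-for-term", {
  m <- figure1_model()
  ev <- worked_example_evidence()

  e_b2 <- expand_evidence_product(ev, track_causality(m, ev, "B2,1"))
  expect_equal(
    expr_canonical(e_b2),
    paste("1/2 A3,1;7,2 A4,1;8,1 A5,1;4,1 A6,1;8,1 A7,2;8,1 A8,1;2,1 A9,1;6,1 A10,2;10D A11,2;12,1 B2,1",
          "1/2 A3,1;7,2 A5,1;2,1 A6,1;8,1 A7,2;8,1 A8,1;2,1 A9,1;6,1 A10,2;10D A11,2;12,1 B2,1",
          sep = " + ")
  )

  e_b1 <- expand_evidence_product(ev, track_causality(m, ev, "B1,1"))
  expect_equal(
    expr_canonical(e_b1),
    "A3,1;7,2 A4,1;8,1 A5,1;4,1 A6,1;8,1 A7,2;8,1 A8,1;1,1 A9,1;6,1 A10,2;10D A11,2;12,1 B1,1"
  )
})

test_that("multiplying an expression with itself leaves it unchanged", {
  m <- figure1_model()
  ev <- worked_example_evidence()
  for (h in c("B1,1", "B2,1")) {
    E <- expand_evidence_product(ev, track_causality(m, ev, h))
    E2 <- expr_multiply(E, E)
    expect_identical(expr_canonical(E2), expr_canonical(E))
    expect_equal(eval_expression(E2, m), eval_expression(E, m))
  }
})

test_that("exclusion wipes terms mixing events from one exclusive category", {
  m <- toy_two_cause(exclusive = TRUE)
  # explanations of two different findings through the two exclusive causes
  e1 <- expand_event("X3,1", track_causality(m, ducg_evidence(X3 = 1), "B1,1"))
  e2 <- expand_event("X4,2", track_causality(m, ducg_evidence(X4 = 2), "B2,1"))
  prod <- expr_multiply(e1, e2)
  expect_true(any(vapply(prod$terms, function(t)
    all(c("B1,1", "B2,1") %in% t$bd), logical(1))))
  cleaned <- apply_exclusions(prod, m)
  expect_length(cleaned$terms, 0L)
})

test_that("same-variable different-state events annihilate a term", {
  t <- ducg:::new_term()
  t <- ducg:::term_add_a(t, "X3", 1L, "X2", 1L)
  expect_null(ducg:::term_add_a(t, "X4", 1L, "X2", 2L))   # X2 cannot be 1 and 2
  expect_null(ducg:::term_add_bd(ducg:::term_add_a(ducg:::new_term(),
                                                   "X3", 1L, "B1", 1L),
                                 "B1", 2L))
})

test_that("gate-branch absorption drops subsumed products and reductions preserve value", {
  # state expression X9,1 + X9,1 X10,2: the longer product is absorbed
  m <- ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("X9", 2), ducg_variable("X10", 3),
         ducg_variable("D10", 1), ducg_variable("X11", 2), ducg_variable("G12", 2)),
    list(ducg_arc("B1", "X9", cbind(c(1, 0), c(0.4, 0.6))),
         ducg_arc("D10", "X10", matrix(c(0.5, 0.2, 0.3), ncol = 1)),
         ducg_arc("G12", "X11", cbind(c(1, 0), c(0.1, 0.9)))),
    list(ducg_gate("G12", c("X9", "X10"),
                   list("1" = list(c(X9 = 1L), c(X9 = 1L, X10 = 2L))))),
    list(B1 = c(0.98, 0.02))
  )
  ctx <- track_causality(m, ducg_evidence(X11 = 1), "B1,1")
  e <- expand_evidence_product(ducg_evidence(X11 = 1), ctx)
  # absorbed: only the X9,1 product remains, no X10 factor
  expect_equal(expr_terms(e), "A9,1;1,1 A11,1;12,1 B1,1")
  # posterior agrees with exhaustive enumeration (the gate chain forces B1)
  post <- posterior_b_states(m, ducg_evidence(X11 = 1))
  res <- diagnose(m, ducg_evidence(X11 = 1))
  expect_equal(as.data.frame(res)$event, "B1,1")
  expect_prob_equal(as.data.frame(res)$h, 1)
  expect_prob_equal(post[["B1,1"]], 1)
})

test_that("merging identical event sets sums their coefficients exactly", {
  t1 <- ducg:::new_term(num = 1, den = 3)
  t1 <- ducg:::term_add_a(t1, "X3", 1L, "B1", 1L)
  t2 <- ducg:::new_term(num = 1, den = 6)
  t2 <- ducg:::term_add_a(t2, "X3", 1L, "B1", 1L)
  e <- ducg:::reduce_expression(ducg:::new_expression(list(t1, t2)))
  expect_length(e$terms, 1L)
  expect_identical(ducg:::term_coef(e$terms[[1]]), c(num = 1, den = 2))
})

test_that("DBV construction merges exclusive candidates into one variable", {
  m <- toy_two_cause(exclusive = TRUE)
  dbv <- build_dbv(c("B1,1", "B2,1"), m)
  expect_equal(dbv$state_map, c("1" = "B1,1", "2" = "B2,1"))
  mm <- dbv$model
  expect_false(any(c("B1", "B2") %in% mm$variables$id))
  bv <- dbv$variable
  expect_equal(mm$n_states[[bv]], 3L)
  # merged weight: both parents had r = 1 and nonzero causal functions
  arc3 <- ducg:::model_arc(mm, bv, "X3")
  expect_equal(arc3$r, 2)
  # inherited columns preserve the original state-1 columns
  orig3 <- lapply(c("B1", "B2"), function(b) ducg:::model_arc(m, b, "X3")$a[, 2])
  expect_equal(arc3$a[, 2], orig3[[1]])
  expect_equal(arc3$a[, 3], orig3[[2]])
  # prior: state probabilities carried over, remnant on state 0
  expect_equal(mm$priors[[bv]], c(1 - 0.02 - 0.03, 0.02, 0.03))

  expect_error(build_dbv("B1,1", m), class = "ducg_usage_error")
  expect_error(build_dbv(c("B1,1", "B2,1"), toy_two_cause(exclusive = FALSE)),
               class = "ducg_usage_error")
})

test_that("DBV posteriors equal constrained exhaustive enumeration", {
  for (seedish in 1:5) {
    b1 <- 0.01 * seedish; b2 <- 0.05 - 0.005 * seedish
    m <- toy_two_cause(b1 = b1, b2 = b2,
                       a3 = c(0.5 + 0.05 * seedish, 0.4),
                       a4 = c(0.3, 0.5 + 0.04 * seedish),
                       exclusive = TRUE)
    ev <- ducg_evidence(X3 = 1, X4 = 2)
    res <- diagnose(m, ev)
    dtab <- res$dbv[["exclusive1"]]$table
    post <- posterior_b_states(m, ev, exclusive = "merge")
    oracle <- c(post[["B1,1"]], post[["B2,1"]])
    oracle <- oracle / sum(oracle)
    expect_prob_equal(dtab$h[match(c("B1,1", "B2,1"), dtab$original)], oracle)
  }
})

test_that("concurrent hypotheses compose into the maximal conjunction", {
  expect_equal(as.character(compose_concurrent_hypothesis(
    c("B28,1", "B24,1", "B30,1"))), c("B24,1", "B28,1", "B30,1"))
  expect_equal(as.character(compose_concurrent_hypothesis("B5,1")), "B5,1")
  m <- bppv_demo_model()
  r2 <- diagnose(m, bppv_demo_evidence(2))
  expect_equal(as.character(r2$composed),
               c("B23,1", "B28,1", "B29,1", "B32,1"))
})
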