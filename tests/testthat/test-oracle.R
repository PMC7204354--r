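test_that("enumeration reproduces hand-computed joints on a two-variable model", {
  m <- ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("X2", 2)),
    list(ducg_arc("B1", "X2", cbind(c(1, 0), c(0.4, 0.6)))),
    list(), list(B1 = c(0.98, 0.02))
  )
  joint <- enumerate_joint(m)
  expect_equal(nrow(joint), 4L)
  expect_prob_equal(sum(joint$probability), 1)
  expect_equal(joint$probability[joint$B1 == 1 & joint$X2 == 1],
               0.02 * 0.6, tolerance = 1e-12)
})

test_that("gates are deterministic in the enumerated joint", {
  # the worked example's gate: state 1 is X9,1 X10,2 + X10,1
  m <- ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("X9", 2), ducg_variable("X10", 3),
         ducg_variable("D10", 1), ducg_variable("X11", 2), ducg_variable("G12", 2)),
    list(ducg_arc("B1", "X9", cbind(c(1, 0), c(0.4, 0.6))),
         ducg_arc("D10", "X10", matrix(c(0.5, 0.2, 0.3), ncol = 1)),
         ducg_arc("G12", "X11", cbind(c(1, 0), c(0.1, 0.9)))),
    list(ducg_gate("G12", c("X9", "X10"),
                   list("1" = list(c(X9 = 1L, X10 = 2L), c(X10 = 1L))))),
    list(B1 = c(0.98, 0.02))
  )
  joint <- enumerate_joint(m)
  want <- as.integer(joint$X10 == 1 | (joint$X9 == 1 & joint$X10 == 2))
  expect_equal(joint$G12, want)
  expect_prob_equal(sum(joint$probability), 1)
})

test_that("a fully parameterized closure of the worked-example graph normalizes", {
  m <- figure1_model()
  # stated completion: normal states are inert and unknown entries spread
  # the remaining mass uniformly over the unconstrained child states
  for (i in seq_along(m$arcs)) {
    a <- m$arcs[[i]]$a
    for (j in seq_len(ncol(a))) {
      col <- a[, j]
      if (!anyNA(col)) next
      if (var_kind(m$arcs[[i]]$parent) != "D" && j == 1L) {
        a[, j] <- c(1, rep(0, nrow(a) - 1L))
      } else {
        miss <- is.na(col)
        a[miss, j] <- (1 - sum(col[!miss])) / sum(miss)
      }
    }
    m$arcs[[i]]$a <- a
  }
  m$priors <- lapply(m$priors, function(b) { b[1] <- 1 - sum(b[-1]); b })
  m <- ducg:::index_model(m)
  expect_equal(validate_model(m), character(0))
  joint <- enumerate_joint(m)
  expect_prob_equal(sum(joint$probability), 1)
})

test_that("posteriors condition on normal observations and detect degeneracy", {
  sym <- toy_two_cause(b1 = 0.02, b2 = 0.02, a3 = c(0.6, 0.6), a4 = c(0.5, 0.5))
  post <- posterior_b_states(sym, ducg_evidence(X3 = 1, X4 = 1))
  expect_prob_equal(post[["B1,1"]], post[["B2,1"]])
  # observing X4 normal changes the posterior relative to ignoring it
  post_n <- posterior_b_states(sym, ducg_evidence(X3 = 1, X4 = 0))
  post_i <- posterior_b_states(sym, ducg_evidence(X3 = 1))
  expect_true(post_n[["B1,1"]] < post_i[["B1,1"]])
  # impossible evidence
  dead <- toy_dead_chain()
  expect_error(posterior_b_states(dead, ducg_evidence(X3 = 1)),
               class = "ducg_degenerate_evidence")
  # state-space bound
  expect_error(enumerate_joint(sym, max_assignments = 3),
               class = "ducg_size_error")
})

test_that("conditioning on more evidence never increases the evidence probability", {
  m <- generate_model(ducg_generator_config(seed = 77, n_b = 2, n_x = 4,
                                            max_states = 3))
  joint <- enumerate_joint(m)
  ev <- generate_evidence(m, seed = 78, n_abnormal = 2)
  pe <- function(obs) {
    keep <- rep(TRUE, nrow(joint))
    for (vn in names(obs)) keep <- keep & joint[[vn]] == obs[[vn]]
    sum(joint$probability[keep])
  }
  expect_lte(pe(ev), pe(ev[1]))
  expect_lte(pe(ev[1]), 1)
})

test_that("forward sampling agrees with enumeration within binomial 3 sigma", {
  m <- generate_model(ducg_generator_config(seed = 5, n_b = 2, n_x = 4,
                                            max_states = 3))
  joint <- enumerate_joint(m)
  n <- 1e5
  draws <- ducg:::with_seed(99, sample_forward(m, n))
  for (id in c("X3", "X4", "X5")) {
    if (!id %in% names(draws)) next
    for (k in 0:(m$n_states[[id]] - 1L)) {
      p <- sum(joint$probability[joint[[id]] == k])
      phat <- mean(draws[[id]] == k)
      se <- sqrt(max(p * (1 - p), 1e-12) / n)
      expect_lt(abs(phat - p), max(3 * se, 1e-3))
    }
  }
})

test_that("engine posteriors match the oracle exactly on the renormalization-free subclass", {
  checked <- 0
  for (s in 1:40) {
    m <- generate_model(ducg_generator_config(seed = 500 + s, n_b = 1,
                                              n_x = 3 + s %% 4,
                                              n_gates = s %% 3 == 0,
                                              max_states = 3))
    if (nrow(m$variables) > 8) next
    ev <- try(generate_evidence(m, seed = 600 + s, n_abnormal = 2),
              silent = TRUE)
    if (inherits(ev, "try-error")) next
    res <- diagnose(m, ev)
    if (res$status != "ok") next
    tab <- as.data.frame(res)
    post <- posterior_b_states(m, ev)
    oracle <- post[tab$event] / sum(post[tab$event])
    expect_prob_equal(tab$h, unname(oracle))
    checked <- checked + 1
  }
  expect_gte(checked, 25)
})
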