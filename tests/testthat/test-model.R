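test_that("the shipped worked-example fixture loads and matches the in-code model", {
  path <- system.file("extdata", "figure1.json", package = "ducg")
  m <- load_model(path)
  expect_s3_class(m, "ducg_model")
  counts <- table(m$variables$kind)
  expect_equal(as.integer(counts[c("B", "X", "G", "D")]), c(2L, 9L, 1L, 1L))
  # 11 weighted arcs plus 2 logical gate inputs = 13 causal links
  expect_length(m$arcs, 11L)
  expect_length(m$gates$G12$inputs, 2L)
  expect_equal(m$priors$B2[3], 0.04)
  expect_equal(model_params <- m$arcs[[ which(vapply(m$arcs, function(a)
    a$parent == "X7" && a$child == "X3", logical(1))) ]]$a[2, 3], 0.5)
  expect_equal(validate_model(m), character(0))
  expect_equal(m[c("variables", "arcs", "gates", "priors", "categories")],
               figure1_model()[c("variables", "arcs", "gates", "priors", "categories")])
})

test_that("a minimal model validates and serialization round-trips losslessly", {
  m <- ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("X2", 2)),
    list(ducg_arc("B1", "X2", cbind(c(1, 0), c(0.4, 0.6)))),
    list(), list(B1 = c(0.98, 0.02))
  )
  expect_equal(validate_model(m), character(0))
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  expect_equal(load_model(tf)[1:6], m[1:6])
})

test_that("unknown entries survive a round-trip and are never coerced to 0", {
  m <- figure1_model()
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  m2 <- load_model(tf)
  a52 <- model_arc <- ducg:::model_arc(m2, "B2", "X5")$a
  expect_true(is.na(a52[1, 1]))          # unknown stays unknown
  expect_identical(a52[2, 3], 0)         # explicit zero stays zero
  expect_identical(m2$priors$B1[1], NA_real_)
})

test_that("generated models round-trip identically (seed 42)", {
  m <- generate_model(ducg_generator_config(seed = 42, n_b = 2, n_x = 5,
                                            n_gates = 1,
                                            unknown_fraction = 0.3))
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  expect_equal(load_model(tf)[1:6], m[1:6])
})

test_that("validation reports each corruption of the worked-example fixture", {
  base <- figure1_model()

  # a-column no longer summing to 1, diagnostic names the column
  m <- base
  m$arcs[[10]]$a[, 1] <- c(0.2, 0.2, 0.8)  # D10 -> X10 column now sums to 1.2
  d <- validate_model(m)
  expect_length(d, 1L)
  expect_match(d, "D10->X10")
  expect_match(d, "parent state 0")

  # load_model refuses the same corruption
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  expect_error(load_model(tf), class = "ducg_validation_error")

  # D variable as arc child (a D node given a parent)
  m <- base
  m$arcs[[length(m$arcs) + 1L]] <- ducg:::normalize_arc(
    ducg_arc("X3", "D10", matrix(c(NA, 1), nrow = 1)))
  m <- ducg:::index_model(m)
  expect_match(validate_model(m), "children must be X", all = FALSE)

  # prior vector summing past 1
  m <- base
  m$priors$B2 <- c(NA, 0.9, 0.6)
  expect_match(validate_model(m), "sum to 1.5", all = FALSE)

  # a cycle
  m <- base
  m$arcs[[length(m$arcs) + 1L]] <- ducg:::normalize_arc(
    ducg_arc("X3", "X7", matrix(c(NA, NA, NA, 0.4, NA, 0.6), nrow = 3)))
  m <- ducg:::index_model(m)
  expect_match(validate_model(m), "cycle", all = FALSE)

  # gate literal referencing a non-input
  m <- base
  m$gates$G12$state_exprs[["1"]][[1]] <- c(X9 = 1L, X8 = 1L)
  expect_match(validate_model(m), "not a declared input", all = FALSE)

  # every known matrix entry corrupted out of [0,1] draws a diagnostic
  for (i in seq_along(base$arcs)) {
    a <- base$arcs[[i]]$a
    for (j in seq_len(ncol(a))) {
      for (k in seq_len(nrow(a))) {
        if (is.na(a[k, j])) next
        m <- base
        m$arcs[[i]]$a[k, j] <- 1.5
        expect_gt(length(validate_model(m)), 0)
      }
    }
  }
  # and in a fully parameterized model any perturbation of a known entry
  # breaks a column normalization
  full <- bppv_demo_model()
  arc <- ducg:::model_arc(full, "B24", "X209")
  i <- which(vapply(full$arcs, function(a)
    a$parent == "B24" && a$child == "X209", logical(1)))
  for (k in seq_len(nrow(arc$a))) {
    m <- full
    m$arcs[[i]]$a[k, 2] <- arc$a[k, 2] + 0.05
    expect_match(validate_model(m), "sums to", all = FALSE)
  }
})

test_that("evidence construction, validation and file round-trip work", {
  m <- figure1_model()
  ev <- worked_example_evidence()
  expect_length(ev, 7L)
  expect_true(all(ev != 0))
  expect_silent(ducg:::check_evidence(m, ev))
  expect_error(ducg:::check_evidence(m, ducg_evidence(X99 = 1)),
               class = "ducg_validation_error")
  expect_error(ducg:::check_evidence(m, ducg_evidence(X3 = 5)),
               class = "ducg_validation_error")
  tf <- withr::local_tempfile(fileext = ".json")
  write_evidence(ev, tf)
  expect_equal(as.integer(read_evidence(tf)), as.integer(ev))
})
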