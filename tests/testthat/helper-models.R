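# Shared toy models built in code.

# B1 -> X2 -> X3 chain; a_{3,1;2,1} is an explicit zero so an abnormal X3
# cannot be explained through X2 state 1.
toy_dead_chain <- function() {
  ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("X2", 2), ducg_variable("X3", 2)),
    list(ducg_arc("B1", "X2", cbind(c(1, 0), c(0.4, 0.6))),
         ducg_arc("X2", "X3", cbind(c(1, 0), c(1, 0)))),
    list(),
    list(B1 = c(0.98, 0.02))
  )
}

# fully parameterized two-cause diamond: B1 and B2 both explain X3 and X4
toy_two_cause <- function(b1 = 0.02, b2 = 0.03,
                          a3 = c(0.7, 0.4), a4 = c(0.3, 0.7),
                          exclusive = FALSE) {
  ducg_model(
    list(ducg_variable("B1", 2), ducg_variable("B2", 2),
         ducg_variable("X3", 2), ducg_variable("X4", 3)),
    list(ducg_arc("B1", "X3", cbind(c(1, 0), c(1 - a3[1], a3[1]))),
         ducg_arc("B2", "X3", cbind(c(1, 0), c(1 - a3[2], a3[2]))),
         ducg_arc("B1", "X4", cbind(c(1, 0, 0), c(1 - a4[1], a4[1] / 3, 2 * a4[1] / 3))),
         ducg_arc("B2", "X4", cbind(c(1, 0, 0), c(1 - a4[2], a4[2] / 3, 2 * a4[2] / 3)))),
    list(),
    list(B1 = c(1 - b1, b1), B2 = c(1 - b2, b2)),
    if (exclusive) list(exclusive = list(c("B1,1", "B2,1"))) else list()
  )
}

# the parameters appearing in the worked example's two context expansions
figure1_used_entries <- function() {
  list(c("X3", 1, "X7", 2), c("X4", 1, "X8", 1), c("X5", 1, "B2", 1),
       c("X5", 1, "X4", 1), c("X6", 1, "X8", 1), c("X7", 2, "X8", 1),
       c("X8", 1, "B1", 1), c("X8", 1, "B2", 1), c("X9", 1, "X6", 1),
       c("X10", 2, "D10", 0), c("X11", 2, "G12", 1))
}

# blank every known nonzero parameter value outside the two context
# expansions (explicit zeros are structural knowledge and stay)
figure1_self_reliance_mutant <- function() {
  m <- figure1_model()
  used <- figure1_used_entries()
  for (i in seq_along(m$arcs)) {
    arc <- m$arcs[[i]]
    keep <- matrix(FALSE, nrow(arc$a), ncol(arc$a))
    for (u in used) {
      if (u[[3]] == arc$parent && u[[1]] == arc$child)
        keep[as.integer(u[[2]]) + 1L, as.integer(u[[4]]) + 1L] <- TRUE
    }
    blank <- !keep & !is.na(arc$a) & arc$a != 0
    m$arcs[[i]]$a[blank] <- NA_real_
  }
  m$priors$B2[3] <- NA_real_   # b2,2 is not part of either expansion
  ducg:::index_model(m)
}

expect_prob_equal <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) < tol),
              label = paste0("max |diff| = ", format(max(abs(x - y)))))
}
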