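# Internal helpers: condition classes, exact rational coefficients, event keys.

ducg_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "ducg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exact rational coefficients --------------------------------------------
# Coefficients are products of renormalized weight ratios r'_{n;i} / r'_n.
# When all weights are integer-valued (the usual case; every worked example
# uses r = 1) the ratio is kept as an exact reduced fraction.  Doubles hold
# the integer numerator/denominator exactly below 2^53.

rat_is_int <- function(x) abs(x - round(x)) < 1e-9 && abs(x) < 2^52

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

rat <- function(num, den = 1) {
  if (den == 0) ducg_abort("rational with zero denominator", "ducg_internal_error")
  if (rat_is_int(num) && rat_is_int(den)) {
    num <- round(num); den <- round(den)
    if (den < 0) { num <- -num; den <- -den }
    g <- rat_gcd(num, den)
    if (g > 0.5) { num <- num / g; den <- den / g }
    c(num = num, den = den)
  } else {
    # non-integer weights: fall back to a plain ratio
    c(num = num / den, den = 1)
  }
}

rat_mul <- function(a, b) rat(a[[1]] * b[[1]], a[[2]] * b[[2]])

rat_add <- function(a, b) rat(a[[1]] * b[[2]] + b[[1]] * a[[2]], a[[2]] * b[[2]])

rat_value <- function(a) a[[1]] / a[[2]]

rat_format <- function(a) {
  if (abs(a[[2]] - 1) < 1e-12) {
    if (rat_is_int(a[[1]])) format(round(a[[1]])) else format(a[[1]])
  } else {
    paste0(format(a[[1]]), "/", format(a[[2]]))
  }
}

# ---- variable and event keys ------------------------------------------------

var_kind <- function(id) substr(id, 1L, 1L)

var_index <- function(id) suppressWarnings(as.integer(substr(id, 2L, nchar(id))))

lit_key <- function(var, state) paste0(var, ",", state)

lit_parse <- function(key) {
  p <- strsplit(key, ",", fixed = TRUE)[[1]]
  list(var = p[[1]], state = as.integer(p[[2]]))
}

# Canonical event-key for B/D terminal events: "B2,1" for B, "D10" for D.
bd_key <- function(var, state) {
  if (var_kind(var) == "D") var else paste0(var, ",", state)
}

# Internal A-event key (unambiguous, full variable ids):
#   "X3,1;X7,2" for ordinary parents, "X10,2;D10" for a default cause.
a_key <- function(child, k, parent, j) {
  if (var_kind(parent) == "D") {
    paste0(child, ",", k, ";", parent)
  } else {
    paste0(child, ",", k, ";", parent, ",", j)
  }
}

# Display form matching the field's notation: A3,1;7,2 and A10,2;10D.
a_display <- function(ev) {
  if (var_kind(ev$parent) == "D") {
    paste0("A", var_index(ev$child), ",", ev$k, ";", var_index(ev$parent), "D")
  } else {
    paste0("A", var_index(ev$child), ",", ev$k, ";", var_index(ev$parent), ",", ev$j)
  }
}

a_sort_key <- function(ev) {
  sprintf("%08d,%04d;%08d,%04d", var_index(ev$child), ev$k,
          var_index(ev$parent), if (is.na(ev$j)) 0L else ev$j)
}

bd_display <- function(key) {
  if (var_kind(key) == "D") key else key
}

bd_sort_key <- function(key) {
  p <- lit_parse(if (var_kind(key) == "D") paste0(key, ",0") else key)
  sprintf("%s%08d,%04d", var_kind(key), var_index(p$var), p$state)
}

# Parameter names as printed in reports/errors: a3,1;7,2 / a10,2;10D / b2,1.
param_name_a <- function(child, k, parent, j) {
  if (var_kind(parent) == "D") {
    paste0("a", var_index(child), ",", k, ";", var_index(parent), "D")
  } else {
    paste0("a", var_index(child), ",", k, ";", var_index(parent), ",", j)
  }
}

param_name_b <- function(var, state) paste0("b", var_index(var), ",", state)
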