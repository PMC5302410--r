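# Independent oracles used across the suite. These deliberately avoid the
# package's code paths they are meant to check.

# Literal evaluation of the threshold rule: signed sum of regulator states
# compared against the midpoint n/2 - m with a strict inequality, written
# exactly as defined (floating-point threshold, explicit loop).
oracle_threshold <- function(states, signs) {
  n <- length(signs)
  m <- sum(signs == -1)
  r <- 0
  for (j in seq_along(signs)) r <- r + states[j] * signs[j]
  if (r > n / 2 - m) 1L else 0L
}

# All 2^n regulator configurations as a matrix (rows = configurations).
all_configs <- function(n) {
  if (n == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# Naive basin enumeration: simulate every initial condition step by step in
# R (via simulate_to_attractor, which uses the interpreted update path) and
# tally canonical attractor keys. Independent of the compiled
# functional-graph engine.
oracle_enumerate <- function(net, controls, clamps = NULL) {
  enumerate_attractors(net, controls, clamps = clamps, method = "simulate")
}

# Named full state helper.
full_state <- function(net, internal_values, controls = NULL) {
  s <- stats::setNames(integer(net$N), node_names(net))
  if (!is.null(controls)) s[names(controls)] <- controls
  s[names(internal_values)] <- internal_values
  s
}

# Compare two basin_set objects by canonical attractor keys and basin sizes.
expect_same_basins <- function(a, b) {
  ka <- vapply(a$attractors, function(x) x$key, "")
  kb <- vapply(b$attractors, function(x) x$key, "")
  expect_setequal(ka, kb)
  expect_equal(a$basin_sizes[order(ka)], b$basin_sizes[order(kb)])
}
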