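fig2_net <- function() {
  parse_network(c("[nodes]", "V1 control", "V2 control", "V3 control",
                  "Vi internal",
                  "[edges]", "V1 -> Vi", "V2 -> Vi", "V3 -| Vi"))
}

test_that("threshold update reproduces the worked two-activator-one-inhibitor table", {
  net <- fig2_net()
  s <- regulator_summary(net, "Vi")
  # full truth table for (s1, s2, s3); on iff r = s1 + s2 - s3 > 0.5
  cases <- all_configs(3)
  for (k in seq_len(nrow(cases))) {
    st <- stats::setNames(cases[k, ], c("V1", "V2", "V3"))
    expect_identical(threshold_update(s, st),
                     oracle_threshold(cases[k, ], c(1, 1, -1)))
  }
  # spot values quoted for this configuration
  expect_equal(threshold_update(s, c(V1 = 1, V2 = 0, V3 = 0)), 1L)
  expect_equal(threshold_update(s, c(V1 = 0, V2 = 1, V3 = 1)), 0L)
})

test_that("the tie sits on the midpoint and resolves to off (strict inequality)", {
  toys <- toy_catalogue()
  g <- regulator_summary(toys$and_gate, "G")
  expect_equal(threshold_update(g, c(X1 = 1, X2 = 0)), 0L)
  expect_equal(threshold_update(g, c(X1 = 0, X2 = 1)), 0L)
  expect_equal(threshold_update(g, c(X1 = 1, X2 = 1)), 1L)
  # single inhibitory regulator, inhibitor off: r = 0 > -0.5 -> on
  net <- parse_network(c("[nodes]", "I control", "V internal",
                         "[edges]", "I -| V"))
  s <- regulator_summary(net, "V")
  expect_equal(threshold_update(s, c(I = 0)), 1L)
  expect_equal(threshold_update(s, c(I = 1)), 0L)
  expect_error(threshold_update(s, c(X = 1)), "missing regulator")
})

test_that("threshold update matches the literal-rule oracle on random regulator sets", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    signs <- sample(c(1L, -1L), n, replace = TRUE)
    nodes <- c(sprintf("R%d internal", seq_len(n)), "T internal")
    edges <- sprintf("R%d %s T", seq_len(n), ifelse(signs == 1, "->", "-|"))
    net <- parse_network(c("[nodes]", nodes, "[edges]", edges))
    s <- regulator_summary(net, "T")
    cfg <- all_configs(n)
    for (k in seq_len(nrow(cfg))) {
      st <- stats::setNames(cfg[k, ], sprintf("R%d", seq_len(n)))
      expect_identical(threshold_update(s, st),
                       oracle_threshold(cfg[k, ], signs))
    }
  }
})

test_that("synchronous step updates all internal nodes from the current state", {
  osc <- toy_catalogue()$oscillator
  s0 <- c(A = 0L, B = 0L)
  expect_equal(synchronous_step(osc, s0), c(A = 1L, B = 0L))
  expect_equal(synchronous_step(osc, c(A = 1L, B = 0L)), c(A = 1L, B = 1L))
  # fixed point maps to itself
  sa <- toy_catalogue()$self_activator
  expect_equal(synchronous_step(sa, c(A = 1L)), c(A = 1L))
  expect_equal(synchronous_step(sa, c(A = 0L)), c(A = 0L))
})

test_that("control nodes never change during a trajectory", {
  net <- toy_catalogue()$and_gate
  for (x1 in 0:1) for (x2 in 0:1) for (g in 0:1) {
    res <- simulate_to_attractor(net, c(X1 = x1, X2 = x2, G = g))
    expect_true(all(res$trajectory[, "X1"] == x1))
    expect_true(all(res$trajectory[, "X2"] == x2))
    expect_true(all(res$attractor$states[, "X1"] == x1))
  }
})

test_that("the oscillator yields one period-4 cycle with zero transient", {
  osc <- toy_catalogue()$oscillator
  res <- simulate_to_attractor(osc, c(A = 0L, B = 0L))
  expect_equal(res$attractor$period, 4)
  expect_equal(res$attractor$kind, "cycle")
  expect_equal(res$transient_length, 0)
  expect_equal(node_activity(res$attractor, "A"), 1 / 2)
})

test_that("the self-activator has two steady states", {
  sa <- toy_catalogue()$self_activator
  for (v in 0:1) {
    res <- simulate_to_attractor(sa, c(A = v))
    expect_equal(res$attractor$period, 1)
    expect_equal(res$attractor$kind, "steady")
    expect_equal(unname(res$attractor$states[1, "A"]), v)
  }
})

test_that("trajectories are deterministic and respect the termination bound", {
  for (seed in 1:8) {
    net <- random_threshold_network(1, 6, mean_in_degree = 2.5,
                                    inhibition_fraction = 0.4, seed = seed)
    init <- full_state(net, stats::setNames(
      as.integer(seed %% 2 == (seq_len(6) %% 2)), internal_nodes(net)),
      controls = stats::setNames(1L, control_nodes(net)))
    r1 <- simulate_to_attractor(net, init)
    r2 <- simulate_to_attractor(net, init)
    expect_identical(r1$trajectory, r2$trajectory)
    expect_identical(r1$attractor$key, r2$attractor$key)
    expect_lte(r1$transient_length + r1$attractor$period, 2^net$N_int)
  }
})

test_that("canonicalisation is rotation-invariant and idempotent", {
  osc <- toy_catalogue()$oscillator
  res <- simulate_to_attractor(osc, c(A = 0L, B = 0L))
  states <- res$attractor$states
  p <- nrow(states)
  keys <- vapply(seq_len(p), function(k) {
    rot <- states[((seq_len(p) + k - 2) %% p) + 1, , drop = FALSE]
    canonicalize_attractor(rot)$key
  }, "")
  expect_length(unique(keys), 1)
  again <- canonicalize_attractor(res$attractor$states)
  expect_identical(again$key, res$attractor$key)
  expect_identical(again$states, res$attractor$states)
  # distinct steady states get distinct canonical forms
  k0 <- canonicalize_attractor(matrix(0L, 1, 1, dimnames = list(NULL, "A")))$key
  k1 <- canonicalize_attractor(matrix(1L, 1, 1, dimnames = list(NULL, "A")))$key
  expect_false(k0 == k1)
})

test_that("canonicalisation verifies cycle closure when given the network", {
  osc <- toy_catalogue()$oscillator
  bad <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  expect_error(canonicalize_attractor(bad, net = osc), "closed cycle")
})

test_that("node_activity is the on-fraction of cycle steps", {
  # synthetic 7-step cycle with a node on in 3 of them
  m <- matrix(0L, 7, 2, dimnames = list(NULL, c("A", "B")))
  m[c(1, 4, 6), "A"] <- 1L
  att <- structure(list(states = m, period = 7L, kind = "cycle"),
                   class = "attractor")
  expect_equal(node_activity(att, "A"), 3 / 7)
  expect_equal(node_activity(att, "B"), 0)
  expect_error(node_activity(att, "Z"), "unknown node")
})

test_that("permanent clamps hold their value at every recorded step", {
  osc <- toy_catalogue()$oscillator
  clamp <- list(control_action("A", 1))
  res <- simulate_to_attractor(osc, c(A = 0L, B = 0L), clamps = clamp)
  expect_true(all(res$trajectory[, "A"] == 1L))
  expect_true(all(res$attractor$states[, "A"] == 1L))
  expect_equal(res$attractor$period, 1)  # B follows A; system freezes at (1,1)
  expect_equal(unname(res$attractor$states[1, "B"]), 1L)
})

test_that("windowed clamps apply only inside their window", {
  sa <- toy_catalogue()$self_activator
  # hold the self-activator on for steps 1..3 from the off state; after the
  # window it sustains itself (self-activation), so the final state is on
  res <- simulate_to_attractor(sa, c(A = 0L),
                               clamps = list(control_action("A", 1, 1, 3)))
  expect_equal(unname(res$trajectory[1, "A"]), 0L)
  expect_true(all(res$trajectory[2:4, "A"] == 1L))
  expect_equal(unname(res$attractor$states[1, "A"]), 1L)
  expect_error(control_action("A", 1, 5, 2), "start must not exceed")
  expect_error(simulate_to_attractor(sa, c(A = 0L),
                                     clamps = list(control_action("Z", 1))),
               "unknown node")
})

test_that("trajectory export has one row per step and a step column", {
  osc <- toy_catalogue()$oscillator
  res <- simulate_to_attractor(osc, c(A = 0L, B = 0L))
  df <- trajectory_table(res$trajectory)
  expect_equal(df$step, seq_len(nrow(res$trajectory)) - 1)
  expect_named(df, c("step", "A", "B"))
})
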