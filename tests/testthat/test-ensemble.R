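test_that("basin weights are exact dyadic rationals in range", {
  expect_equal(basin_weight(2^24, 24), 1)
  expect_equal(basin_weight(2^23, 24), 1 / 2)
  expect_equal(basin_weight(1, 2), 1 / 4)
  expect_error(basin_weight(0, 2), "out of range")
  expect_error(basin_weight(5, 2), "out of range")
})

test_that("the self-activator splits the state space into two unit basins", {
  b <- enumerate_attractors(toy_catalogue()$self_activator)
  expect_length(b$attractors, 2)
  expect_equal(b$basin_sizes, c(1, 1))
  expect_equal(b$weights, c(1 / 2, 1 / 2))
  expect_equal(sum(b$weights), 1)
  expect_setequal(vapply(b$attractors, function(a) a$kind, ""),
                  c("steady", "steady"))
})

test_that("the oscillator has a single period-4 attractor owning every state", {
  b <- enumerate_attractors(toy_catalogue()$oscillator)
  expect_length(b$attractors, 1)
  expect_equal(b$attractors[[1]]$period, 4)
  expect_equal(b$weights, 1)
})

test_that("weights always sum to exactly 1 on random networks", {
  for (seed in 1:10) {
    net <- random_threshold_network(1, 3 + seed %% 5, mean_in_degree = 2,
                                    inhibition_fraction = 0.3, seed = seed)
    ctl <- stats::setNames(seed %% 2, control_nodes(net))
    b <- enumerate_attractors(net, ctl)
    expect_identical(sum(b$weights), 1)
    expect_identical(sum(b$basin_sizes), 2^b$n_free)
  }
})

test_that("functional-graph enumeration agrees with naive simulation", {
  for (seed in 1:6) {
    net <- random_threshold_network(2, 4 + seed %% 3, mean_in_degree = 2.5,
                                    inhibition_fraction = 0.4, seed = 100 + seed)
    ctl <- stats::setNames(c(seed %% 2, (seed + 1) %% 2), control_nodes(net))
    fast <- enumerate_attractors(net, ctl, method = "graph")
    slow <- oracle_enumerate(net, ctl)
    expect_same_basins(fast, slow)
  }
})

test_that("average activity equals the basin-weighted mean and the direct mean", {
  # single attractor with full weight passes its activity through
  osc <- toy_catalogue()$oscillator
  b <- enumerate_attractors(osc)
  expect_equal(average_activity(b, "A"), 1 / 2)
  # two half-weight steady states at 0 and 1 average to 1/2
  sa <- toy_catalogue()$self_activator
  expect_equal(average_activity(enumerate_attractors(sa), "A"), 1 / 2)
  # equivalence with the per-initial-condition mean on 4-internal fixtures
  for (seed in 1:5) {
    net <- random_threshold_network(1, 4, mean_in_degree = 2,
                                    inhibition_fraction = 0.3, seed = 200 + seed)
    ctl <- stats::setNames(1L, control_nodes(net))
    b <- enumerate_attractors(net, ctl)
    node <- internal_nodes(net)[1]
    direct <- mean(vapply(0:15, function(s) {
      init <- full_state(net, carenet:::decode_state(s, internal_nodes(net)),
                         controls = ctl)
      node_activity(simulate_to_attractor(net, init)$attractor, node)
    }, numeric(1)))
    expect_equal(average_activity(b, node), direct, tolerance = 1e-12)
  }
})

test_that("combined reporter activity supports both readings", {
  expect_equal(combined_activity(1, 1), 1)
  expect_equal(combined_activity(0, 0), 0)
  expect_equal(combined_activity(1, 0), sqrt(1 / 2))
  expect_equal(combined_activity(1, 0, method = "meansq"), 0.5)
  expect_equal(combined_activity(1, 1, method = "meansq"), 1)
  # RMS preserves scale on the diagonal
  for (x in c(0.2, 0.5, 0.9))
    expect_equal(combined_activity(x, x), x)
  expect_error(combined_activity(1.2, 0), "\\[0, 1\\]")
})

test_that("activity bins are closed below with the top bin closed at 1", {
  expect_equal(as.character(classify_activity_bin(
    c(0, 0.1, 0.25, 0.49, 0.5, 0.7, 0.74, 0.75, 1))),
    c("none", "none", "low", "low", "medium", "medium", "medium",
      "high", "high"))
  expect_error(classify_activity_bin(-0.1), "\\[0, 1\\]")
  expect_error(classify_activity_bin(1.1), "\\[0, 1\\]")
})

test_that("the control-state scan enumerates every control assignment deterministically", {
  net <- parse_network(c("[nodes]", "C control", "A internal", "B internal",
                         "[edges]", "C -> A", "A -> B", "B -| A"))
  s1 <- control_state_scan(net, reporters = c("A", "B"))
  expect_equal(nrow(s1$table), 2)
  expect_equal(s1$table$C, c(0L, 1L))
  s2 <- control_state_scan(net, reporters = c("A", "B"))
  expect_identical(s1$table, s2$table)
  expect_true(all(s1$table$avg_combined >= 0 & s1$table$avg_combined <= 1))
})

test_that("final-state counting distinguishes control states by default", {
  # 1 control x self-activating internal node: 2 controls x 2 steady states
  net <- parse_network(c("[nodes]", "C control", "A internal",
                         "[edges]", "A -> A"))
  scan <- control_state_scan(net, reporters = c("A", "A"))
  s <- count_final_states(scan)
  expect_equal(s$total, 4)
  expect_equal(s$n_cycles, 0)
  expect_equal(s$max_period, 1)
  # merging on internal bits collapses identical steady states across controls
  m <- count_final_states(scan, merge_across_controls = TRUE)
  expect_equal(m$total, 2)
  # oscillator with no controls: one cycle, max period 4
  scan2 <- control_state_scan(toy_catalogue()$oscillator,
                              reporters = c("A", "B"))
  s2 <- count_final_states(scan2)
  expect_equal(unlist(s2), c(total = 1, n_cycles = 1, max_period = 4))
})

test_that("steady-state-only control states give dyadic average activities", {
  net <- parse_network(c("[nodes]", "C control", "A internal", "B internal",
                         "[edges]", "C -> A", "A -> B"))
  b <- enumerate_attractors(net, c(C = 1L))
  expect_true(all(vapply(b$attractors, function(a) a$kind, "") == "steady"))
  for (v in internal_nodes(net)) {
    a <- average_activity(b, v)
    expect_equal(a * 2^b$n_free, round(a * 2^b$n_free))
  }
})

test_that("clamping a node to 1 forces its average activity to 1 everywhere", {
  net <- parse_network(c("[nodes]", "C control", "A internal", "B internal",
                         "[edges]", "C -> A", "A -> B", "B -| A"))
  clamp <- list(control_action("B", 1))
  for (cv in 0:1) {
    b <- enumerate_attractors(net, c(C = cv), clamps = clamp)
    expect_equal(average_activity(b, "B"), 1)
  }
})

test_that("clamped internal nodes are excluded from the enumerated bits", {
  net <- toy_catalogue()$oscillator
  b <- enumerate_attractors(net, clamps = list(control_action("A", 0)))
  expect_equal(b$n_free, 1)
  expect_equal(sum(b$basin_sizes), 2)
  # fully clamped system: one steady state equal to the clamp vector
  b2 <- enumerate_attractors(net, clamps = list(control_action("A", 0),
                                                control_action("B", 1)))
  expect_equal(b2$n_free, 0)
  expect_equal(b2$weights, 1)
  expect_equal(unname(b2$attractors[[1]]$states[1, ]), c(0L, 1L))
})

test_that("the state-space cap guards enumeration", {
  net <- random_threshold_network(0, 6, mean_in_degree = 2,
                                  inhibition_fraction = 0.3, seed = 5)
  expect_error(enumerate_attractors(net, cap_bits = 4), "exceeds cap")
})

test_that("scan catalogue and TSV export carry one row per attractor", {
  net <- parse_network(c("[nodes]", "C control", "A internal",
                         "[edges]", "A -> A"))
  scan <- control_state_scan(net, reporters = c("A", "A"))
  cat_df <- scan_catalogue(scan)
  expect_equal(nrow(cat_df), 4)
  expect_true(all(c("control_row", "C", "period", "basin_size", "weight",
                    "activity_A") %in% names(cat_df)))
  tmp <- tempfile(fileext = ".tsv")
  write_scan(scan, tmp)
  expect_equal(nrow(utils::read.delim(tmp)), 2)
})
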