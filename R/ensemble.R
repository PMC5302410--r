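#' Basin weight of an attractor
#'
#' The probability of a final state under equiprobable initial conditions:
#' `p(F) = I(F) / 2^N_int`, where `I(F)` is the number of initial internal
#' states whose trajectory reaches `F`. Basin sizes are integers and the
#' denominator is a power of two, so the weight is a dyadic rational
#' represented exactly in double precision (for `N_int <= 52`); weights over
#' the attractors of one control state sum to 1 exactly.
#'
#' @param basin_size integer count `I(F)`, in `[1, 2^n_internal]`.
#' @param n_internal number of free internal nodes.
#' @return Exact dyadic weight in `(0, 1]`.
#' @export
basin_weight <- function(basin_size, n_internal) {
  total <- 2^n_internal
  if (any(basin_size < 1 | basin_size > total))
    stop("basin_size out of range [1, 2^n_internal]")
  basin_size / total
}

#' Exhaustively enumerate attractors and basins for one control state
#'
#' Every one of the `2^n_free` initial conditions of the free internal nodes
#' (internal nodes not held by a permanent clamp) is assigned to exactly one
#' attractor. The default `"graph"` method materialises the full transition
#' map in compiled code and resolves basins by functional-graph traversal;
#' `"simulate"` runs a plain per-initial-condition simulation in R and is
#' retained as a slow independent cross-check for small networks.
#'
#' Clamped internal nodes are excluded from the enumerated initial-condition
#' bits (their initial value is their clamp value), so basin weights are
#' normalised over the reduced space; for permanent clamps this leaves all
#' ensemble averages unchanged.
#'
#' @param net a `boolean_network`.
#' @param controls named 0/1 vector covering every control node.
#' @param clamps list of permanent [control_action()] objects (clamps on
#'   control nodes override the corresponding `controls` entry).
#' @param method `"graph"` (compiled engine) or `"simulate"` (R oracle).
#' @param cap_bits refuse enumeration above `2^cap_bits` states.
#' @return An object of class `basin_set`: list with `attractors` (list of
#'   canonical [canonicalize_attractor()] objects, sorted by canonical key),
#'   `basin_sizes`, `weights`, `n_free`, `free_nodes`, `controls`.
#' @export
enumerate_attractors <- function(net, controls = NULL, clamps = NULL,
                                 method = c("graph", "simulate"),
                                 cap_bits = 28) {
  method <- match.arg(method)
  ctrl <- control_nodes(net)
  if (is.null(controls)) controls <- stats::setNames(integer(length(ctrl)), ctrl)
  if (!all(ctrl %in% names(controls)))
    stop("controls must cover every control node")
  controls <- controls[ctrl]
  stopifnot(all(controls %in% c(0, 1)))

  if (length(clamps)) {
    if (any(vapply(clamps, function(a) !is.null(a$start), logical(1))))
      stop("ensemble enumeration supports permanent clamps only")
    cv <- active_clamp_values(clamps, t = 0L)
    unknown <- setdiff(names(cv), node_names(net))
    if (length(unknown)) stop("clamp references unknown node: ", unknown[1])
  } else {
    cv <- integer(0)
  }
  controls[intersect(names(cv), ctrl)] <- cv[intersect(names(cv), ctrl)]
  clamped_int <- intersect(names(cv), internal_nodes(net))
  free_nodes <- setdiff(internal_nodes(net), clamped_int)
  n_free <- length(free_nodes)
  if (n_free > cap_bits)
    stop("state space 2^", n_free, " exceeds cap 2^", cap_bits,
         "; raise cap_bits to proceed")

  fixed <- c(controls, cv[clamped_int])

  if (n_free == 0) {
    # fully clamped system: single steady state equal to the fixed vector
    state <- stats::setNames(as.integer(fixed[node_names(net)]),
                             node_names(net))
    att <- canonicalize_attractor(matrix(state, nrow = 1,
                                         dimnames = list(NULL, node_names(net))))
    return(new_basin_set(list(att), 1, 0, free_nodes, controls))
  }

  if (method == "simulate") {
    if (n_free > 16)
      stop("method 'simulate' is intended for small networks (n_free <= 16)")
    return(enumerate_by_simulation(net, controls, clamps, free_nodes))
  }

  summaries <- all_summaries(net)
  reg_idx <- vector("list", n_free)
  reg_sign <- vector("list", n_free)
  base_r <- integer(n_free)
  rhs <- integer(n_free)
  for (i in seq_len(n_free)) {
    s <- summaries[[free_nodes[i]]]
    src <- s$regulators$source
    sg <- s$regulators$sign
    is_free <- src %in% free_nodes
    reg_idx[[i]] <- match(src[is_free], free_nodes) - 1L
    reg_sign[[i]] <- as.integer(sg[is_free])
    base_r[i] <- if (any(!is_free))
      sum(as.integer(fixed[src[!is_free]]) * sg[!is_free]) else 0L
    rhs[i] <- s$n - 2L * s$m
  }

  res <- engine_enumerate(n_free, reg_idx, reg_sign, base_r, rhs)

  nodes <- node_names(net)
  full_template <- stats::setNames(integer(length(nodes)), nodes)
  full_template[names(fixed)] <- as.integer(fixed)
  attractors <- lapply(res$cycles, function(encs) {
    p <- length(encs)
    m <- matrix(rep(full_template, each = p), nrow = p,
                dimnames = list(NULL, nodes))
    for (k in seq_len(n_free))
      m[, free_nodes[k]] <- bitwAnd(bitwShiftR(encs, k - 1L), 1L)
    canonicalize_attractor(m)
  })
  new_basin_set(attractors, res$basin_sizes, n_free, free_nodes, controls)
}

# Naive per-initial-condition oracle path (R simulation only).
enumerate_by_simulation <- function(net, controls, clamps, free_nodes) {
  nodes <- node_names(net)
  n_free <- length(free_nodes)
  cv <- if (length(clamps)) active_clamp_values(clamps, t = 0L) else integer(0)
  template <- stats::setNames(integer(length(nodes)), nodes)
  template[names(controls)] <- as.integer(controls)
  template[names(cv)] <- as.integer(cv)
  tally <- new.env(hash = TRUE, parent = emptyenv())
  atts <- list()
  for (s in 0:(2^n_free - 1)) {
    init <- template
    init[free_nodes] <- decode_state(s, free_nodes)
    att <- simulate_to_attractor(net, init, clamps = clamps)$attractor
    prev <- tally[[att$key]]
    if (is.null(prev)) {
      atts[[att$key]] <- att
      assign(att$key, 1, envir = tally)
    } else {
      assign(att$key, prev + 1, envir = tally)
    }
  }
  keys <- names(atts)
  new_basin_set(atts[keys],
                vapply(keys, function(k) tally[[k]], numeric(1)),
                n_free, free_nodes, controls)
}

new_basin_set <- function(attractors, basin_sizes, n_free, free_nodes,
                          controls) {
  ord <- order(vapply(attractors, function(a) a$encodings[1], numeric(1)),
               vapply(attractors, function(a) a$period, numeric(1)))
  attractors <- attractors[ord]
  basin_sizes <- as.numeric(basin_sizes)[ord]
  weights <- basin_sizes / 2^n_free
  stopifnot(sum(basin_sizes) == 2^n_free, sum(weights) == 1)
  structure(
    list(attractors = unname(attractors), basin_sizes = basin_sizes,
         weights = weights, n_free = n_free, free_nodes = free_nodes,
         controls = controls),
    class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("Basin set: %d attractor(s) over 2^%d initial conditions\n",
              length(x$attractors), x$n_free))
  cat("  control state:",
      paste(names(x$controls), x$controls, sep = "=", collapse = " "), "\n")
  df <- as.data.frame(x)
  print(df[, c("id", "period", "kind", "basin_size", "weight")])
  invisible(x)
}

#' Tabulate a basin set as an attractor catalogue
#'
#' @param x a `basin_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per attractor: `id`, `period`, `kind`,
#'   `basin_size`, `weight`, and one `activity_<node>` column per node.
#' @export
as.data.frame.basin_set <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  act <- t(vapply(x$attractors,
                  function(a) colMeans(a$states),
                  numeric(ncol(x$attractors[[1]]$states))))
  colnames(act) <- paste0("activity_", colnames(act))
  data.frame(id = seq_along(x$attractors),
             period = vapply(x$attractors, function(a) a$period, numeric(1)),
             kind = vapply(x$attractors, function(a) a$kind, ""),
             basin_size = x$basin_sizes,
             weight = x$weights,
             act,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Basin-weighted average activity of a node under one control state
#'
#' Computes `sum_k p(F_k) * alpha_i(F_k)` over all attractors of the control
#' state. Because the weights are the fractions of initial conditions in each
#' basin, this equals the arithmetic mean of the node's attractor activity
#' over all `2^N_int` initial conditions.
#'
#' @param basins a `basin_set` from [enumerate_attractors()].
#' @param node node name.
#' @return Value in `[0, 1]`.
#' @export
average_activity <- function(basins, node) {
  stopifnot(inherits(basins, "basin_set"))
  if (!node %in% colnames(basins$attractors[[1]]$states))
    stop("unknown node: ", node)
  if (sum(basins$weights) != 1)
    stop("basin weights do not sum to 1")
  sum(basins$weights *
        vapply(basins$attractors, node_activity, numeric(1), node = node))
}

#' Combined proliferation activity of the two reporter nodes
#'
#' Aggregates the average activities of the WOX4 and HB8 reporters into a
#' single proliferation score. The default is the quadratic (root) mean
#' `sqrt((a^2 + b^2)/2)`, which preserves scale (`a = b = x` gives `x`); the
#' non-root variant `(a^2 + b^2)/2` is available via `method = "meansq"`.
#' Both map `[0,1]^2` to `[0,1]`.
#'
#' @param a_wox4,a_hb8 average reporter activities in `[0, 1]`; vectorised.
#' @param method `"rms"` (default) or `"meansq"`.
#' @return Combined activity in `[0, 1]`.
#' @export
combined_activity <- function(a_wox4, a_hb8, method = c("rms", "meansq")) {
  method <- match.arg(method)
  if (any(a_wox4 < 0 | a_wox4 > 1 | a_hb8 < 0 | a_hb8 > 1))
    stop("reporter activities must lie in [0, 1]")
  ms <- (a_wox4^2 + a_hb8^2) / 2
  if (method == "rms") sqrt(ms) else ms
}

#' Classify an activity value into the four standard bins
#'
#' Equal-width quarters of `[0, 1]`: `none` `[0, 0.25)`, `low` `[0.25, 0.5)`,
#' `medium` `[0.5, 0.75)`, `high` `[0.75, 1]`. Bins are closed below and the
#' top bin is closed at 1 so the four bins cover the whole interval.
#'
#' @param a numeric vector in `[0, 1]`.
#' @return Factor with levels `none`, `low`, `medium`, `high`.
#' @export
classify_activity_bin <- function(a) {
  if (any(a < 0 | a > 1)) stop("activity must lie in [0, 1]")
  lev <- c("none", "low", "medium", "high")
  factor(lev[pmin(floor(a * 4), 3) + 1], levels = lev)
}

# Deterministic table of control-state assignments: 2^k rows in binary
# counting order, first declared control most significant.
control_state_grid <- function(ctrl) {
  k <- length(ctrl)
  n <- 2^k
  g <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, ctrl))
  for (j in seq_len(k))
    g[, j] <- bitwAnd(bitwShiftR(0:(n - 1), k - j), 1L)
  g
}

#' Scan all control states of a network
#'
#' Enumerates attractors and basins for every assignment of the (unclamped)
#' control nodes — `2^6 = 64` control states for the bundled cambium network
#' — and reports per-row ensemble statistics: the basin-weighted average
#' activity of every internal node, the combined proliferation activity of
#' the two reporters, activity-bin labels, and the attractor count `K(C)`.
#' Rows follow binary counting order over the controls in declaration order,
#' so repeated runs are bit-identical.
#'
#' @param net a `boolean_network`.
#' @param clamps list of permanent [control_action()] objects; clamped
#'   control nodes are fixed and drop out of the scanned grid.
#' @param reporters pair of node names combined by [combined_activity()].
#' @param combine Eq-style combination method, see [combined_activity()].
#' @param cap_bits passed to [enumerate_attractors()].
#' @return An object of class `control_scan`: list with `table` (data.frame,
#'   one row per control state), `basins` (list of `basin_set`), `reporters`,
#'   `clamps`.
#' @export
control_state_scan <- function(net, clamps = NULL,
                               reporters = c("WOX4", "HB8"),
                               combine = c("rms", "meansq"),
                               cap_bits = 28) {
  combine <- match.arg(combine)
  stopifnot(all(reporters %in% node_names(net)), length(reporters) == 2)
  cv <- if (length(clamps)) active_clamp_values(clamps, t = 0L) else integer(0)
  ctrl <- setdiff(control_nodes(net), names(cv))
  grid <- control_state_grid(ctrl)
  ints <- internal_nodes(net)

  basins_list <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    controls <- stats::setNames(grid[r, ], ctrl)
    full_controls <- stats::setNames(integer(length(control_nodes(net))),
                                     control_nodes(net))
    full_controls[ctrl] <- controls
    full_controls[intersect(names(cv), names(full_controls))] <-
      cv[intersect(names(cv), names(full_controls))]
    b <- enumerate_attractors(net, full_controls, clamps = clamps,
                              cap_bits = cap_bits)
    basins_list[[r]] <- b
    avg <- vapply(ints, average_activity, numeric(1), basins = b)
    comb <- combined_activity(avg[reporters[1]], avg[reporters[2]],
                              method = combine)
    row <- c(as.list(controls),
             list(K = length(b$attractors)),
             as.list(stats::setNames(avg, paste0("avg_", ints))),
             list(avg_combined = comb,
                  bin_combined = as.character(classify_activity_bin(comb)),
                  bin_reporter1 =
                    as.character(classify_activity_bin(avg[reporters[1]]))))
    rows[[r]] <- as.data.frame(row, check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, basins = basins_list,
                 reporters = reporters, clamps = clamps,
                 controls = ctrl, internal = ints, combine = combine),
            class = "control_scan")
}

#' @export
print.control_scan <- function(x, ...) {
  cat(sprintf("Control-state scan: %d control state(s) over {%s}\n",
              nrow(x$table), paste(x$controls, collapse = ", ")))
  s <- count_final_states(x)
  cat(sprintf("  %d final states in total; %d limit cycles (max period %d)\n",
              s$total, s$n_cycles, s$max_period))
  invisible(x)
}

#' Count distinct final states across a full control-state scan
#'
#' By default attractors are identified by their canonical full-state cycle
#' including the control bits, so the same internal cycle under two different
#' control states counts twice (equivalently: distinct (control state,
#' canonical internal cycle) pairs). Set `merge_across_controls = TRUE` to
#' deduplicate on the internal bits only.
#'
#' @param scan a `control_scan`.
#' @param merge_across_controls logical; see above.
#' @return List with `total` (distinct final states), `n_cycles` (those with
#'   period >= 2) and `max_period`.
#' @export
count_final_states <- function(scan, merge_across_controls = FALSE) {
  stopifnot(inherits(scan, "control_scan"))
  atts <- unlist(lapply(scan$basins, function(b) b$attractors),
                 recursive = FALSE)
  if (merge_across_controls) {
    # identity on internal bits only: re-encode over internal columns
    keys <- vapply(atts, function(a) {
      m <- a$states[, scan$internal, drop = FALSE]
      enc <- apply(m, 1, function(row)
        sum(as.numeric(row) * 2^(seq_along(row) - 1)))
      r <- min_rotation(enc)
      p <- length(enc)
      paste(format(enc[((seq_len(p) + r - 2L) %% p) + 1L],
                   scientific = FALSE, trim = TRUE), collapse = ",")
    }, "")
    keep <- !duplicated(keys)
    atts <- atts[keep]
  }
  periods <- vapply(atts, function(a) a$period, numeric(1))
  list(total = length(atts),
       n_cycles = sum(periods >= 2),
       max_period = max(periods))
}

#' Write scan outputs as tab-separated files
#'
#' @param scan a `control_scan`.
#' @param scan_path path for the per-control-state table (one row per control
#'   state).
#' @param catalogue_path optional path for the attractor catalogue (one row
#'   per attractor with its control state, period, basin size, weight and
#'   per-node activities).
#' @return Invisibly, the catalogue data.frame.
#' @export
write_scan <- function(scan, scan_path, catalogue_path = NULL) {
  utils::write.table(format(scan$table, digits = 6, scientific = FALSE),
                     scan_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat_df <- scan_catalogue(scan)
  if (!is.null(catalogue_path))
    utils::write.table(format(cat_df, digits = 6, scientific = FALSE),
                       catalogue_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(cat_df)
}

#' Attractor catalogue of a scan as one data.frame
#'
#' @param scan a `control_scan`.
#' @return data.frame, one row per attractor across all control states.
#' @export
scan_catalogue <- function(scan) {
  out <- lapply(seq_along(scan$basins), function(r) {
    b <- scan$basins[[r]]
    df <- as.data.frame(b)
    ctrl <- as.data.frame(as.list(b$controls), check.names = FALSE)
    cbind(control_row = r, ctrl[rep(1, nrow(df)), , drop = FALSE], df,
          row.names = NULL)
  })
  do.call(rbind, out)
}
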