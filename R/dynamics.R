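#' Threshold update rule for a single node
#'
#' Computes the signed input sum `r` (`sum_j s_j * w_j`) over the node's
#' regulators and returns 1 exactly when `r` strictly exceeds the threshold
#' `n/2 - m` (the midpoint of the attainable range `[-m, n - m]`), else 0.
#' The strict inequality is deliberate: with two activators and exactly one
#' of them on, `r` sits on the midpoint and the node stays off — both
#' activators must be on. The comparison is carried out as `2*r > n - 2*m`
#' in integer arithmetic, which is exactly equivalent and immune to
#' floating-point ties.
#'
#' A node with no regulators has an input sum of 0 and threshold 0, so it evaluates
#' to 0: unregulated internal nodes decay to the off state after one step.
#'
#' @param summary a [regulator_summary()].
#' @param state named vector of 0/1 values covering at least the regulators.
#' @return 0 or 1 (integer).
#' @export
threshold_update <- function(summary, state) {
  stopifnot(inherits(summary, "regulator_summary"))
  src <- summary$regulators$source
  if (length(src)) {
    miss <- setdiff(src, names(state))
    if (length(miss))
      stop("missing regulator value: ", miss[1])
    r <- sum(as.integer(state[src]) * summary$regulators$sign)
  } else {
    r <- 0L
  }
  if (2L * r > summary$n - 2L * summary$m) 1L else 0L
}

# Active clamp values at step `t` (t = 0 is the initial state). Permanent
# actions apply at every step; windowed ones only inside [start, end].
active_clamp_values <- function(clamps, t) {
  vals <- integer(0)
  for (a in clamps) {
    if (is.null(a$start) || (t >= a$start && t <= a$end))
      vals[a$node] <- a$value
  }
  vals
}

#' Advance the whole network by one synchronous step
#'
#' All internal nodes are updated simultaneously from the *current* state via
#' [threshold_update()]; control nodes are copied unchanged. Clamped nodes
#' are forced to their clamp value after the update (override semantics).
#'
#' @param net a `boolean_network`.
#' @param state named 0/1 vector covering every node.
#' @param clamps list of [control_action()] objects (permanent ones only are
#'   honoured here; see [simulate_to_attractor()] for time windows).
#' @param summaries optional precomputed result of regulator summaries (an
#'   internal cache; pass the same list across calls to avoid recomputation).
#' @return Named 0/1 vector, same node order as `state`.
#' @export
synchronous_step <- function(net, state, clamps = NULL, summaries = NULL) {
  stopifnot(all(node_names(net) %in% names(state)))
  if (is.null(summaries)) summaries <- all_summaries(net)
  out <- state
  for (nm in internal_nodes(net))
    out[nm] <- threshold_update(summaries[[nm]], state)
  if (length(clamps)) {
    cv <- active_clamp_values(clamps, t = 1L)
    unknown <- setdiff(names(cv), node_names(net))
    if (length(unknown)) stop("clamp references unknown node: ", unknown[1])
    out[names(cv)] <- cv
  }
  out
}

# Integer encoding of the internal sub-state: bit k (0-based) is the k-th
# declared internal node. Returned as double so N_int up to 52 is exact.
encode_state <- function(state, internal) {
  sum(as.numeric(state[internal]) * 2^(seq_along(internal) - 1))
}

decode_state <- function(enc, internal) {
  bits <- as.integer(enc %/% 2^(seq_along(internal) - 1)) %% 2L
  names(bits) <- internal
  bits
}

# Full-state encoding over ALL nodes in declaration order; used as the
# attractor identity key (control bits included).
encode_full <- function(state, nodes) {
  sum(as.numeric(state[nodes]) * 2^(seq_along(nodes) - 1))
}

# Index (1-based) of the lexicographically minimal rotation of x.
min_rotation <- function(x) {
  p <- length(x)
  if (p == 1) return(1L)
  best <- 1L
  idx <- seq_len(p)
  for (k in 2:p) {
    a <- x[((idx + k - 2L) %% p) + 1L]
    b <- x[((idx + best - 2L) %% p) + 1L]
    d <- which(a != b)
    if (length(d) && a[d[1]] < b[d[1]]) best <- k
  }
  best
}

#' Canonicalise a closed state cycle into an attractor object
#'
#' An attractor (final state) is either a steady state (period 1) or a limit
#' cycle. To give every attractor a unique identity regardless of which of
#' its states a trajectory entered first, the cycle is rotated so that its
#' sequence of full-state integer encodings (all nodes, declaration order)
#' is lexicographically minimal. The operation is idempotent.
#'
#' @param states matrix of 0/1 rows (one per step, columns named by node)
#'   forming a closed cycle under [synchronous_step()].
#' @param net a `boolean_network`; if supplied, closure of the cycle is
#'   verified.
#' @return An object of class `attractor`: list with `states` (matrix in
#'   canonical rotation), `period`, `kind` (`"steady"`/`"cycle"`),
#'   `encodings` (full-state encodings per step) and `key` (string identity).
#' @export
canonicalize_attractor <- function(states, net = NULL) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1,
                                             dimnames = list(NULL, names(states)))
  if (!is.null(net)) {
    summaries <- all_summaries(net)
    p <- nrow(states)
    for (k in seq_len(p)) {
      nxt <- synchronous_step(net, states[k, ], summaries = summaries)
      if (!all(nxt == states[(k %% p) + 1L, ]))
        stop("states do not form a closed cycle under the synchronous update")
    }
  }
  nodes <- colnames(states)
  enc <- apply(states, 1, encode_full, nodes = nodes)
  r <- min_rotation(enc)
  p <- nrow(states)
  ord <- ((seq_len(p) + r - 2L) %% p) + 1L
  states <- states[ord, , drop = FALSE]
  rownames(states) <- NULL
  enc <- enc[ord]
  structure(
    list(states = states, period = p,
         kind = if (p == 1L) "steady" else "cycle",
         encodings = enc,
         key = paste(format(enc, scientific = FALSE, trim = TRUE),
                     collapse = ",")),
    class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("%s attractor, period %d\n",
              if (x$kind == "steady") "Steady-state" else "Limit-cycle",
              x$period))
  print(x$states)
  invisible(x)
}

#' Fraction of attractor steps in which a node is on
#'
#' For a steady state this is the node's state (0 or 1); for a limit cycle it
#' is the number of on-steps divided by the period, e.g. 3/7 for a node on in
#' 3 of 7 cycle steps. This converts the binary readout of the network into a
#' continuous activity scale.
#'
#' @param attractor an `attractor`.
#' @param node node name.
#' @return Value in `[0, 1]`.
#' @export
node_activity <- function(attractor, node) {
  stopifnot(inherits(attractor, "attractor"))
  if (!node %in% colnames(attractor$states))
    stop("unknown node: ", node)
  sum(attractor$states[, node]) / attractor$period
}

#' Simulate one trajectory until its attractor is reached
#'
#' Iterates the synchronous update from `initial` until a state repeats; the
#' repeating block is the attractor, the steps before it the transient. The
#' map is deterministic on a finite state space, so this always terminates
#' within `2^N_int` steps. Control nodes stay fixed throughout; permanent
#' clamps are applied to the initial state and to every step; time-windowed
#' clamps are applied only within their window (repeat detection starts only
#' after all windows have expired, since the dynamics are time-varying until
#' then).
#'
#' @param net a `boolean_network`.
#' @param initial named 0/1 vector covering every node (control values are
#'   taken from here).
#' @param clamps list of [control_action()] objects.
#' @return List with `attractor` (canonical [canonicalize_attractor()]
#'   object), `trajectory` (matrix, one row per step from the initial state
#'   up to attractor entry) and `transient_length`.
#' @export
simulate_to_attractor <- function(net, initial, clamps = NULL) {
  nodes <- node_names(net)
  stopifnot(all(nodes %in% names(initial)))
  state <- as.integer(initial[nodes])
  names(state) <- nodes
  if (length(clamps)) {
    unknown <- setdiff(vapply(clamps, function(a) a$node, ""), nodes)
    if (length(unknown)) stop("clamp references unknown node: ", unknown[1])
    cv <- active_clamp_values(clamps, t = 0L)
    state[names(cv)] <- cv
  }
  ends <- vapply(clamps, function(a) if (is.null(a$start)) 0L else a$end,
                 integer(1))
  settle <- if (length(ends)) max(0L, ends) else 0L

  summaries <- all_summaries(net)
  internal <- internal_nodes(net)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  history <- list(state)
  key <- paste(state, collapse = "")
  if (settle == 0L) assign(key, 1L, envir = seen)
  t <- 0L
  repeat {
    t <- t + 1L
    nxt <- state
    for (nm in internal)
      nxt[nm] <- threshold_update(summaries[[nm]], state)
    if (length(clamps)) {
      cv <- active_clamp_values(clamps, t = t)
      nxt[names(cv)] <- cv
    }
    state <- nxt
    key <- paste(state, collapse = "")
    if (t >= settle && !is.null(first <- seen[[key]])) {
      cycle_states <- history[first:length(history)]
      transient <- first - 1L
      traj <- do.call(rbind, history[seq_len(first)])
      colnames(traj) <- nodes
      cyc <- do.call(rbind, cycle_states)
      colnames(cyc) <- nodes
      return(list(attractor = canonicalize_attractor(cyc),
                  trajectory = traj,
                  transient_length = transient))
    }
    history[[length(history) + 1L]] <- state
    if (t >= settle) assign(key, length(history), envir = seen)
    if (t > settle + 2^net$N_int + 1L)
      stop("no attractor found within the state-space bound; internal error")
  }
}

#' Export a trajectory as a tab-separated table
#'
#' One row per step with a `step` index column and one 0/1 column per node.
#'
#' @param trajectory matrix as returned by [simulate_to_attractor()].
#' @param path optional output file.
#' @return data.frame of the table (invisibly if `path` given).
#' @export
trajectory_table <- function(trajectory, path = NULL) {
  df <- data.frame(step = seq_len(nrow(trajectory)) - 1L, trajectory,
                   check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
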