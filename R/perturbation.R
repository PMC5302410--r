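#' A control action: clamp a node to a fixed value
#'
#' Control actions manually override the state of a chosen node. A permanent
#' action (no window) forces the node to `value` at every step, which is how
#' knockout (`value = 0`) and constitutive (`value = 1`) alleles are
#' emulated. A windowed action applies only between steps `start` and `end`
#' (inclusive) and is supported in single-trajectory simulation only — final
#' states under temporary overrides are not well defined for ensemble runs.
#'
#' @param node node name.
#' @param value 0 or 1.
#' @param start,end optional window bounds (step indices, `start <= end`).
#' @return An object of class `control_action`.
#' @export
control_action <- function(node, value, start = NULL, end = NULL) {
  stopifnot(is.character(node), length(node) == 1, value %in% c(0, 1))
  if (xor(is.null(start), is.null(end)))
    stop("window requires both start and end")
  if (!is.null(start) && start > end)
    stop("window start must not exceed end")
  structure(list(node = node, value = as.integer(value),
                 start = if (!is.null(start)) as.integer(start),
                 end = if (!is.null(end)) as.integer(end)),
            class = "control_action")
}

#' @export
print.control_action <- function(x, ...) {
  win <- if (is.null(x$start)) "permanent"
         else sprintf("steps %d..%d", x$start, x$end)
  cat(sprintf("clamp %s = %d (%s)\n", x$node, x$value, win))
  invisible(x)
}

#' Build the clamp set for a mutant genotype
#'
#' Knocked-out nodes are clamped to 0 at every step, constitutive ones to 1;
#' e.g. clamping PXY to 0 emulates the *pxy* loss-of-function mutant. The
#' returned list plugs into every dynamics and ensemble operation.
#'
#' @param net a `boolean_network`.
#' @param knockouts,constitutive disjoint character vectors of node names.
#' @return List of permanent [control_action()] objects.
#' @export
mutant_clamps <- function(net, knockouts = character(),
                          constitutive = character()) {
  unknown <- setdiff(c(knockouts, constitutive), node_names(net))
  if (length(unknown)) stop("unknown node: ", unknown[1])
  both <- intersect(knockouts, constitutive)
  if (length(both))
    stop("node cannot be both knocked out and constitutive: ", both[1])
  c(lapply(knockouts, control_action, value = 0),
    lapply(constitutive, control_action, value = 1))
}

#' Response of a reporter to switching one hormone input on vs off
#'
#' Implements the hormone-response protocol: the hormone control node is
#' fixed at 1 (on arm) or 0 (off arm) while all remaining free control nodes
#' vary over every assignment; for each assignment the reporter's
#' basin-weighted average activity is computed over all initial conditions,
#' and the two arms are summarised by their unweighted means over the free
#' assignments (each control state equally likely). A fixed `background`
#' assignment can hold other controls constant (e.g. TDIF always on), and a
#' mutant clamp set can be supplied.
#'
#' @param net a `boolean_network`.
#' @param hormone a control node, not in `background`.
#' @param reporter node whose average activity is measured.
#' @param background named 0/1 vector fixing other control nodes.
#' @param clamps list of permanent [control_action()] objects.
#' @param cap_bits passed to [enumerate_attractors()].
#' @return Object of class `hormone_profile`: list with `hormone`,
#'   `reporter`, `avg_on`, `avg_off`, and `detail` (per-assignment
#'   data.frame).
#' @export
hormone_effect_profile <- function(net, hormone, reporter,
                                   background = NULL, clamps = NULL,
                                   cap_bits = 28) {
  ctrl <- control_nodes(net)
  stopifnot(hormone %in% ctrl)
  if (!reporter %in% node_names(net)) stop("unknown reporter: ", reporter)
  if (hormone %in% names(background))
    stop("hormone must not appear in the background assignment")
  cv <- if (length(clamps)) active_clamp_values(clamps, t = 0L) else integer(0)
  fixed <- c(background, cv[intersect(names(cv), ctrl)])
  free <- setdiff(ctrl, c(hormone, names(fixed)))
  grid <- control_state_grid(free)
  if (nrow(grid) == 0) grid <- matrix(integer(0), nrow = 1, ncol = 0)

  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    controls <- stats::setNames(integer(length(ctrl)), ctrl)
    controls[names(fixed)] <- as.integer(fixed)
    if (length(free)) controls[free] <- grid[r, ]
    a <- numeric(2)
    for (v in 0:1) {
      controls[hormone] <- v
      b <- enumerate_attractors(net, controls, clamps = clamps,
                                cap_bits = cap_bits)
      a[v + 1] <- average_activity(b, reporter)
    }
    base <- data.frame(avg_off = a[1], avg_on = a[2])
    rows[[r]] <- if (length(free))
      cbind(as.data.frame(as.list(stats::setNames(grid[r, ], free)),
                          check.names = FALSE), base)
    else base
  }
  detail <- do.call(rbind, rows)
  structure(list(hormone = hormone, reporter = reporter,
                 background = background,
                 avg_on = mean(detail$avg_on),
                 avg_off = mean(detail$avg_off),
                 detail = detail),
            class = "hormone_profile")
}

#' @export
print.hormone_profile <- function(x, ...) {
  cat(sprintf("%s response of %s: mean avg activity %.4f (on) vs %.4f (off)\n",
              x$hormone, x$reporter, x$avg_on, x$avg_off))
  invisible(x)
}

#' Two-hormone interaction table
#'
#' Computes the reporter's basin-weighted average activity for the four
#' on/off combinations of two hormone control nodes under a fixed background
#' assignment of all remaining controls (e.g. gibberellin x brassinosteroid
#' with every other input on).
#'
#' @param net a `boolean_network`.
#' @param hormones character vector of two distinct control nodes.
#' @param background named 0/1 vector covering the remaining control nodes.
#' @param reporter node whose average activity is measured.
#' @param clamps list of permanent [control_action()] objects.
#' @param cap_bits passed to [enumerate_attractors()].
#' @return 2x2 numeric matrix; rows = first hormone 0/1, cols = second
#'   hormone 0/1.
#' @export
interaction_scan <- function(net, hormones, background, reporter,
                             clamps = NULL, cap_bits = 28) {
  ctrl <- control_nodes(net)
  stopifnot(length(hormones) == 2, hormones[1] != hormones[2],
            all(hormones %in% ctrl))
  if (any(hormones %in% names(background)))
    stop("hormones must not appear in the background assignment")
  missing_bg <- setdiff(ctrl, c(hormones, names(background)))
  if (length(missing_bg))
    stop("background must fix remaining control node: ", missing_bg[1])
  out <- matrix(NA_real_, 2, 2,
                dimnames = list(paste0(hormones[1], "=", 0:1),
                                paste0(hormones[2], "=", 0:1)))
  controls <- stats::setNames(integer(length(ctrl)), ctrl)
  controls[names(background)] <- as.integer(background)
  for (i in 0:1) for (j in 0:1) {
    controls[hormones] <- c(i, j)
    b <- enumerate_attractors(net, controls, clamps = clamps,
                              cap_bits = cap_bits)
    out[i + 1, j + 1] <- average_activity(b, reporter)
  }
  out
}
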