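#' Generate a random signed-threshold network
#'
#' Draws a valid random network for property-based testing: `n_control`
#' input nodes (named `C1..`), `n_internal` internal nodes (`V1..`), each
#' internal node receiving a Poisson(`mean_in_degree`) number of regulators
#' sampled without replacement from all nodes (so duplicate regulator pairs
#' never arise and controls never gain in-edges), each edge inhibitory with
#' probability `inhibition_fraction`. Generation is driven entirely by the
#' supplied seed and leaves the session's global random state untouched.
#'
#' @param n_control number of control nodes (>= 0).
#' @param n_internal number of internal nodes (>= 1).
#' @param mean_in_degree mean regulator count per internal node.
#' @param inhibition_fraction probability that an edge is inhibitory.
#' @param seed integer seed; the same seed reproduces the same network.
#' @return A validated `boolean_network` with attribute `"seed"`.
#' @export
random_threshold_network <- function(n_control, n_internal,
                                     mean_in_degree = 2,
                                     inhibition_fraction = 0.3,
                                     seed) {
  stopifnot(n_internal >= 1, n_control >= 0,
            inhibition_fraction >= 0, inhibition_fraction <= 1,
            mean_in_degree >= 0)
  n_nodes <- n_control + n_internal
  if (mean_in_degree > n_nodes)
    stop("mean_in_degree exceeds the number of available source nodes")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  ctrl <- if (n_control > 0) paste0("C", seq_len(n_control)) else character(0)
  ints <- paste0("V", seq_len(n_internal))
  nodes <- data.frame(name = c(ctrl, ints),
                      role = rep(c("control", "internal"),
                                 c(n_control, n_internal)),
                      stringsAsFactors = FALSE)
  all_names <- nodes$name
  edges <- list()
  for (tgt in ints) {
    k <- min(stats::rpois(1, mean_in_degree), n_nodes)
    if (k == 0) next
    src <- sample(all_names, k)
    sgn <- ifelse(stats::runif(k) < inhibition_fraction, -1L, 1L)
    edges[[tgt]] <- data.frame(from = src, to = tgt, sign = sgn,
                               stringsAsFactors = FALSE)
  }
  net <- boolean_network(nodes, if (length(edges)) do.call(rbind, edges))
  attr(net, "seed") <- seed
  net
}

#' Catalogue of small networks with known attractor structure
#'
#' Deterministic toy instances used throughout the tests:
#' \describe{
#'   \item{self_activator}{one internal node activating itself: two steady
#'     states (0 and 1), basin weight 1/2 each.}
#'   \item{oscillator}{two internal nodes, `A -> B` and `B -| A`: a single
#'     period-4 limit cycle containing all four states.}
#'   \item{and_gate}{two control inputs both activating one internal node:
#'     the strict-inequality tie rule makes the gate an AND — with exactly
#'     one input on, the signed sum sits on the threshold midpoint and the
#'     node stays off.}
#' }
#'
#' @return Named list of `boolean_network` objects.
#' @export
toy_catalogue <- function() {
  list(
    self_activator = parse_network(c(
      "[nodes]", "A internal", "[edges]", "A -> A")),
    oscillator = parse_network(c(
      "[nodes]", "A internal", "B internal",
      "[edges]", "A -> B", "B -| A")),
    and_gate = parse_network(c(
      "[nodes]", "X1 control", "X2 control", "G internal",
      "[edges]", "X1 -> G", "X2 -> G"))
  )
}
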