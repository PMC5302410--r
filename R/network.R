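#' Construct a signed-threshold Boolean network
#'
#' A Boolean network consists of named nodes, each either a *control* node
#' (an external input whose state is fixed for a whole simulation run) or an
#' *internal* node (updated by the threshold rule), and signed directed edges.
#' An edge with sign `+1` is activatory, `-1` inhibitory. Control nodes may
#' not be the target of any edge.
#'
#' Node declaration order is significant: it fixes the bit position of every
#' internal node in integer state encodings (bit *k* is the *k*-th declared
#' internal node), so results are reproducible across runs.
#'
#' An internal node with zero regulators deserves a warning flag in the mind
#' of the modeller: its signed input sum is always 0, which does not strictly
#' exceed its threshold of 0, so such a node falls to state 0 after the first
#' update and stays there. This follows from the update rule itself, not from
#' an implementation choice.
#'
#' @param nodes data.frame with columns `name` (unique non-empty strings) and
#'   `role` (`"control"` or `"internal"`), in declaration order.
#' @param edges data.frame with columns `from`, `to` (declared node names) and
#'   `sign` (`+1` or `-1`). At most one edge per ordered `(from, to)` pair;
#'   self-loops are allowed.
#' @return An object of class `boolean_network` with elements `nodes`,
#'   `edges`, `N` (node count) and `N_int` (internal node count).
#' @examples
#' net <- boolean_network(
#'   nodes = data.frame(name = c("A", "B"), role = c("control", "internal")),
#'   edges = data.frame(from = "A", to = "B", sign = 1)
#' )
#' net$N_int
#' @export
boolean_network <- function(nodes, edges = NULL) {
  stopifnot(is.data.frame(nodes), all(c("name", "role") %in% names(nodes)))
  nodes <- data.frame(name = as.character(nodes$name),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(nodes$name)))
    stop("node names must be non-empty")
  if (anyDuplicated(nodes$name))
    stop("duplicate node: ", nodes$name[duplicated(nodes$name)][1])
  bad_role <- setdiff(unique(nodes$role), c("control", "internal"))
  if (length(bad_role))
    stop("node role must be 'control' or 'internal', got: ", bad_role[1])
  if (sum(nodes$role == "internal") < 1)
    stop("network must contain at least one internal node")

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(edges), all(c("from", "to", "sign") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        sign = as.integer(edges$sign),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(unknown))
      stop("edge references unknown node: ", unknown[1])
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      d <- edges[duplicated(key), , drop = FALSE]
      stop("duplicate edge: ", d$from[1], " -> ", d$to[1])
    }
    ctrl <- nodes$name[nodes$role == "control"]
    if (any(edges$to %in% ctrl)) {
      tgt <- edges$to[edges$to %in% ctrl][1]
      stop("control node cannot be regulated: ", tgt)
    }
  }

  net <- structure(
    list(nodes = nodes, edges = edges,
         N = nrow(nodes), N_int = sum(nodes$role == "internal")),
    class = "boolean_network")
  net
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Signed-threshold Boolean network\n")
  cat("  nodes:", x$N, "(", sum(x$nodes$role == "control"), "control,",
      x$N_int, "internal )\n")
  cat("  edges:", nrow(x$edges), "(",
      sum(x$edges$sign == 1), "activatory,",
      sum(x$edges$sign == -1), "inhibitory )\n")
  invisible(x)
}

#' Node-name accessors
#'
#' @param net a `boolean_network`.
#' @return Character vector of node names in declaration order.
#' @export
node_names <- function(net) net$nodes$name

#' @rdname node_names
#' @export
control_nodes <- function(net) net$nodes$name[net$nodes$role == "control"]

#' @rdname node_names
#' @export
internal_nodes <- function(net) net$nodes$name[net$nodes$role == "internal"]

#' Summarise the regulators of an internal node
#'
#' Collects the incoming edges of `target` in declaration order and derives
#' the quantities used by the threshold update rule: the regulator count `n`,
#' the inhibitory count `m`, and the activation threshold `n/2 - m`. The
#' threshold is exact (an integer for even `n`, a half-integer for odd `n`;
#' both are represented exactly in double precision), and all state
#' comparisons elsewhere are done in integer arithmetic so no rounding can
#' ever decide a tie.
#'
#' @param net a `boolean_network`.
#' @param target name of an internal node.
#' @return An object of class `regulator_summary`: list with `target`,
#'   `regulators` (data.frame `source`, `sign`), `n`, `m`, `threshold`.
#' @examples
#' net <- parse_network(c("[nodes]", "V1 control", "V2 control", "V3 control",
#'                        "Vi internal", "[edges]",
#'                        "V1 -> Vi", "V2 -> Vi", "V3 -| Vi"))
#' regulator_summary(net, "Vi")  # n = 3, m = 1, threshold = 0.5
#' @export
regulator_summary <- function(net, target) {
  if (!target %in% node_names(net))
    stop("unknown node: ", target)
  if (target %in% control_nodes(net))
    stop("control node has no regulators: ", target)
  e <- net$edges[net$edges$to == target, , drop = FALSE]
  n <- nrow(e)
  m <- sum(e$sign == -1L)
  structure(
    list(target = target,
         regulators = data.frame(source = e$from, sign = e$sign,
                                 stringsAsFactors = FALSE),
         n = n, m = m, threshold = n / 2 - m),
    class = "regulator_summary")
}

#' @export
print.regulator_summary <- function(x, ...) {
  cat(sprintf("Regulators of %s: n = %d (m = %d inhibitory), threshold %g\n",
              x$target, x$n, x$m, x$threshold))
  if (x$n > 0)
    cat(paste0("  ", x$regulators$source,
               ifelse(x$regulators$sign == 1, " -> ", " -| "),
               x$target, collapse = "\n"), "\n")
  invisible(x)
}

# All regulator summaries, keyed by internal node name.
all_summaries <- function(net) {
  ints <- internal_nodes(net)
  out <- lapply(ints, regulator_summary, net = net)
  names(out) <- ints
  out
}

#' Parse a network-definition document
#'
#' The file format is plain UTF-8 text, line-oriented:
#' \preformatted{
#' # comment lines start with '#'; blank lines are ignored
#' [nodes]
#' CK0   control
#' CK    internal
#' [edges]
#' CK0 -> CK      # activation
#' CKX -| CK      # inhibition
#' }
#' Whitespace separates fields. Nodes are declared before edges reference
#' them; declaration order is preserved (it defines state-encoding bit
#' positions). Errors report the offending line number.
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines.
#' @return A validated [boolean_network()].
#' @seealso [read_network()], [write_network()]
#' @export
parse_network <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  section <- ""
  nodes <- list()
  edges <- list()
  for (ln in seq_along(text)) {
    line <- sub("#.*$", "", text[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (line == "[nodes]") { section <- "nodes"; next }
    if (line == "[edges]") { section <- "edges"; next }
    if (grepl("^\\[", line))
      stop("line ", ln, ": unknown section header '", line, "'")
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    if (section == "nodes") {
      if (length(fields) != 2)
        stop("line ", ln, ": expected 'NAME control|internal'")
      if (!fields[2] %in% c("control", "internal"))
        stop("line ", ln, ": role must be 'control' or 'internal'")
      nodes[[length(nodes) + 1L]] <- fields
    } else if (section == "edges") {
      if (length(fields) != 3 || !fields[2] %in% c("->", "-|"))
        stop("line ", ln, ": expected 'SOURCE -> TARGET' or 'SOURCE -| TARGET'")
      edges[[length(edges) + 1L]] <-
        list(from = fields[1], to = fields[3],
             sign = if (fields[2] == "->") 1L else -1L, ln = ln)
    } else {
      stop("line ", ln, ": content before any [nodes]/[edges] section")
    }
  }
  if (!length(nodes))
    stop("no [nodes] section found")
  nd <- data.frame(name = vapply(nodes, `[`, "", 1),
                   role = vapply(nodes, `[`, "", 2),
                   stringsAsFactors = FALSE)
  ed <- if (length(edges)) {
    data.frame(from = vapply(edges, function(e) e$from, ""),
               to = vapply(edges, function(e) e$to, ""),
               sign = vapply(edges, function(e) e$sign, 1L),
               stringsAsFactors = FALSE)
  } else NULL
  boolean_network(nd, ed)
}

#' Read a network-definition file
#'
#' @param path path to a file in the format of [parse_network()].
#' @return A validated [boolean_network()].
#' @export
read_network <- function(path) {
  parse_network(readLines(path, warn = FALSE))
}

#' Serialise a network to the network-definition format
#'
#' `parse_network(write_network(net))` reproduces `net` exactly (node and
#' edge order included).
#'
#' @param net a `boolean_network`.
#' @param path optional file path; if given, the document is also written
#'   there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_network <- function(net, path = NULL) {
  w <- max(nchar(net$nodes$name), 1L)
  lines <- c(
    "[nodes]",
    sprintf("%-*s  %s", w, net$nodes$name, net$nodes$role),
    "[edges]")
  if (nrow(net$edges) > 0)
    lines <- c(lines,
               sprintf("%-*s %s %s", w, net$edges$from,
                       ifelse(net$edges$sign == 1L, "->", "-|"),
                       net$edges$to))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export the edge list as a SIF-like three-column table
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `source`, `relation`
#'   (`"activates"`/`"inhibits"`) and `target`; lossless for the edge set.
#' @export
network_to_sif <- function(net) {
  data.frame(source = net$edges$from,
             relation = ifelse(net$edges$sign == 1L, "activates", "inhibits"),
             target = net$edges$to,
             stringsAsFactors = FALSE)
}

#' Test whether every node in `to` is reachable from some node in `from`
#'
#' Simple breadth-first reachability on the directed edge set; used e.g. to
#' confirm that reporter nodes can be influenced by at least one control
#' input.
#'
#' @param net a `boolean_network`.
#' @param from,to character vectors of node names.
#' @return Named logical vector over `to`.
#' @export
reachable_from <- function(net, from, to) {
  stopifnot(all(c(from, to) %in% node_names(net)))
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(net$edges$to[net$edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  structure(to %in% seen, names = to)
}
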