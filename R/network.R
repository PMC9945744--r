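#' Build a PPI network from an edge list
#'
#' Constructs an undirected simple graph over protein identifiers. Node
#' identifiers are opaque, case-sensitive strings. The constructor collapses
#' directional duplicates (`a b` and `b a` become one edge), removes exact
#' duplicates, and silently drops self-loops, so the resulting object always
#' satisfies the simple-graph invariants: symmetry of adjacency, no
#' self-loops, and `edge_count` equal to half the sum of neighbor-set sizes.
#' For raw dataset files with cleaning accounting, use [load_edge_list()].
#'
#' Adjacency is stored as sorted integer index vectors, one per node, giving
#' effectively constant-time membership tests via hashing (`match`). Nodes
#' are stored in lexicographic order so that all edge iteration downstream is
#' deterministic.
#'
#' @param edges A two-column `matrix` or `data.frame` of node identifiers
#'   (one interaction per row), or `NULL` for an edgeless graph.
#' @param nodes Optional character vector of node identifiers to include even
#'   when isolated (e.g. proteins with no retained interaction).
#' @return An object of class `ppi_network` with elements `nodes` (character
#'   vector), `adj` (list of sorted integer neighbor indices) and `m` (edge
#'   count).
#' @examples
#' net <- ppi_network(rbind(c("a", "b"), c("b", "c")))
#' ppi_neighbors(net, "b")
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    ea <- eb <- character(0)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("`edges` must have at least two columns")
    ea <- as.character(edges[, 1])
    eb <- as.character(edges[, 2])
  }
  ok <- !is.na(ea) & !is.na(eb) & nzchar(ea) & nzchar(eb)
  ea <- ea[ok]; eb <- eb[ok]
  loop <- ea == eb
  ea <- ea[!loop]; eb <- eb[!loop]
  a <- pmin(ea, eb); b <- pmax(ea, eb)
  keep <- !duplicated(paste(a, b, sep = "\x1f"))
  a <- a[keep]; b <- b[keep]

  all_nodes <- sort(unique(c(a, b, as.character(nodes))))
  n <- length(all_nodes)
  adj <- rep(list(integer(0)), n)
  if (length(a)) {
    ia <- match(a, all_nodes)
    ib <- match(b, all_nodes)
    sp <- split(c(ib, ia), c(ia, ib))
    idx <- as.integer(names(sp))
    adj[idx] <- lapply(sp, function(v) sort.int(v))
  }
  structure(
    list(nodes = all_nodes, adj = adj, m = length(a)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network: %d nodes, %d edges>\n", length(x$nodes), x$m))
  invisible(x)
}

node_idx <- function(net, a) {
  i <- match(as.character(a), net$nodes)
  if (anyNA(i)) {
    stop(sprintf("unknown node identifier(s): %s",
                 paste(sQuote(a[is.na(i)]), collapse = ", ")))
  }
  i
}

has_edge_idx <- function(net, i, j) {
  match(j, net$adj[[i]], nomatch = 0L) > 0L
}

# Assumes the edge is absent / present; callers maintain that.
net_add_edge <- function(net, i, j) {
  net$adj[[i]] <- sort.int(c(net$adj[[i]], j))
  net$adj[[j]] <- sort.int(c(net$adj[[j]], i))
  net$m <- net$m + 1L
  net
}

net_drop_edge <- function(net, i, j) {
  net$adj[[i]] <- net$adj[[i]][net$adj[[i]] != j]
  net$adj[[j]] <- net$adj[[j]][net$adj[[j]] != i]
  net$m <- net$m - 1L
  net
}

#' Network accessors
#'
#' `ppi_nodes()` returns the node identifiers, `ppi_edge_count()` the number
#' of (undirected, deduplicated) edges, `ppi_edges()` the canonical edge
#' table (lexicographic within each row, rows sorted), `ppi_degree()` node
#' degrees, and `has_edge()` tests adjacency of a node pair.
#'
#' @param net A [ppi_network].
#' @param a,b Node identifiers.
#' @return See individual descriptions.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
ppi_nodes <- function(net) net$nodes

#' @rdname network-accessors
#' @export
ppi_edge_count <- function(net) net$m

#' @rdname network-accessors
#' @export
ppi_edges <- function(net) {
  from <- rep.int(seq_along(net$adj), lengths(net$adj))
  to <- unlist(net$adj, use.names = FALSE)
  keep <- from < to
  df <- data.frame(
    node_a = net$nodes[from[keep]],
    node_b = net$nodes[to[keep]],
    stringsAsFactors = FALSE
  )
  df[order(df$node_a, df$node_b), , drop = FALSE]
}

#' @rdname network-accessors
#' @export
ppi_degree <- function(net, a = NULL) {
  if (is.null(a)) {
    stats::setNames(lengths(net$adj), net$nodes)
  } else {
    lengths(net$adj[node_idx(net, a)])
  }
}

#' @rdname network-accessors
#' @export
has_edge <- function(net, a, b) {
  has_edge_idx(net, node_idx(net, a), node_idx(net, b))
}

#' Neighbor set of a node
#'
#' Returns `N(a)`, the set of nodes adjacent to `a`, as a sorted character
#' vector. Asking for an unknown node is an error naming the identifier.
#'
#' @param net A [ppi_network].
#' @param a A node identifier present in `net`.
#' @return Character vector of neighbor identifiers (possibly empty).
#' @export
ppi_neighbors <- function(net, a) {
  net$nodes[net$adj[[node_idx(net, a)]]]
}

#' Validate the structural invariants of a PPI network
#'
#' Checks adjacency symmetry, absence of self-loops, sortedness of the
#' internal adjacency vectors, and consistency of the stored edge count.
#' Intended for defensive use in tests and simulations.
#'
#' @param net A [ppi_network].
#' @return `net`, invisibly; errors if an invariant is violated.
#' @export
validate_ppi_network <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  if (length(net$adj) != n) stop("adjacency/node length mismatch")
  for (i in seq_len(n)) {
    nb <- net$adj[[i]]
    if (is.unsorted(nb, strictly = TRUE) && length(nb) > 1) {
      stop("adjacency vector not strictly sorted")
    }
    if (any(nb == i)) stop("self-loop found at node ", net$nodes[i])
    for (j in nb) {
      if (!has_edge_idx(net, j, i)) {
        stop(sprintf("asymmetric adjacency: %s -> %s",
                     net$nodes[i], net$nodes[j]))
      }
    }
  }
  if (sum(lengths(net$adj)) != 2L * net$m) {
    stop("edge count disagrees with adjacency lists")
  }
  invisible(net)
}
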