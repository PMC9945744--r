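# L3-elements (x, y, U, V) and P4 counting for candidate pairs.

# Index-level workhorse. U and V are found with the hash-table construction:
# scan a in N(x), b in N(y) and test the edge {a, b}, so the cost is
# O(|N(x)| * |N(y)|) per pair.
l3_uv <- function(net, xi, yi) {
  Nx <- net$adj[[xi]]
  Ny <- net$adj[[yi]]
  if (!length(Nx) || !length(Ny)) {
    return(list(U = integer(0), V = integer(0)))
  }
  adj <- net$adj
  in_u <- vapply(Nx, function(a) any_common(adj[[a]], Ny), logical(1))
  in_v <- vapply(Ny, function(b) any_common(adj[[b]], Nx), logical(1))
  list(U = Nx[in_u], V = Ny[in_v])
}

check_candidate <- function(net, x, y) {
  xi <- node_idx(net, x)
  yi <- node_idx(net, y)
  if (xi == yi) stop("candidate pair must be two distinct nodes")
  if (has_edge_idx(net, xi, yi)) {
    stop(sprintf("nodes %s and %s are adjacent; scores are defined for non-adjacent pairs only",
                 sQuote(x), sQuote(y)))
  }
  c(xi, yi)
}

#' L3-elements of a candidate pair
#'
#' For a non-adjacent pair `{x, y}`, computes the L3-elements: the set
#' `U = N(x) ∩ N(N(y))` of neighbors of `x` at distance 2 from `y`, and
#' symmetrically `V = N(y) ∩ N(N(x))`. Every path of length three between
#' `x` and `y` has the form `x–u–v–y` with `u ∈ U`, `v ∈ V`. A node may
#' belong to both `U` and `V` and can then play either role.
#'
#' @param net A [ppi_network].
#' @param x,y A non-adjacent node pair (adjacent pairs are an error; filter
#'   candidates first).
#' @return An object of class `l3_neighborhood`: a list with elements `x`,
#'   `y`, `U` and `V` (sorted character vectors).
#' @export
l3_elements <- function(net, x, y) {
  idx <- check_candidate(net, x, y)
  uv <- l3_uv(net, idx[1], idx[2])
  structure(
    list(x = as.character(x), y = as.character(y),
         U = net$nodes[uv$U], V = net$nodes[uv$V]),
    class = "l3_neighborhood"
  )
}

#' @export
print.l3_neighborhood <- function(x, ...) {
  cat(sprintf("<l3_neighborhood: pair (%s, %s), |U| = %d, |V| = %d>\n",
              x$x, x$y, length(x$U), length(x$V)))
  invisible(x)
}

count_p4_idx <- function(net, xi, yi, uv = NULL) {
  if (is.null(uv)) uv <- l3_uv(net, xi, yi)
  if (!length(uv$U) || !length(uv$V)) return(0L)
  adj <- net$adj
  sum(vapply(uv$U, function(u) n_common(adj[[u]], uv$V), 0L))
}

#' Count paths of length three between a candidate pair
#'
#' Counts the simple paths `x–u–v–y` (P4 subgraphs) between a non-adjacent
#' pair, i.e. the number of ordered role assignments `(u, v)` with `u ∈ U`,
#' `v ∈ V` and `{u, v}` an edge. Because the graph is simple and the pair is
#' non-adjacent, `u ≠ v`, `u ≠ y` and `v ≠ x` hold automatically, so every
#' counted tuple is a simple path.
#'
#' @inheritParams l3_elements
#' @return A non-negative integer.
#' @export
count_p4 <- function(net, x, y) {
  idx <- check_candidate(net, x, y)
  count_p4_idx(net, idx[1], idx[2])
}
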