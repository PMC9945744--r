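# Ideal L3 graphs and the compatible / incompatible edge inventory.

#' Build an ideal L3 graph
#'
#' Constructs the maximal-evidence configuration for a candidate edge
#' `{x, y}`: a complete bipartite graph between parts `U` (size `n_u`) and
#' `V` (size `n_v`), with a node `x` attached to all of `U` and a node `y`
#' attached to all of `V`. The result has `n_u + n_v + 2` nodes and
#' `n_u * n_v + n_u + n_v` edges, and `x`, `y` are non-adjacent.
#'
#' The matching pairs `u_i` with `v_i` under the index pairing for
#' `i = 1..min(n_u, n_v)`; these protected edges are never removed by
#' [run_removal_sim()], which keeps the L3-elements intact along the whole
#' removal trajectory. Rectangular graphs (`n_u != n_v`) are supported; the
#' canonical configuration in the perturbation studies is the square one.
#'
#' @param n_u,n_v Positive part sizes.
#' @return An object of class `ideal_l3_graph`: a list with elements `net`
#'   (a [ppi_network]), `x`, `y`, `U`, `V` and `matching` (a two-column
#'   character matrix of protected edges).
#' @examples
#' g <- build_ideal_l3(50, 50)
#' ppi_edge_count(g$net)  # 2600
#' @export
build_ideal_l3 <- function(n_u, n_v) {
  if (!is_count(n_u) || !is_count(n_v)) {
    stop("`n_u` and `n_v` must be positive integers")
  }
  n_u <- as.integer(n_u); n_v <- as.integer(n_v)
  U <- sprintf("u%04d", seq_len(n_u))
  V <- sprintf("v%04d", seq_len(n_v))
  edges <- rbind(
    cbind("x", U),
    cbind("y", V),
    cbind(rep(U, each = n_v), rep(V, times = n_u))
  )
  k <- min(n_u, n_v)
  structure(
    list(net = ppi_network(edges),
         x = "x", y = "y", U = U, V = V,
         matching = cbind(U[seq_len(k)], V[seq_len(k)])),
    class = "ideal_l3_graph"
  )
}

#' @export
print.ideal_l3_graph <- function(x, ...) {
  cat(sprintf("<ideal_l3_graph: |U| = %d, |V| = %d, %d nodes, %d edges>\n",
              length(x$U), length(x$V), length(x$net$nodes), x$net$m))
  invisible(x)
}

#' Classify perturbation edges of an ideal L3 graph
#'
#' Partitions the perturbation universe of an ideal L3 graph into
#' *compatible* edges — present edges `{u_i, v_j}` with `i != j` (the
#' index-matched edges are protected and excluded) whose removal degrades
#' the graph while preserving the L3-elements — and *incompatible* edges —
#' absent edges `{u_i, u_j}`, `{v_i, v_j}`, `{x, v_i}` or `{y, u_i}` whose
#' insertion corrupts the ideal structure. The candidate edge `{x, y}`
#' itself belongs to neither set. For part sizes `nU`, `nV` the counts are
#' `nU*nV - min(nU, nV)` compatible and
#' `choose(nU, 2) + choose(nV, 2) + nU + nV` incompatible edges.
#'
#' @param g An `ideal_l3_graph` from [build_ideal_l3()].
#' @return A list with two-column character matrices `compatible` and
#'   `incompatible`, in deterministic (sorted) order.
#' @examples
#' cls <- classify_edges(build_ideal_l3(50, 50))
#' nrow(cls$compatible)    # 2450
#' nrow(cls$incompatible)  # 2550
#' @export
classify_edges <- function(g) {
  stopifnot(inherits(g, "ideal_l3_graph"))
  U <- g$U; V <- g$V
  nu <- length(U); nv <- length(V)
  all_uv <- cbind(rep(U, each = nv), rep(V, times = nu))
  mk <- paste(g$matching[, 1], g$matching[, 2], sep = "\x1f")
  compat <- all_uv[!(paste(all_uv[, 1], all_uv[, 2], sep = "\x1f") %in% mk), ,
                   drop = FALSE]

  pairs_within <- function(S) {
    if (length(S) < 2) return(matrix(character(0), ncol = 2))
    idx <- utils::combn(length(S), 2)
    cbind(S[idx[1, ]], S[idx[2, ]])
  }
  incompat <- rbind(
    pairs_within(U),
    pairs_within(V),
    cbind(g$x, V),
    cbind(g$y, U)
  )
  ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  list(compatible = ord(compat), incompatible = ord(incompat))
}
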