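# Small graphs used across tests, built in code.

# Six-node toy: x-u1, x-u2, u1-v1, u2-v1, u2-v2, v1-y, v2-y.
toy_t1 <- function() {
  ppi_network(rbind(
    c("x", "u1"), c("x", "u2"), c("u1", "v1"), c("u2", "v1"),
    c("u2", "v2"), c("v1", "y"), c("v2", "y")
  ))
}

# 4-cycle x-a-y-b-x; optionally with the chord a-b added.
four_cycle <- function(chord = FALSE) {
  e <- rbind(c("x", "a"), c("a", "y"), c("y", "b"), c("b", "x"))
  if (chord) e <- rbind(e, c("a", "b"))
  ppi_network(e)
}

# Two stars centered on x and y sharing nothing.
disjoint_stars <- function(k = 3) {
  ppi_network(rbind(
    cbind("x", paste0("s", seq_len(k))),
    cbind("y", paste0("t", seq_len(k)))
  ))
}

# Erdos-Renyi G(n, p) over nodes n01..; returns a ppi_network.
er_graph <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  withr::with_seed(seed, {
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < p
    ppi_network(cbind(nodes[idx[1, keep]], nodes[idx[2, keep]]),
                nodes = nodes)
  })
}

# A network made of several ideal L3 gadgets WITH their x-y edges present,
# plus a sparse random background. Returns the network and the list of x-y
# edges (the recoverable "missing" interactions when hidden).
gadget_network <- function(n_gadgets = 6, n_u = 5, n_v = 5, p_bg = 0.004,
                           seed = 1) {
  edges <- NULL
  truth <- NULL
  for (k in seq_len(n_gadgets)) {
    pre <- sprintf("g%d_", k)
    U <- paste0(pre, "u", seq_len(n_u))
    V <- paste0(pre, "v", seq_len(n_v))
    x <- paste0(pre, "x"); y <- paste0(pre, "y")
    edges <- rbind(edges,
                   cbind(x, U), cbind(y, V),
                   cbind(rep(U, each = n_v), rep(V, times = n_u)),
                   cbind(x, y))
    truth <- rbind(truth, cbind(x, y))
  }
  nodes <- sort(unique(as.vector(edges)))
  bg <- withr::with_seed(seed, {
    idx <- utils::combn(length(nodes), 2)
    keep <- stats::runif(ncol(idx)) < p_bg
    cbind(nodes[idx[1, keep]], nodes[idx[2, keep]])
  })
  list(net = ppi_network(rbind(edges, bg)),
       truth = data.frame(node_a = pmin(truth[, 1], truth[, 2]),
                          node_b = pmax(truth[, 1], truth[, 2]),
                          stringsAsFactors = FALSE))
}
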