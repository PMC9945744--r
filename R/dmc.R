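#' Generate a duplication-mutation synthetic interactome
#'
#' Grows a synthetic PPI network by the duplication-mutation-with-
#' complementarity scheme that underlies gene-duplication models of
#' interactome evolution: starting from a single interacting pair, each step
#' duplicates a uniformly chosen existing protein, the duplicate inherits
#' each of its parent's interactions independently with probability
#' `p_keep`, and an anchor interaction between duplicate and parent is added
#' with probability `p_anchor`. The result reproduces the heavy-tailed
#' degree distributions of real interactomes, unlike an Erdős–Rényi graph
#' of equal density.
#'
#' @param n_final Final number of proteins (at least 3).
#' @param p_keep Probability that the duplicate retains each inherited
#'   interaction (default 0.7).
#' @param p_anchor Probability of the duplicate-parent anchor interaction
#'   (default 0.1).
#' @param seed Seed; a fixed seed reproduces the identical edge list.
#' @return A [ppi_network] with nodes `p1 ... p<n_final>` (duplicates that
#'   retain no interaction remain as isolated nodes).
#' @examples
#' net <- generate_dmc_network(100, seed = 7)
#' @export
generate_dmc_network <- function(n_final, p_keep = 0.7, p_anchor = 0.1,
                                 seed = 1L) {
  if (!is_count(n_final, min = 3)) stop("`n_final` must be an integer >= 3")
  if (!is_prob(p_keep)) stop("`p_keep` must lie in [0, 1]")
  if (!is_prob(p_anchor)) stop("`p_anchor` must lie in [0, 1]")
  n_final <- as.integer(n_final)

  adj <- withr::with_seed(seed, {
    adj <- rep(list(integer(0)), n_final)
    adj[[1]] <- 2L
    adj[[2]] <- 1L
    for (id in 3:n_final) {
      parent <- sample.int(id - 1L, 1L)
      nb <- adj[[parent]]
      kept <- nb[stats::runif(length(nb)) < p_keep]
      if (stats::runif(1) < p_anchor) kept <- c(kept, parent)
      adj[[id]] <- kept
      for (k in kept) adj[[k]] <- c(adj[[k]], id)
    }
    adj
  })

  from <- rep.int(seq_along(adj), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  nodes <- paste0("p", seq_len(n_final))
  ppi_network(cbind(nodes[from[keep]], nodes[to[keep]]), nodes = nodes)
}
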