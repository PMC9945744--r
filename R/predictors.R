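# Candidate-pair score functions: CN-based baselines (CN, RA, AA, CRA),
# L3-based predictors (L3, CH2_L3, Sim), the normalized L3 family (L3N and
# L3N' under the f1 / f2 similarity metrics), and the two controls (uniform
# random, raw P4 count).

#' Registered predictor names
#'
#' The predictor identifiers accepted by [score_pair()],
#' [score_all_candidates()] and the simulation/evaluation harnesses:
#' `"cn"`, `"ra"`, `"aa"`, `"cra"` (CN-based), `"l3"`, `"ch2"`, `"sim"`,
#' `"l3n_f1"`, `"l3n_f2"`, `"l3n_prime_f1"`, `"l3n_prime_f2"` (L3-based),
#' and the controls `"p4"` (raw path count) and `"rand"`.
#'
#' @return Character vector of predictor names.
#' @export
predictor_names <- function() {
  c("cn", "ra", "aa", "cra",
    "l3", "ch2", "sim",
    "l3n_f1", "l3n_f2", "l3n_prime_f1", "l3n_prime_f2",
    "p4", "rand")
}

L3_FAMILY <- c("l3", "ch2", "sim",
               "l3n_f1", "l3n_f2", "l3n_prime_f1", "l3n_prime_f2")

# ---- CN-based scores -------------------------------------------------------

cn_family_idx <- function(net, xi, yi, kind) {
  adj <- net$adj
  A <- intersect(adj[[xi]], adj[[yi]])
  if (!length(A)) return(0)
  switch(kind,
    cn = length(A),
    ra = sum(1 / lengths(adj[A])),
    aa = {
      d <- lengths(adj[A])
      d <- d[d > 1L]  # degree-1 terms would divide by log(1) = 0; skipped
      if (!length(d)) 0 else sum(1 / log(d))
    },
    cra = sum(vapply(A, function(a) {
      n_common(adj[[a]], A) / length(adj[[a]])
    }, 0))
  )
}

# ---- L3-based scores -------------------------------------------------------

# All L3-family scores factorize as outer * sum over U-V edges of a(u)*b(v),
# with a() depending only on u and b() only on v (Sim drops the edge sum and
# adds per-node terms directly). This keeps a single pass per node instead of
# per path.
l3_family_idx <- function(net, xi, yi, kind, uv = NULL) {
  adj <- net$adj
  if (is.null(uv)) uv <- l3_uv(net, xi, yi)
  U <- uv$U; V <- uv$V
  if (!length(U) || !length(V)) return(0)
  Nx <- adj[[xi]]; Ny <- adj[[yi]]

  if (kind == "sim") {
    sv <- vapply(V, function(v) f2_idx(adj[[v]], Nx), 0)
    su <- vapply(U, function(u) f2_idx(adj[[u]], Ny), 0)
    return(sum(sv) + sum(su))
  }

  outer_f <- 1
  if (kind == "p4") {
    a <- rep.int(1, length(U))
    b <- rep.int(1, length(V))
  } else if (kind == "l3") {
    a <- 1 / sqrt(lengths(adj[U]))
    b <- 1 / sqrt(lengths(adj[V]))
  } else if (kind == "ch2") {
    cset <- union(U, V)
    ch2_fac <- function(w) {
      inn <- n_common(adj[[w]], cset)
      out <- length(setdiff(setdiff(adj[[w]], cset), c(xi, yi)))
      sqrt(1 + inn) / sqrt(1 + out)
    }
    a <- vapply(U, ch2_fac, 0)
    b <- vapply(V, ch2_fac, 0)
  } else if (kind %in% c("l3n_f1", "l3n_f2", "l3n_prime_f1", "l3n_prime_f2")) {
    f <- metric_fun(if (endsWith(kind, "f1")) "f1" else "f2")
    prime <- startsWith(kind, "l3n_prime")
    outer_f <- f(Nx, U) * f(Ny, V)
    if (outer_f == 0) return(0)
    a <- vapply(U, function(u) {
      Nu <- if (prime) adj[[u]] else adj[[u]][adj[[u]] != xi]
      f(Nu, V) * f(Ny, Nu)
    }, 0)
    b <- vapply(V, function(v) {
      Nv <- if (prime) adj[[v]] else adj[[v]][adj[[v]] != yi]
      f(Nv, U) * f(Nx, Nv)
    }, 0)
  } else {
    stop(sprintf("unknown predictor %s", sQuote(kind)))
  }

  s <- 0
  for (k in seq_along(U)) {
    hits <- match(adj[[U[k]]], V, nomatch = 0L)
    hits <- hits[hits > 0L]
    if (length(hits)) s <- s + a[k] * sum(b[hits])
  }
  outer_f * s
}

# Deterministic per-pair uniform draw: the random control predictor. The draw
# depends only on the root seed and the unordered pair, so a fixed seed gives
# an identical ranking regardless of enumeration order.
pair_unif <- function(a, b, seed) {
  key <- paste(min(a, b), max(a, b), sep = "\x1f")
  cp <- utf8ToInt(key)
  h <- sum(cp * (seq_along(cp) %% 97 + 1)) %% 1000003
  withr::with_seed(derive_seed(seed, h), stats::runif(1))
}

pair_score_idx <- function(net, xi, yi, predictor, seed = 1L, uv = NULL) {
  if (predictor %in% c("cn", "ra", "aa", "cra")) {
    cn_family_idx(net, xi, yi, predictor)
  } else if (predictor == "rand") {
    pair_unif(net$nodes[xi], net$nodes[yi], seed)
  } else {
    l3_family_idx(net, xi, yi, predictor, uv = uv)
  }
}

#' Score one candidate pair with a named predictor
#'
#' Dispatches to any registered predictor (see [predictor_names()]). All
#' predictors require the pair to be non-adjacent; scoring an adjacent pair
#' is an error.
#'
#' @param net A [ppi_network].
#' @param x,y A non-adjacent node pair.
#' @param predictor A predictor name from [predictor_names()].
#' @param seed Root seed; only consulted by the `"rand"` control.
#' @return A non-negative numeric score.
#' @export
score_pair <- function(net, x, y, predictor, seed = 1L) {
  predictor <- match.arg(predictor, predictor_names())
  idx <- check_candidate(net, x, y)
  pair_score_idx(net, idx[1], idx[2], predictor, seed = seed)
}

#' Individual link-predictor score functions
#'
#' Per-pair scores for a non-adjacent candidate pair `{x, y}`. Writing
#' `N(a)` for the neighbor set of `a`, `A = N(x) ∩ N(y)` for the common
#' neighbors, and `U`, `V` for the L3-elements (see [l3_elements()]):
#'
#' * `score_cn()`: `|A|` (Common Neighbors).
#' * `score_ra()`: `Σ_{z∈A} 1/|N(z)|` (Resource Allocation).
#' * `score_aa()`: `Σ_{z∈A} 1/log|N(z)|` (Adamic-Adar, natural log; common
#'   neighbors of degree ≤ 1 contribute 0).
#' * `score_cra()`: `Σ_{a∈A} |N(a) ∩ A| / |N(a)|`.
#' * `score_l3()`: `Σ 1/sqrt(|N(u)|·|N(v)|)` over U–V edges `(u, v)`; the
#'   square-root degree modifier of the original L3 predictor.
#' * `score_ch2()`: the CH2_L3 score, rewarding `u`, `v` connected to many
#'   nodes inside `c = U ∪ V` and few outside it (excluding `x`, `y`).
#' * `score_sim()`: `Σ_{v∈V} f2(N(v), N(x)) + Σ_{u∈U} f2(N(u), N(y))`,
#'   Jaccard similarity of interface neighborhoods summed per node.
#' * `score_l3n()`: the NormalizedL3 score
#'   `f(N(x),U)·f(N(y),V) · Σ f(N¬x(u),V)·f(N¬y(v),U)·f(N(x),N¬y(v))·f(N(y),N¬x(u))`
#'   over U–V edges, where `N¬b(a) = N(a) \\ {b}` and `f` is [metric_f1()]
#'   or [metric_f2()]. Each factor measures one condition under which the
#'   pair's neighborhood matches an ideal L3 graph.
#' * `score_l3n_prime()`: the L3N' variant using un-deleted neighborhoods
#'   `N(u)`, `N(v)` throughout the sum, which offsets each comparison by the
#'   anchoring membership of `x` (resp. `y`) in `N(u)` (resp. `N(v)`).
#' * `score_p4_control()`: the raw P4 count, equal to [count_p4()] (the
#'   control used in the perturbation simulations).
#' * `score_rand()`: a deterministic per-pair uniform(0, 1) draw from the
#'   given seed (the negative control).
#'
#' @inheritParams score_pair
#' @param metric `"f1"` (simple ratio) or `"f2"` (Jaccard).
#' @return A non-negative numeric score.
#' @examples
#' t1 <- ppi_network(rbind(
#'   c("x", "u1"), c("x", "u2"), c("u1", "v1"), c("u2", "v1"),
#'   c("u2", "v2"), c("v1", "y"), c("v2", "y")))
#' score_l3(t1, "x", "y")        # 2/sqrt(6) + 1/3
#' score_l3n(t1, "x", "y", "f1") # 2
#' @name score-functions
NULL

#' @rdname score-functions
#' @export
score_cn <- function(net, x, y) score_pair(net, x, y, "cn")

#' @rdname score-functions
#' @export
score_ra <- function(net, x, y) score_pair(net, x, y, "ra")

#' @rdname score-functions
#' @export
score_aa <- function(net, x, y) score_pair(net, x, y, "aa")

#' @rdname score-functions
#' @export
score_cra <- function(net, x, y) score_pair(net, x, y, "cra")

#' @rdname score-functions
#' @export
score_l3 <- function(net, x, y) score_pair(net, x, y, "l3")

#' @rdname score-functions
#' @export
score_ch2 <- function(net, x, y) score_pair(net, x, y, "ch2")

#' @rdname score-functions
#' @export
score_sim <- function(net, x, y) score_pair(net, x, y, "sim")

#' @rdname score-functions
#' @export
score_l3n <- function(net, x, y, metric = c("f1", "f2")) {
  metric <- match.arg(metric)
  score_pair(net, x, y, paste0("l3n_", metric))
}

#' @rdname score-functions
#' @export
score_l3n_prime <- function(net, x, y, metric = c("f1", "f2")) {
  metric <- match.arg(metric)
  score_pair(net, x, y, paste0("l3n_prime_", metric))
}

#' @rdname score-functions
#' @export
score_p4_control <- function(net, x, y) score_pair(net, x, y, "p4")

#' @rdname score-functions
#' @export
score_rand <- function(net, x, y, seed = 1L) {
  score_pair(net, x, y, "rand", seed = seed)
}

# ---- Ranking all candidates ------------------------------------------------

enumerate_candidates <- function(net) {
  n <- length(net$nodes)
  adj <- net$adj
  out_i <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- seq.int(i + 1L, n)
    nb <- adj[[i]]
    if (length(nb)) js <- js[match(js, nb, nomatch = 0L) == 0L]
    out_i[[i]] <- js
  }
  list(i = rep.int(seq_len(n - 1L), lengths(out_i)),
       j = unlist(out_i, use.names = FALSE))
}

# Nodes within distance 2 or 3 of i (excluding i and its direct neighbors):
# the only pairs an L3-family predictor can score above zero.
l3_reachable <- function(net, i) {
  adj <- net$adj
  n1 <- adj[[i]]
  n2 <- unique(unlist(adj[n1], use.names = FALSE))
  n3 <- unique(unlist(adj[n2], use.names = FALSE))
  setdiff(unique(c(n2, n3)), c(i, n1))
}

#' Score and rank every candidate edge
#'
#' Scores all unordered non-adjacent node pairs (the candidate edges) with
#' the named predictor and returns them in non-increasing score order. Ties
#' are broken by a seeded random shuffle, so identical inputs and seed give
#' an identical ordering while avoiding order-of-insertion artifacts in
#' downstream precision-recall curves.
#'
#' For L3-family predictors, `restrict = "l3"` only evaluates pairs joined
#' by at least one path of length 2 or 3 (all other candidates provably
#' score 0); the excluded pairs are kept in the table with score 0 and rank
#' after every positive-score pair.
#'
#' @inheritParams score_pair
#' @param restrict `"all"` (default) or `"l3"` (fast path, L3-family only).
#' @return A `data.frame` of class `ranked_predictions` with columns
#'   `node_a`, `node_b` (lexicographic within a row) and `score`, ordered by
#'   decreasing score; attributes `predictor` and `seed` record provenance.
#' @export
score_all_candidates <- function(net, predictor, seed = 1L,
                                 restrict = c("all", "l3")) {
  predictor <- match.arg(predictor, predictor_names())
  restrict <- match.arg(restrict)
  if (length(net$nodes) < 2) {
    stop("need at least two nodes to enumerate candidate pairs")
  }
  cand <- enumerate_candidates(net)
  np <- length(cand$i)
  score <- numeric(np)
  if (np) {
    if (restrict == "l3" && predictor %in% c(L3_FAMILY, "p4")) {
      reach <- lapply(seq_along(net$nodes), function(i) l3_reachable(net, i))
      do_score <- vapply(seq_len(np), function(k) {
        match(cand$j[k], reach[[cand$i[k]]], nomatch = 0L) > 0L
      }, logical(1))
    } else {
      do_score <- rep.int(TRUE, np)
    }
    for (k in which(do_score)) {
      score[k] <- pair_score_idx(net, cand$i[k], cand$j[k], predictor,
                                 seed = seed)
    }
  }
  # Node names are stored sorted, so index order is lexicographic order.
  tie <- withr::with_seed(derive_seed(seed, 999983L), stats::runif(np))
  o <- order(-score, tie)
  structure(
    data.frame(node_a = net$nodes[cand$i][o],
               node_b = net$nodes[cand$j][o],
               score = score[o],
               stringsAsFactors = FALSE,
               row.names = NULL),
    class = c("ranked_predictions", "data.frame"),
    predictor = predictor,
    seed = seed
  )
}

#' Export a ranked score table as TSV
#'
#' Writes a three-column tab-separated table (`node_a`, `node_b`, `score`)
#' with node identifiers in lexicographic order within each row, preserving
#' the ranking order. Output is byte-stable for identical inputs.
#'
#' @param ranking A `ranked_predictions` table from [score_all_candidates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(ranking, path) {
  stopifnot(is.data.frame(ranking))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tscore", con)
  if (nrow(ranking)) {
    writeLines(paste(ranking$node_a, ranking$node_b,
                     format(ranking$score, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}
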