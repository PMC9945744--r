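test_that("ideal L3 graphs have the expected size and structure", {
  g <- build_ideal_l3(50, 50)
  expect_length(ppi_nodes(g$net), 102)
  expect_equal(ppi_edge_count(g$net), 2600)
  expect_false(has_edge(g$net, "x", "y"))
  expect_setequal(ppi_neighbors(g$net, "x"), g$U)
  expect_setequal(ppi_neighbors(g$net, "y"), g$V)

  tiny <- build_ideal_l3(1, 1)
  expect_equal(ppi_edge_count(tiny$net), 3)  # the path x-u-v-y
  expect_identical(count_p4(tiny$net, "x", "y"), 1L)

  rect <- build_ideal_l3(2, 3)
  expect_identical(count_p4(rect$net, "x", "y"), 6L)

  expect_error(build_ideal_l3(0, 3), "positive")
  expect_error(build_ideal_l3(2, -1), "positive")
})

test_that("edge classification matches the combinatorial inventory", {
  cls50 <- classify_edges(build_ideal_l3(50, 50))
  expect_identical(nrow(cls50$compatible), 2450L)
  expect_identical(nrow(cls50$incompatible), 2550L)

  cls1 <- classify_edges(build_ideal_l3(1, 1))
  expect_identical(nrow(cls1$compatible), 0L)
  expect_identical(nrow(cls1$incompatible), 2L)

  # brute-force cross-check at nU = nV = 2: compatible edges are present
  # U-V edges off the matching; incompatible edges are absent edges within
  # parts or from x to V / y to U; the sets are disjoint and exclude {x,y}.
  g2 <- build_ideal_l3(2, 2)
  cls2 <- classify_edges(g2)
  expect_identical(nrow(cls2$compatible), 2L)
  expect_identical(nrow(cls2$incompatible), 6L)
  ck <- pair_key(cls2$compatible[, 1], cls2$compatible[, 2])
  ik <- pair_key(cls2$incompatible[, 1], cls2$incompatible[, 2])
  expect_length(intersect(ck, ik), 0)
  expect_false(pair_key("x", "y") %in% c(ck, ik))
  for (k in seq_len(nrow(cls2$compatible))) {
    expect_true(has_edge(g2$net, cls2$compatible[k, 1], cls2$compatible[k, 2]))
  }
  for (k in seq_len(nrow(cls2$incompatible))) {
    expect_false(has_edge(g2$net, cls2$incompatible[k, 1],
                          cls2$incompatible[k, 2]))
  }
})

test_that("removal simulation starts at the ideal closed forms and ends on the matching", {
  n <- 6
  g <- build_ideal_l3(n, n)
  preds <- c("p4", "l3", "l3n_f1", "l3n_prime_f1", "sim")
  tr <- run_removal_sim(g, preds, repeats = 2, seed = 31)
  expect_equal(attr(tr, "n_iter"), n * n - n)
  at <- function(p, it, r) tr$raw[tr$predictor == p & tr$iteration == it & tr$rep == r]
  for (r in 1:2) {
    expect_equal(at("p4", 0, r), n^2)
    expect_equal(at("l3", 0, r), n^2 / (n + 1))
    expect_equal(at("l3n_f1", 0, r), n^2)
    expect_equal(at("l3n_prime_f1", 0, r), n^2 * (n / (n + 1))^2)
    expect_equal(at("sim", 0, r), 2 * n^2 / (n + 1))
    # only the protected matching paths remain at the end
    expect_equal(at("p4", n * n - n, r), n)
  }
  expect_error(run_removal_sim(g, character(0)), "at least one predictor")
})

test_that("removal trace replays exactly from the logged edit order", {
  g <- build_ideal_l3(2, 2)
  tr <- run_removal_sim(g, c("p4", "l3", "l3n_f1"), repeats = 1, seed = 77)
  log1 <- attr(tr, "edge_log")[[1]]
  edges <- as.matrix(ppi_edges(g$net))
  for (it in 0:attr(tr, "n_iter")) {
    cur <- edges
    if (it > 0) {
      gone <- pair_key(log1[seq_len(it), 1], log1[seq_len(it), 2])
      cur <- cur[!(pair_key(cur[, 1], cur[, 2]) %in% gone), , drop = FALSE]
    }
    net <- ppi_network(cur, nodes = ppi_nodes(g$net))
    for (p in c("p4", "l3", "l3n_f1")) {
      expect_equal(tr$raw[tr$predictor == p & tr$iteration == it],
                   bf_score(net, "x", "y", p))
    }
  }
})

test_that("insertion trace replays exactly and the control trend is non-decreasing", {
  g <- build_ideal_l3(2, 2)
  tr <- run_insertion_sim(g, c("p4", "l3n_prime_f2"), repeats = 1, seed = 5)
  expect_identical(attr(tr, "n_iter"), 6L)
  log1 <- attr(tr, "edge_log")[[1]]
  edges <- as.matrix(ppi_edges(g$net))
  for (it in 0:6) {
    cur <- rbind(edges, log1[seq_len(it), , drop = FALSE])
    net <- ppi_network(cur, nodes = ppi_nodes(g$net))
    for (p in c("p4", "l3n_prime_f2")) {
      expect_equal(tr$raw[tr$predictor == p & tr$iteration == it],
                   bf_score(net, "x", "y", p))
    }
  }

  g20 <- build_ideal_l3(10, 10)
  t20 <- run_insertion_sim(g20, "p4", repeats = 3, seed = 2)
  expect_equal(attr(t20, "n_iter"), 2 * choose(10, 2) + 20)
  mean_by_iter <- tapply(t20$raw, t20$iteration, mean)
  expect_true(all(diff(mean_by_iter) >= 0))
})

test_that("frozen L3-elements keep U and V at their ideal values during insertion", {
  g <- build_ideal_l3(3, 3)
  tf <- run_insertion_sim(g, "p4", repeats = 1, seed = 9,
                          freeze_elements = TRUE)
  # with frozen elements the control counts only U-V edges, which insertion
  # never adds, so the trace is constant at n^2
  expect_true(all(tf$raw == 9))
  tr <- run_insertion_sim(g, "p4", repeats = 1, seed = 9)
  expect_gt(max(tr$raw), 9)
})

test_that("normalization maps every trajectory into [0, 1] with maximum one", {
  g <- build_ideal_l3(5, 5)
  tr <- normalize_trace(run_removal_sim(g, c("p4", "l3n_f1", "l3n_prime_f2"),
                                        repeats = 3, seed = 13))
  expect_true(all(tr$normalized >= 0 & tr$normalized <= 1))
  for (p in attr(tr, "predictors")) {
    for (r in 1:3) {
      traj <- tr$normalized[tr$predictor == p & tr$rep == r]
      expect_equal(max(traj), 1)
    }
  }
  # L3N-family trajectories peak at the ideal graph on removal trajectories
  for (p in c("l3n_f1", "l3n_prime_f2")) {
    for (r in 1:3) {
      traj <- tr$normalized[tr$predictor == p & tr$rep == r]
      expect_equal(traj[1], 1)
    }
  }
})

test_that("trace AUC follows the trapezoidal rule, full and partial", {
  # build a synthetic one-repeat trace directly
  mk_trace <- function(y) {
    structure(
      data.frame(iteration = seq_along(y) - 1L, predictor = "p4", rep = 1L,
                 raw = y, stringsAsFactors = FALSE),
      class = c("sim_trace", "data.frame"),
      type = "removal", predictors = "p4", repeats = 1L,
      n_iter = length(y) - 1L, seed = 1L, pair = c("x", "y"),
      edge_log = list(), normalized = FALSE)
  }
  expect_equal(unname(trace_auc(normalize_trace(mk_trace(rep(3, 11))), "full")), 1)
  expect_equal(unname(trace_auc(normalize_trace(mk_trace(seq(10, 0))), "full")), 0.5)
  v <- c(seq(10, 0), seq(1, 10))  # V shape, min exactly at the midpoint
  pa <- trace_auc(normalize_trace(mk_trace(v)), "partial_from_min")
  expect_equal(unname(pa), pracma::trapz(seq(0, 1, length.out = 11),
                                         c(0:9, 10) / 10))
  expect_error(trace_auc(mk_trace(1:5)), "normalize")
})

test_that("Savitzky-Golay smoothing is exact on cubics and reduces noise", {
  x <- 0:80
  cubic <- 2 + 0.5 * x - 0.02 * x^2 + 0.0005 * x^3
  mk <- function(y) {
    structure(
      data.frame(iteration = seq_along(y) - 1L, predictor = "p4", rep = 1L,
                 raw = y, stringsAsFactors = FALSE),
      class = c("sim_trace", "data.frame"),
      type = "removal", predictors = "p4", repeats = 1L,
      n_iter = length(y) - 1L, seed = 1L, pair = c("x", "y"),
      edge_log = list(), normalized = FALSE)
  }
  sm <- smooth_trace(mk(cubic), window = 21, polyorder = 3)
  expect_equal(sm$raw, cubic, tolerance = 1e-8)
  const <- smooth_trace(mk(rep(4, 81)), window = 21, polyorder = 3)
  expect_equal(const$raw, rep(4, 81))
  noisy <- withr::with_seed(8, sin(x / 8) + rnorm(81, sd = 0.2))
  smn <- smooth_trace(mk(noisy), window = 21, polyorder = 3)
  expect_lt(stats::var(smn$raw - sin(x / 8)), stats::var(noisy - sin(x / 8)))
  expect_error(smooth_trace(mk(cubic), window = 20), "odd")
  expect_error(smooth_trace(mk(cubic), window = 3, polyorder = 3), "exceed")
  expect_error(smooth_trace(mk(cubic[1:10]), window = 21), "length")
})

test_that("duplication-mutation generator is seed-stable with twin duplicates at p_keep 1", {
  twins <- generate_dmc_network(30, p_keep = 1, p_anchor = 0, seed = 3)
  # every node duplicated from a parent has exactly its parent's neighbors;
  # with full retention and no anchor, some pair of nodes must be twins
  degs <- ppi_degree(twins)
  nb <- lapply(ppi_nodes(twins), function(a) ppi_neighbors(twins, a))
  names(nb) <- ppi_nodes(twins)
  twin_found <- FALSE
  nodes <- ppi_nodes(twins)
  for (i in seq_along(nodes)) for (j in seq_len(i - 1L)) {
    if (identical(nb[[i]], nb[[j]])) twin_found <- TRUE
  }
  expect_true(twin_found)

  a <- generate_dmc_network(60, seed = 11)
  b <- generate_dmc_network(60, seed = 11)
  expect_identical(ppi_edges(a), ppi_edges(b))
  expect_false(identical(ppi_edges(a),
                         ppi_edges(generate_dmc_network(60, seed = 12))))
  expect_error(generate_dmc_network(2), ">= 3")
  expect_error(generate_dmc_network(10, p_keep = 1.4), "0, 1")
})

test_that("duplication-mutation degree distributions are heavier-tailed than Erdos-Renyi", {
  dmc_tail <- 0; er_tail <- 0
  for (s in 1:5) {
    net <- generate_dmc_network(300, p_keep = 0.7, p_anchor = 0.1, seed = 900 + s)
    d <- ppi_degree(net)
    dmc_tail <- dmc_tail + mean(d > 3 * mean(d))
    er <- er_graph(300, mean(d) / 299, seed = 950 + s)
    de <- ppi_degree(er)
    er_tail <- er_tail + mean(de > 3 * mean(de))
  }
  expect_gt(dmc_tail, er_tail)
})
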