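# Cross-validation harness: edge-removal splits, negative-PPI injection,
# precision-recall curves and AUCs, top-k prediction sets, overlap ratios,
# moving means and significance tests.

new_eval_split <- function(train, removed, injected, original, seed) {
  structure(
    list(train = train, removed = removed, injected = injected,
         original = original, seed = seed),
    class = "eval_split"
  )
}

#' @export
print.eval_split <- function(x, ...) {
  cat(sprintf("<eval_split: %d train edges, %d removed, %d injected negatives>\n",
              x$train$m, nrow(x$removed), nrow(x$injected)))
  invisible(x)
}

edges_to_net <- function(edge_df, nodes) {
  ppi_network(as.matrix(edge_df), nodes = nodes)
}

#' Monte-Carlo edge-removal splits
#'
#' Creates `repeats` independent train/hidden splits, each removing
#' `round(fraction * m)` distinct edges uniformly at random. The removed
#' edges are the ground-truth positives the predictor is asked to recover;
#' the train network keeps the full node universe so every hidden edge
#' remains a candidate pair.
#'
#' @param net A [ppi_network].
#' @param fraction Fraction of edges to hide, strictly between 0 and 1.
#' @param repeats Number of independent splits (default 10).
#' @param seed Root seed; split `r` uses a derived seed.
#' @return A list of `eval_split` objects, each with elements `train`
#'   (network), `removed` (edge `data.frame`), `injected` (empty until
#'   [inject_negatives()]), `original` and `seed`.
#' @export
monte_carlo_split <- function(net, fraction, repeats = 10, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is_prob(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1")
  }
  if (!is_count(repeats)) stop("`repeats` must be a positive integer")
  edges <- ppi_edges(net)
  m <- nrow(edges)
  k <- round(fraction * m)
  if (k < 1 || k >= m) {
    stop("`fraction` removes no edges, or all of them, at this network size")
  }
  lapply(seq_len(repeats), function(r) {
    sr <- derive_seed(seed, r)
    hide <- withr::with_seed(sr, sample.int(m, k))
    new_eval_split(
      train = edges_to_net(edges[-hide, ], net$nodes),
      removed = edges[hide, , drop = FALSE],
      injected = edges[0, , drop = FALSE],
      original = net,
      seed = sr
    )
  })
}

#' k-fold cross-validation splits over edges
#'
#' Partitions the edge set into `k` disjoint, exhaustive folds; split `i`
#' trains on the other `k - 1` folds and hides fold `i` as ground truth.
#'
#' @inheritParams monte_carlo_split
#' @param k Number of folds, between 2 and the number of edges.
#' @return A list of `k` `eval_split` objects.
#' @export
kfold_split <- function(net, k, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  edges <- ppi_edges(net)
  m <- nrow(edges)
  if (!is_count(k, min = 2)) stop("`k` must be an integer >= 2")
  if (k > m) stop("`k` must not exceed the number of edges")
  perm <- withr::with_seed(derive_seed(seed, 0L), sample.int(m))
  fold <- rep_len(seq_len(k), m)[order(perm)]
  lapply(seq_len(k), function(i) {
    hide <- which(fold == i)
    new_eval_split(
      train = edges_to_net(edges[-hide, ], net$nodes),
      removed = edges[hide, , drop = FALSE],
      injected = edges[0, , drop = FALSE],
      original = net,
      seed = derive_seed(seed, i)
    )
  })
}

sample_non_edges <- function(net, n_needed, seed) {
  n <- length(net$nodes)
  total_pairs <- n * (n - 1) / 2
  n_non <- total_pairs - net$m
  if (n_needed > n_non) {
    stop("not enough non-edges in the original network to sample from")
  }
  withr::with_seed(seed, {
    if (total_pairs <= 2e6) {
      cand <- enumerate_candidates(net)
      pick <- sample.int(length(cand$i), n_needed)
      data.frame(node_a = net$nodes[cand$i[pick]],
                 node_b = net$nodes[cand$j[pick]],
                 stringsAsFactors = FALSE)
    } else {
      seen <- character(0)
      out_a <- character(0); out_b <- character(0)
      while (length(out_a) < n_needed) {
        i <- sample.int(n, 1L); j <- sample.int(n, 1L)
        if (i == j) next
        a <- min(i, j); b <- max(i, j)
        if (has_edge_idx(net, a, b)) next
        key <- paste(a, b)
        if (key %in% seen) next
        seen <- c(seen, key)
        out_a <- c(out_a, net$nodes[a]); out_b <- c(out_b, net$nodes[b])
      }
      data.frame(node_a = out_a, node_b = out_b, stringsAsFactors = FALSE)
    }
  })
}

#' Inject negative (non-) PPIs into a training split
#'
#' Replaces `round(ratio * train-edge-count)` uniformly chosen train edges
#' one-for-one by uniformly sampled non-edges of the original full network,
#' holding the train edge count fixed. The corrupted true edges do not join
#' the hidden ground-truth set: evaluation scores recovery of the
#' originally removed edges only, against a partially falsified network.
#'
#' @param split An `eval_split`.
#' @param ratio Fraction of train edges to replace, in `[0, 1]`.
#' @param seed Seed for the replacement draws.
#' @return The modified `eval_split` with the sampled negatives recorded in
#'   `$injected`.
#' @export
inject_negatives <- function(split, ratio, seed = 1L) {
  stopifnot(inherits(split, "eval_split"))
  if (!is_prob(ratio)) stop("`ratio` must lie in [0, 1]")
  train_edges <- ppi_edges(split$train)
  mt <- nrow(train_edges)
  n_inj <- round(ratio * mt)
  if (n_inj == 0) return(split)
  drop <- withr::with_seed(derive_seed(seed, 1L), sample.int(mt, n_inj))
  negs <- sample_non_edges(split$original, n_inj, derive_seed(seed, 2L))
  split$train <- edges_to_net(rbind(train_edges[-drop, ], negs),
                              split$original$nodes)
  split$injected <- negs
  split
}

#' Precision-recall curve down a ranking
#'
#' Walks the ranking from the top, one candidate at a time: a candidate in
#' `truth` increments the true positives, any other increments the false
#' positives, and `fn = |truth| - tp`. At every step precision
#' `tp/(tp+fp)` and recall `tp/(tp+fn)` are emitted; the walk stops once
#' recall reaches `recall_cap`, if one is set. The AUC is the trapezoidal
#' area under precision as a function of recall over the walked range
#' (anchored at recall 0 with the first precision value), so a perfect
#' ranking with no cap has AUC exactly 1.
#'
#' @param ranking A `ranked_predictions` table (see
#'   [score_all_candidates()]); ties must already be resolved, which the
#'   seeded tie-break guarantees.
#' @param truth Two-column edge `data.frame`/matrix of ground-truth
#'   positives; every truth pair must appear in the ranking's candidate
#'   universe.
#' @param recall_cap Optional recall level in (0, 1] at which to stop
#'   walking (e.g. 0.1 for the 10%-recall convention).
#' @return An object of class `pr_curve`: a list with `recall` and
#'   `precision` vectors, final `tp`/`fp`/`fn` counters, `auc`,
#'   `recall_cap` and `n_truth`.
#' @export
pr_curve <- function(ranking, truth, recall_cap = NULL) {
  stopifnot(is.data.frame(ranking))
  truth <- as.matrix(truth)
  if (nrow(truth) == 0) stop("`truth` must contain at least one edge")
  truth_keys <- unique(pair_key(as.character(truth[, 1]),
                                as.character(truth[, 2])))
  rank_keys <- pair_key(ranking$node_a, ranking$node_b)
  missing <- setdiff(truth_keys, rank_keys)
  if (length(missing)) {
    stop(sprintf("%d ground-truth pair(s) absent from the candidate universe",
                 length(missing)))
  }
  if (!is.null(recall_cap)) {
    if (!is_prob(recall_cap) || recall_cap <= 0) {
      stop("`recall_cap` must lie in (0, 1]")
    }
  }
  n_truth <- length(truth_keys)
  is_pos <- rank_keys %in% truth_keys
  tp <- cumsum(is_pos)
  steps <- seq_along(tp)
  recall <- tp / n_truth
  precision <- tp / steps
  if (!is.null(recall_cap)) {
    stop_at <- which(recall >= recall_cap)[1]
    if (!is.na(stop_at)) {
      recall <- recall[seq_len(stop_at)]
      precision <- precision[seq_len(stop_at)]
      tp <- tp[seq_len(stop_at)]
      steps <- steps[seq_len(stop_at)]
    }
  }
  nw <- length(recall)
  auc <- trapz_area(c(0, recall), c(precision[1], precision))
  structure(
    list(recall = recall, precision = precision,
         tp = tp[nw], fp = steps[nw] - tp[nw], fn = n_truth - tp[nw],
         n_truth = n_truth, auc = auc,
         recall_cap = if (is.null(recall_cap)) NA_real_ else recall_cap),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: %d steps, tp=%d fp=%d fn=%d, AUC=%.4f%s>\n",
              length(x$recall), x$tp, x$fp, x$fn, x$auc,
              if (is.na(x$recall_cap)) "" else
                sprintf(", recall cap %.2f", x$recall_cap)))
  invisible(x)
}

#' Top-k predicted edge set
#'
#' The first `k` pairs of a ranking — by convention `k` equals the number
#' of removed edges, so a perfect predictor attains 100% precision and
#' recall when its top-k set equals the hidden truth.
#'
#' @param ranking A `ranked_predictions` table.
#' @param k Number of predictions (0 gives an empty set; `k` beyond the
#'   number of candidates returns all candidates with a warning).
#' @return A `data.frame` with columns `node_a`, `node_b`.
#' @export
top_k_predictions <- function(ranking, k) {
  stopifnot(is.data.frame(ranking))
  if (!is_count(k, min = 0)) stop("`k` must be a non-negative integer")
  if (k > nrow(ranking)) {
    warning("`k` exceeds the number of candidates; returning all of them")
    k <- nrow(ranking)
  }
  ranking[seq_len(k), c("node_a", "node_b"), drop = FALSE]
}

#' Overlap ratio of two equally sized prediction sets
#'
#' `|A ∩ B| / k` for two top-k edge sets of the same size `k` — the
#' statistic used to compare the PPI pools favored by different predictors.
#'
#' @param pred_a,pred_b Two-column edge tables of equal size.
#' @return A number in `[0, 1]`.
#' @export
overlap_ratio <- function(pred_a, pred_b) {
  pred_a <- as.matrix(pred_a); pred_b <- as.matrix(pred_b)
  if (nrow(pred_a) != nrow(pred_b)) {
    stop("both prediction sets must have the same size k")
  }
  if (nrow(pred_a) == 0) stop("prediction sets must be non-empty")
  ka <- pair_key(as.character(pred_a[, 1]), as.character(pred_a[, 2]))
  kb <- pair_key(as.character(pred_b[, 1]), as.character(pred_b[, 2]))
  length(intersect(ka, kb)) / nrow(pred_a)
}

#' Mean relative change of PR AUC across a negative-PPI grid
#'
#' Given PR-AUC samples at increasing negative-injection ratios, computes
#' the mean over consecutive ratio steps of
#' `(mean AUC at next ratio - mean AUC at previous) / mean AUC at previous`.
#' Negative values mean the predictor degrades as more false PPIs enter the
#' training data.
#'
#' @param auc_by_ratio Named list mapping each ratio (names coercible to
#'   numeric) to a numeric vector of PR AUCs across repeats; at least two
#'   ratios required.
#' @return A single number (the mean relative ΔPR AUC).
#' @export
delta_pr_auc <- function(auc_by_ratio) {
  if (!is.list(auc_by_ratio) || length(auc_by_ratio) < 2) {
    stop("need PR AUCs at two or more ratios")
  }
  ratios <- as.numeric(names(auc_by_ratio))
  if (anyNA(ratios)) stop("list names must be numeric ratios")
  means <- vapply(auc_by_ratio, function(v) mean(as.numeric(v)), 0)
  means <- means[order(ratios)]
  base <- means[-length(means)]
  if (any(base == 0)) stop("zero baseline PR AUC; relative change undefined")
  mean(diff(means) / base)
}

#' Moving mean over a rank-ordered sequence
#'
#' Mean over sliding windows of length `window`, advancing `step` positions
#' per iteration — the summary used to relate prediction rank to external
#' per-edge scores.
#'
#' @param values Numeric vector in rank order.
#' @param window Window size (default 100), at most `length(values)`.
#' @param step Advance per iteration (default 10).
#' @return Numeric vector of window means (windows start at positions
#'   1, 1+step, 1+2*step, ...).
#' @export
moving_mean <- function(values, window = 100, step = 10) {
  if (!is_count(window)) stop("`window` must be a positive integer")
  if (!is_count(step)) stop("`step` must be a positive integer")
  if (window > length(values)) stop("`window` must not exceed the sequence length")
  starts <- seq.int(1L, length(values) - window + 1L, by = step)
  vapply(starts, function(s) mean(values[s:(s + window - 1L)]), 0)
}

#' Two-sample t-test on PR-AUC samples
#'
#' Two-tailed independent two-sample t-test (pooled variance) comparing two
#' sets of PR AUCs across repeats. When both samples are constant, the
#' p-value is 1 for equal means and 0 otherwise (the degenerate-variance
#' convention).
#'
#' @param aucs_a,aucs_b Numeric vectors with at least two values each.
#' @return The two-tailed p-value.
#' @export
compare_auc_ttest <- function(aucs_a, aucs_b) {
  aucs_a <- as.numeric(aucs_a); aucs_b <- as.numeric(aucs_b)
  if (length(aucs_a) < 2 || length(aucs_b) < 2) {
    stop("both samples need at least two values")
  }
  if (stats::sd(aucs_a) == 0 && stats::sd(aucs_b) == 0) {
    return(if (isTRUE(all.equal(mean(aucs_a), mean(aucs_b)))) 1 else 0)
  }
  stats::t.test(aucs_a, aucs_b, var.equal = TRUE)$p.value
}
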