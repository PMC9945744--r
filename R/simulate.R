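# Perturbation simulations on ideal L3 graphs: trace the score of the
# candidate pair (x, y) while compatible edges are removed or incompatible
# edges are inserted, one uniformly chosen edge per iteration.

sim_run <- function(g, predictors, repeats, seed, type,
                    freeze_elements = FALSE, assert_elements = (type == "removal")) {
  stopifnot(inherits(g, "ideal_l3_graph"))
  if (!length(predictors)) stop("`predictors` must name at least one predictor")
  predictors <- vapply(predictors, function(p) match.arg(p, predictor_names()),
                       character(1), USE.NAMES = FALSE)
  if (!is_count(repeats)) stop("`repeats` must be a positive integer")

  cls <- classify_edges(g)
  pool <- if (type == "removal") cls$compatible else cls$incompatible
  n_iter <- nrow(pool)
  xi <- node_idx(g$net, g$x)
  yi <- node_idx(g$net, g$y)
  ideal_uv <- l3_uv(g$net, xi, yi)
  frozen <- if (freeze_elements) ideal_uv else NULL

  score_now <- function(net) {
    uv <- if (freeze_elements) frozen else l3_uv(net, xi, yi)
    if (assert_elements && type == "removal") {
      if (!setequal(uv$U, ideal_uv$U) || !setequal(uv$V, ideal_uv$V)) {
        stop("internal error: L3-elements drifted during removal simulation")
      }
    }
    vapply(predictors, function(p) {
      if (p %in% c("cn", "ra", "aa", "cra", "rand")) {
        pair_score_idx(net, xi, yi, p, seed = seed)
      } else {
        l3_family_idx(net, xi, yi, p, uv = uv)
      }
    }, 0)
  }

  chunks <- vector("list", repeats)
  edge_log <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    perm <- withr::with_seed(derive_seed(seed, r), sample.int(n_iter))
    ordered <- pool[perm, , drop = FALSE]
    edge_log[[r]] <- ordered
    net <- g$net
    raw <- matrix(0, nrow = n_iter + 1L, ncol = length(predictors))
    raw[1L, ] <- score_now(net)
    for (t in seq_len(n_iter)) {
      i <- node_idx(net, ordered[t, 1])
      j <- node_idx(net, ordered[t, 2])
      net <- if (type == "removal") net_drop_edge(net, i, j)
             else net_add_edge(net, i, j)
      raw[t + 1L, ] <- score_now(net)
    }
    chunks[[r]] <- data.frame(
      iteration = rep(0:n_iter, times = length(predictors)),
      predictor = rep(predictors, each = n_iter + 1L),
      rep = r,
      raw = as.vector(raw),
      stringsAsFactors = FALSE
    )
  }
  structure(
    do.call(rbind, chunks),
    class = c("sim_trace", "data.frame"),
    type = type,
    predictors = predictors,
    repeats = as.integer(repeats),
    n_iter = n_iter,
    seed = seed,
    freeze_elements = freeze_elements,
    pair = c(g$x, g$y),
    edge_log = edge_log,
    normalized = FALSE
  )
}

#' Perturbation simulations on an ideal L3 graph
#'
#' `run_removal_sim()` deletes one uniformly chosen, not-yet-removed
#' *compatible* edge per iteration until all are gone; the index-matched
#' edges are protected, so the L3-elements `(x, y, U, V)` stay fixed along
#' the whole trajectory (asserted at every step). `run_insertion_sim()`
#' inserts one uniformly chosen, not-yet-inserted *incompatible* edge per
#' iteration. Each predictor's score of the pair `(x, y)` is recorded at
#' iteration 0 (the ideal graph) and after every edit; the whole trajectory
#' is repeated `repeats` times with derived seeds.
#'
#' During insertion, edges of the form `{x, v}` / `{y, u}` can change the
#' membership of `U` and `V`, so by default the L3-elements are recomputed
#' from their definitions at every iteration. `freeze_elements = TRUE`
#' instead keeps `U`, `V` fixed at their ideal values (the alternative
#' reading of the protocol).
#'
#' @param g An `ideal_l3_graph` from [build_ideal_l3()].
#' @param predictors Character vector of predictor names
#'   (see [predictor_names()]); the perturbation studies use the L3-based
#'   predictors plus the `"p4"` control.
#' @param repeats Number of independent repeat trajectories (default 10).
#' @param seed Root seed; repeat `r` uses a seed derived from it.
#' @param freeze_elements Insertion only: keep `U`, `V` at their ideal
#'   values instead of recomputing per iteration.
#' @return A long-format `data.frame` of class `sim_trace` with columns
#'   `iteration` (0..T), `predictor`, `rep` and `raw`, plus attributes
#'   `type`, `n_iter`, `seed` and `edge_log` (the per-repeat edit order,
#'   enabling exact replay).
#' @export
run_removal_sim <- function(g, predictors, repeats = 10, seed = 1L) {
  sim_run(g, predictors, repeats, seed, type = "removal")
}

#' @rdname run_removal_sim
#' @export
run_insertion_sim <- function(g, predictors, repeats = 10, seed = 1L,
                              freeze_elements = FALSE) {
  sim_run(g, predictors, repeats, seed, type = "insertion",
          freeze_elements = freeze_elements)
}

#' Normalize simulation trajectories to [0, 1]
#'
#' Divides each (predictor, repeat) trajectory by its own maximum so that
#' every trajectory lies in `[0, 1]` with maximum exactly 1; an all-zero
#' trajectory maps to all zeros. All predictor scores are non-negative, so
#' max-division is the natural scale-free normalization and reproduces
#' trajectories that start at 1 whenever the ideal graph is the maximum.
#'
#' @param trace A `sim_trace` from [run_removal_sim()] /
#'   [run_insertion_sim()].
#' @return The trace with an added `normalized` column.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  key <- paste(trace$predictor, trace$rep, sep = "\x1f")
  mx <- tapply(trace$raw, key, max)
  denom <- as.numeric(mx[key])
  norm <- ifelse(denom > 0, trace$raw / denom, 0)
  trace$normalized <- norm
  attr(trace, "normalized") <- TRUE
  trace
}

trace_median_matrix <- function(trace, column) {
  preds <- attr(trace, "predictors")
  n_iter <- attr(trace, "n_iter")
  vapply(preds, function(p) {
    sub <- trace[trace$predictor == p, ]
    as.numeric(tapply(sub[[column]], sub$iteration, stats::median))
  }, numeric(n_iter + 1L))
}

#' Trapezoidal AUC of normalized simulation trajectories
#'
#' Computes, per predictor, the area under the median (across repeats)
#' normalized trajectory with the iteration axis rescaled to `[0, 1]`.
#' `mode = "partial_from_min"` integrates only from the iteration where the
#' median trajectory attains its minimum to the end, with the x-axis
#' rescaled over that window — the summary used for insertion trajectories,
#' whose score eventually rises again as inserted edges create new paths.
#'
#' @param trace A normalized `sim_trace` (see [normalize_trace()]).
#' @param mode `"full"` or `"partial_from_min"`.
#' @return Named numeric vector of AUCs, one per predictor.
#' @export
trace_auc <- function(trace, mode = c("full", "partial_from_min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "sim_trace"))
  if (!isTRUE(attr(trace, "normalized"))) {
    stop("trace must be normalized first; see normalize_trace()")
  }
  n_iter <- attr(trace, "n_iter")
  if (n_iter + 1L < 2L) stop("trace must contain at least two points")
  med <- trace_median_matrix(trace, "normalized")
  x <- (0:n_iter) / n_iter
  out <- apply(med, 2, function(y) {
    if (mode == "full") {
      trapz_area(x, y)
    } else {
      i0 <- which.min(y)
      if (i0 >= length(y)) return(0)
      xs <- x[i0:length(y)]
      trapz_area((xs - xs[1]) / (xs[length(xs)] - xs[1]), y[i0:length(y)])
    }
  })
  stats::setNames(as.numeric(out), attr(trace, "predictors"))
}

#' Savitzky-Golay smoothing of simulation trajectories
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial fit) to
#' each (predictor, repeat) trajectory, for presentation of noisy insertion
#' traces. Smoothing is never applied before [trace_auc()] unless the
#' caller explicitly passes a smoothed trace; summary statistics default to
#' unsmoothed data.
#'
#' @param trace A `sim_trace`.
#' @param window Odd window length, greater than `polyorder` and at most
#'   the trajectory length (default 21).
#' @param polyorder Polynomial degree (default 3).
#' @return The trace with `raw` (and `normalized`, if present) replaced by
#'   their smoothed versions.
#' @export
smooth_trace <- function(trace, window = 21, polyorder = 3) {
  stopifnot(inherits(trace, "sim_trace"))
  n_len <- attr(trace, "n_iter") + 1L
  if (!is_count(window) || window %% 2 == 0) {
    stop("`window` must be a positive odd integer")
  }
  if (!is_count(polyorder, min = 0) || window <= polyorder) {
    stop("`window` must exceed `polyorder`")
  }
  if (window > n_len) stop("`window` must not exceed the trajectory length")
  cols <- intersect(c("raw", "normalized"), names(trace))
  key <- paste(trace$predictor, trace$rep, sep = "\x1f")
  for (cl in cols) {
    trace[[cl]] <- as.numeric(unlist(
      lapply(split(trace[[cl]], key)[unique(key)], function(y) {
        as.numeric(signal::sgolayfilt(y, p = polyorder, n = window))
      }),
      use.names = FALSE
    ))
  }
  trace
}

#' Export a simulation trace as long-format TSV
#'
#' Columns: `iteration`, `predictor`, `rep`, `raw` and (when present)
#' `normalized`. A comment header records the simulation type, seed and
#' problem size so the trace can be regenerated exactly.
#'
#' @param trace A `sim_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# type=%s seed=%s repeats=%d n_iter=%d pair=%s,%s",
                     attr(trace, "type"), format(attr(trace, "seed")),
                     attr(trace, "repeats"), attr(trace, "n_iter"),
                     attr(trace, "pair")[1], attr(trace, "pair")[2]), con)
  cols <- intersect(c("iteration", "predictor", "rep", "raw", "normalized"),
                    names(trace))
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(cols, function(cl) {
    v <- trace[[cl]]
    if (is.numeric(v) && cl %in% c("raw", "normalized")) {
      format(v, digits = 15, trim = TRUE, scientific = FALSE)
    } else format(v, trim = TRUE)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}
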