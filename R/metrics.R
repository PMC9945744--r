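# Set-similarity metrics used by the normalized L3 predictors.

# Index-level versions operating on duplicate-free integer vectors.
f1_idx <- function(a, b) {
  if (!length(a)) return(0)
  n_common(a, b) / length(a)
}

f2_idx <- function(a, b) {
  i <- n_common(a, b)
  u <- length(a) + length(b) - i
  if (u == 0L) return(0)
  i / u
}

metric_fun <- function(tag) {
  switch(tag, f1 = f1_idx, f2 = f2_idx,
         stop(sprintf("unknown similarity metric %s (use \"f1\" or \"f2\")",
                      sQuote(tag))))
}

#' Set-similarity metrics: simple ratio and Jaccard coefficient
#'
#' `metric_f1()` is the simple ratio `|A ∩ B| / |A|`: the size of the
#' intersection relative to the size of the first set, so a perfect score is
#' reached whenever `A ⊆ B`. `metric_f2()` is the Jaccard coefficient
#' `|A ∩ B| / |A ∪ B|`, which treats both sets as equally important and is
#' maximal only when `A = B`. Both lie in `[0, 1]`.
#'
#' Empty-denominator rule: when the denominator set is empty (for `f1`, an
#' empty `A`; for `f2`, both sets empty) the metric returns 0, the
#' conservative no-evidence value that keeps all predictor scores finite.
#'
#' @param A,B Vectors interpreted as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' metric_f1(c("a", "b"), c("b", "c"))  # 0.5
#' metric_f2(c("a", "b"), c("b", "c"))  # 1/3
#' @export
metric_f1 <- function(A, B) {
  f1_idx(unique(A), unique(B))
}

#' @rdname metric_f1
#' @export
metric_f2 <- function(A, B) {
  f2_idx(unique(A), unique(B))
}
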