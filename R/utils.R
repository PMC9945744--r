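# Internal helpers shared across modules.

# Derive a child seed from a root seed and a stream index. Kept inside 32-bit
# integer range so it is always a legal argument to set.seed().
derive_seed <- function(seed, k) {
  s <- abs(as.double(seed)) %% 2147483647
  r <- (s * 48271 + abs(as.double(k)) * 69621 + 1) %% 2147483647
  as.integer(r)
}

# Canonical unordered-pair key; \x1f cannot occur in sane identifiers.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

# Number of shared elements of two duplicate-free vectors.
n_common <- function(a, b) {
  if (length(a) > length(b)) {
    sum(match(b, a, nomatch = 0L) > 0L)
  } else {
    sum(match(a, b, nomatch = 0L) > 0L)
  }
}

any_common <- function(a, b) {
  if (length(a) > length(b)) {
    any(match(b, a, nomatch = 0L) > 0L)
  } else {
    any(match(a, b, nomatch = 0L) > 0L)
  }
}

trapz_area <- function(x, y) pracma::trapz(x, y)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
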