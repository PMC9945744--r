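# Brute-force oracles written straight from the defining formulas, using only
# the public neighbor-set accessor. Deliberately naive (explicit double loops
# over U x V, character sets) and independent of the package's factorized
# scoring path.

bf_f1 <- function(A, B) if (length(A) == 0) 0 else length(intersect(A, B)) / length(A)
bf_f2 <- function(A, B) {
  u <- union(A, B)
  if (length(u) == 0) 0 else length(intersect(A, B)) / length(u)
}

bf_uv <- function(net, x, y) {
  Nx <- ppi_neighbors(net, x)
  Ny <- ppi_neighbors(net, y)
  U <- Nx[vapply(Nx, function(a) length(intersect(ppi_neighbors(net, a), Ny)) > 0, TRUE)]
  V <- Ny[vapply(Ny, function(b) length(intersect(ppi_neighbors(net, b), Nx)) > 0, TRUE)]
  list(U = U, V = V)
}

# All simple paths x-u-v-y, by exhaustive enumeration over neighbor pairs.
bf_count_p4 <- function(net, x, y) {
  total <- 0L
  for (u in ppi_neighbors(net, x)) {
    if (u == y) next
    for (v in ppi_neighbors(net, u)) {
      if (v == x || v == u) next
      if (has_edge(net, v, y) && v != y && u != y) total <- total + 1L
    }
  }
  total
}

bf_score <- function(net, x, y, predictor) {
  uv <- bf_uv(net, x, y)
  U <- uv$U; V <- uv$V
  Nx <- ppi_neighbors(net, x)
  Ny <- ppi_neighbors(net, y)
  deg <- function(a) length(ppi_neighbors(net, a))

  if (predictor == "sim") {
    s <- 0
    for (v in V) s <- s + bf_f2(ppi_neighbors(net, v), Nx)
    for (u in U) s <- s + bf_f2(ppi_neighbors(net, u), Ny)
    return(s)
  }

  total <- 0
  for (u in U) for (v in V) {
    if (!has_edge(net, u, v)) next
    Nu <- ppi_neighbors(net, u)
    Nv <- ppi_neighbors(net, v)
    term <- switch(predictor,
      p4 = 1,
      l3 = 1 / sqrt(deg(u) * deg(v)),
      ch2 = {
        cs <- union(U, V)
        num <- sqrt((1 + length(intersect(Nu, cs))) *
                    (1 + length(intersect(Nv, cs))))
        den <- sqrt((1 + length(setdiff(setdiff(Nu, cs), c(x, y)))) *
                    (1 + length(setdiff(setdiff(Nv, cs), c(x, y)))))
        num / den
      },
      l3n_f1 = ,
      l3n_f2 = {
        f <- if (predictor == "l3n_f1") bf_f1 else bf_f2
        Nu_ <- setdiff(Nu, x); Nv_ <- setdiff(Nv, y)
        f(Nu_, V) * f(Nv_, U) * f(Nx, Nv_) * f(Ny, Nu_)
      },
      l3n_prime_f1 = ,
      l3n_prime_f2 = {
        f <- if (predictor == "l3n_prime_f1") bf_f1 else bf_f2
        f(Nu, V) * f(Nv, U) * f(Nx, Nv) * f(Ny, Nu)
      },
      stop("no brute-force oracle for ", predictor)
    )
    total <- total + term
  }
  if (startsWith(predictor, "l3n")) {
    f <- if (endsWith(predictor, "f1")) bf_f1 else bf_f2
    total <- f(Nx, U) * f(Ny, V) * total
  }
  total
}

# Non-adjacent pairs of a network, as a two-column character matrix.
non_adjacent_pairs <- function(net) {
  nodes <- ppi_nodes(net)
  idx <- utils::combn(length(nodes), 2)
  keep <- !mapply(function(i, j) has_edge(net, nodes[i], nodes[j]),
                  idx[1, ], idx[2, ])
  cbind(nodes[idx[1, keep]], nodes[idx[2, keep]])
}

# Local canonical pair key for test bookkeeping.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\x1f")
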