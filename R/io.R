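# Edge-list ingestion with dataset-cleaning accounting, and canonical
# edge-list output.

detect_delimiter <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else "[[:space:]]+"
}

looks_like_header <- function(tokens, id_cols) {
  pat <- "(?i)protein|interactor|node|gene|symbol|source|target|^id$|^from$|^to$"
  any(grepl(pat, tokens[id_cols], perl = TRUE))
}

#' Load a PPI edge list with cleaning accounting
#'
#' Reads a delimited interaction file (two identifier columns plus optional
#' annotation columns) and applies the standard dataset-cleaning rules:
#' directional records `a b` / `b a` collapse to one undirected edge, exact
#' duplicates (multiple lines of evidence) are excluded, and
#' self-interacting-protein records (`a a`) are removed and counted. A
#' generic column filter (column index plus accepted values) covers
#' annotation-based record selection without hard-coding any database
#' vocabulary. Malformed rows are counted and skipped. Every count is
#' reported in the returned manifest, whose arithmetic always reconciles:
#' `raw = edges kept + duplicates collapsed + self-loops + filtered out +
#' malformed`.
#'
#' The network container is a simple graph, so self-loop records can never
#' become edges; with `drop_sips = FALSE` they are still excluded (with a
#' warning) but remain counted in the manifest.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab,
#'   comma or whitespace from the first data line.
#' @param drop_sips Count-and-drop self-interaction records (default
#'   `TRUE`; see Details).
#' @param column_filter Optional `list(col = <index>, values = <character
#'   vector>)`: keep only rows whose `col`-th field is one of `values`.
#' @param header `"auto"` (default; first row skipped when its identifier
#'   columns look like column names), `TRUE` (always skip) or `FALSE`
#'   (never skip).
#' @param id_cols Integer positions of the two identifier columns
#'   (default `c(1, 2)`).
#' @return A list with elements `network` (a [ppi_network]) and `manifest`
#'   (class `dataset_manifest`).
#' @export
load_edge_list <- function(path, delimiter = NULL, drop_sips = TRUE,
                           column_filter = NULL, header = "auto",
                           id_cols = c(1L, 2L)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", sQuote(path)))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("no records in %s", sQuote(path)))
  if (!isTRUE(drop_sips)) {
    warning("self-interactions cannot be represented in a simple graph; ",
            "they are dropped regardless (and counted in the manifest)")
  }
  if (!is.null(column_filter) &&
      (!is.list(column_filter) || is.null(column_filter$col) ||
       is.null(column_filter$values))) {
    stop("`column_filter` must be list(col = <index>, values = <values>)")
  }

  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[1])
  fixed <- delimiter %in% c("\t", ",", ";", " ")
  toks <- strsplit(lines, delimiter, fixed = fixed, perl = !fixed)
  toks <- lapply(toks, trimws)

  skip_header <- FALSE
  if (identical(header, TRUE)) {
    skip_header <- TRUE
  } else if (identical(header, "auto")) {
    first <- toks[[1]]
    skip_header <- length(first) >= max(id_cols) &&
      looks_like_header(first, id_cols)
  }
  header_rows <- as.integer(skip_header)
  if (skip_header) toks <- toks[-1]
  raw <- length(toks)
  if (!raw) stop(sprintf("no records in %s", sQuote(path)))

  need_cols <- max(id_cols, if (!is.null(column_filter)) column_filter$col else 0L)
  ok_len <- vapply(toks, length, 0L) >= need_cols
  a <- rep(NA_character_, raw); b <- rep(NA_character_, raw)
  a[ok_len] <- vapply(toks[ok_len], `[[`, "", id_cols[1])
  b[ok_len] <- vapply(toks[ok_len], `[[`, "", id_cols[2])
  malformed <- !ok_len | is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)
  n_malformed <- sum(malformed)
  if (n_malformed) {
    message(sprintf("skipped %d malformed row(s) in %s", n_malformed,
                    basename(path)))
  }

  filtered <- rep(FALSE, raw)
  if (!is.null(column_filter)) {
    vals <- rep(NA_character_, raw)
    vals[ok_len] <- vapply(toks[ok_len], `[[`, "", column_filter$col)
    filtered <- !malformed & !(vals %in% as.character(column_filter$values))
  }

  use <- !malformed & !filtered
  a <- a[use]; b <- b[use]
  loops <- a == b
  n_sips <- sum(loops)
  a <- a[!loops]; b <- b[!loops]
  ka <- pmin(a, b); kb <- pmax(a, b)
  dup <- duplicated(paste(ka, kb, sep = "\x1f"))
  n_dup <- sum(dup)
  ka <- ka[!dup]; kb <- kb[!dup]
  if (!length(ka)) stop(sprintf("no edges survive cleaning in %s", sQuote(path)))

  net <- ppi_network(cbind(ka, kb))
  manifest <- structure(
    list(source = path,
         raw_records = raw,
         header_rows = header_rows,
         malformed = n_malformed,
         filtered_out = sum(filtered),
         self_loops_removed = n_sips,
         duplicates_collapsed = n_dup,
         n_nodes = length(net$nodes),
         n_edges = net$m,
         options = list(delimiter = delimiter, drop_sips = drop_sips,
                        column_filter = column_filter, header = header,
                        id_cols = id_cols)),
    class = "dataset_manifest"
  )
  list(network = net, manifest = manifest)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest>\n")
  cat(sprintf("  source:               %s\n", x$source))
  cat(sprintf("  raw records:          %d\n", x$raw_records))
  cat(sprintf("  malformed skipped:    %d\n", x$malformed))
  cat(sprintf("  filtered out:         %d\n", x$filtered_out))
  cat(sprintf("  self-loops removed:   %d\n", x$self_loops_removed))
  cat(sprintf("  duplicates collapsed: %d\n", x$duplicates_collapsed))
  cat(sprintf("  final:                %d nodes, %d edges\n",
              x$n_nodes, x$n_edges))
  invisible(x)
}

#' Write a canonical edge list
#'
#' One edge per line, tab-separated, identifiers in lexicographic order
#' within each line and lines sorted, so two networks with equal edge sets
#' produce byte-identical files.
#'
#' @param net A non-empty [ppi_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  if (net$m == 0) stop("refusing to write an edgeless network")
  edges <- ppi_edges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(edges$node_a, edges$node_b, sep = "\t"), con)
  invisible(path)
}
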