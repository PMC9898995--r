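#' Read a gene-interaction edge list
#'
#' Reads a two-column tab- or whitespace-separated edge list of gene symbols
#' into an undirected simple [igraph][igraph::graph] graph. A third SIF-style
#' relation column is tolerated and ignored. Self-loops and duplicate edges
#' are dropped with a message reporting the count; a malformed line is a hard
#' error naming the line.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph with gene symbols as vertex
#'   names.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  ends <- matrix(NA_character_, length(lines), 2)
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (!length(fields) %in% c(2L, 3L))
      ln_stop("malformed edge-list line %d (%d field(s), need 2 or 3): '%s'",
              i, length(fields), lines[i])
    ends[i, ] <- fields[1:2]
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- igraph::ecount(g) - igraph::ecount(gs)
  if (dropped > 0)
    message(sprintf("dropped %d self-loop/duplicate edge(s)", dropped))
  gs
}

#' Write a gene network as a two-column edge list
#'
#' @param g An undirected `igraph` graph with named vertices.
#' @param path Output path.
#' @return `g`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(), path)
  invisible(g)
}

# Validate the simple-graph invariants of a gene network.
check_network <- function(g) {
  if (!igraph::is_igraph(g)) ln_stop("expected an igraph graph")
  if (igraph::is_directed(g)) ln_stop("network must be undirected")
  if (!igraph::is_simple(g)) ln_stop("network must be simple (no loops/multi-edges)")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    ln_stop("network vertices must be named with gene symbols")
  invisible(g)
}
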