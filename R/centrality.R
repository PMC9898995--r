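#' Hub centrality scores
#'
#' Computes one of the five hub centralities used to rank regulatory genes:
#' * `degree` — number of incident edges;
#' * `mnc` — maximum neighborhood component: the size of the largest
#'   connected component of the subgraph induced by the open neighborhood
#'   `N(v)`;
#' * `dmnc` — density of the maximum neighborhood component:
#'   `|E(M)| / |V(M)|^epsilon` over that same component (ties between
#'   equal-sized components broken by the larger edge count);
#' * `mcc` — maximal clique centrality: the sum over maximal cliques `C`
#'   containing `v` of `(|C| - 1)!`, with the convention that an isolated
#'   vertex scores `0! = 1`;
#' * `epc` — edge percolated component: the mean, over `epc_iters`
#'   Monte-Carlo percolations (each trial draws a retention probability
#'   `p ~ U(0,1)` and keeps each edge independently with probability `p`),
#'   of the size of `v`'s component (including `v`). Deterministic given
#'   `seed`.
#'
#' @param g Undirected simple igraph graph with named vertices.
#' @param method One of `"degree"`, `"mnc"`, `"dmnc"`, `"mcc"`, `"epc"`.
#' @param epc_iters Monte-Carlo iterations for EPC (>= 1).
#' @param epsilon DMNC density exponent.
#' @param seed Seed for EPC percolation draws.
#' @param retention Optional fixed edge-retention probability for EPC
#'   (`NULL`, the default, draws `p ~ U(0,1)` per trial; `1` disables
#'   percolation entirely, so EPC(v) is v's component size).
#' @return Named numeric vector of scores, one per vertex.
#' @export
centrality_scores <- function(g, method = c("degree", "mnc", "dmnc", "mcc", "epc"),
                              epc_iters = 100, epsilon = 1.7, seed = 1,
                              retention = NULL) {
  check_network(g)
  if (igraph::vcount(g) == 0) ln_stop("empty graph")
  method <- match.arg(method)
  nms <- igraph::V(g)$name
  switch(method,
    degree = igraph::degree(g)[nms],
    mnc = mnc_components(g)$size,
    dmnc = {
      comp <- mnc_components(g)
      ifelse(comp$size > 0, comp$edges / comp$size^epsilon, 0)
    },
    mcc = {
      score <- stats::setNames(numeric(length(nms)), nms)
      cliques <- igraph::max_cliques(g, min = 1)
      for (cl in cliques) {
        members <- cl$name
        score[members] <- score[members] + factorial(length(members) - 1)
      }
      score
    },
    epc = {
      if (epc_iters < 1) ln_stop("epc_iters must be >= 1")
      el <- igraph::as_edgelist(g, names = FALSE)
      n <- length(nms)
      acc <- numeric(n)
      with_seed(seed, {
        for (i in seq_len(epc_iters)) {
          p <- retention %||% stats::runif(1)
          keep <- stats::runif(nrow(el)) <= p
          sub <- igraph::make_graph(t(el[keep, , drop = FALSE]), n = n,
                                    directed = FALSE)
          comp <- igraph::components(sub)
          acc <- acc + comp$csize[comp$membership]
        }
      })
      stats::setNames(acc / epc_iters, nms)
    }
  )
}

# For each vertex: size and edge count of the largest connected component of
# the open-neighborhood-induced subgraph (ties by edge count).
mnc_components <- function(g) {
  nms <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  size <- stats::setNames(numeric(length(nms)), nms)
  edges <- stats::setNames(numeric(length(nms)), nms)
  for (i in seq_along(nms)) {
    nb <- adj[[i]]$name
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    best_size <- max(comp$csize)
    best_edges <- max(vapply(which(comp$csize == best_size), function(k) {
      igraph::ecount(igraph::induced_subgraph(
        sub, names(comp$membership)[comp$membership == k]))
    }, numeric(1)))
    size[i] <- best_size
    edges[i] <- best_edges
  }
  list(size = size, edges = edges)
}

#' Aggregate per-method top-k hub membership
#'
#' Takes the top `k` genes of each centrality method (ties broken by
#' descending degree then lexicographic symbol), removes genes with degree
#' below `min_degree` from every top-k list, and tallies in how many methods
#' each gene remains (`selected_count`, 0-5).
#'
#' @param tables Named list of named score vectors; must contain all five of
#'   `degree`, `mnc`, `dmnc`, `mcc`, `epc` over the same genes.
#' @param k Top-k size (clamped to the gene count with a warning).
#' @param min_degree Degree threshold for the exclusion rule.
#' @return A tibble of class `hub_score_table`: `gene`, the five scores, the
#'   five `top_*` logical flags and `selected_count`, sorted by decreasing
#'   `selected_count` then degree.
#' @export
top_k_aggregate <- function(tables, k = 10, min_degree = 10) {
  methods <- c("degree", "mnc", "dmnc", "mcc", "epc")
  if (!all(methods %in% names(tables)))
    ln_stop("`tables` must contain all of: %s", paste(methods, collapse = ", "))
  genes <- names(tables$degree)
  if (any(vapply(tables[methods], function(t) !setequal(names(t), genes), logical(1))))
    ln_stop("all score tables must cover the same genes")
  if (k > length(genes)) {
    ln_warn("k = %d exceeds the %d genes; clamped", k, length(genes))
    k <- length(genes)
  }
  deg <- tables$degree[genes]
  top <- lapply(tables[methods], function(sc) {
    sc <- sc[genes]
    ord <- order(-sc, -deg, genes)
    picked <- genes[ord[seq_len(k)]]
    setdiff(picked, genes[deg < min_degree])
  })
  res <- tibble(
    gene = genes,
    degree = unname(deg),
    mnc = unname(tables$mnc[genes]),
    dmnc = unname(tables$dmnc[genes]),
    mcc = unname(tables$mcc[genes]),
    epc = unname(tables$epc[genes])
  )
  for (m in methods) res[[paste0("top_", m)]] <- genes %in% top[[m]]
  res$selected_count <- rowSums(as.matrix(res[paste0("top_", methods)]))
  res <- dplyr::arrange(res, dplyr::desc(.data$selected_count),
                        dplyr::desc(.data$degree), .data$gene)
  class(res) <- c("hub_score_table", class(res))
  res
}

#' Compute all five hub centralities on one graph
#'
#' Convenience wrapper returning the named list [top_k_aggregate()] expects.
#'
#' @inheritParams centrality_scores
#' @return Named list of the five score vectors.
#' @export
all_centralities <- function(g, epc_iters = 100, epsilon = 1.7, seed = 1) {
  list(degree = centrality_scores(g, "degree"),
       mnc = centrality_scores(g, "mnc"),
       dmnc = centrality_scores(g, "dmnc", epsilon = epsilon),
       mcc = centrality_scores(g, "mcc"),
       epc = centrality_scores(g, "epc", epc_iters = epc_iters, seed = seed))
}
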