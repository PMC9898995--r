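#' MCODE molecular-complex detection
#'
#' Bader–Hogue procedure. Stage 1 weights each vertex by the highest k-core
#' of its closed neighborhood: `w(v) = k_max * density(k_max-core)`, where
#' the density of a subgraph on `V` vertices and `E` edges is
#' `2E / (V (V - 1))`. Stage 2 grows complexes outward from unvisited
#' highest-weight seed vertices, admitting neighbours with weight
#' `>= (1 - vwp) * w(seed)` up to `max_depth` steps; each vertex joins at most
#' one complex. Stage 3 optionally "fluffs" (adds boundary neighbours whose
#' closed-neighbourhood density exceeds `fluff_density`; such vertices may be
#' shared between complexes) and "haircuts" (keeps the 2-core, removing
#' tree-like fringes). The module score is `density * node count`.
#'
#' @param g Undirected simple igraph graph with named vertices.
#' @param vwp Vertex weight percentage in (0, 1); larger admits more.
#' @param haircut,fluff Post-processing flags.
#' @param fluff_density Closed-neighbourhood density threshold for fluff.
#' @param max_depth Growth depth limit from each seed.
#' @return A tibble of class `mcode_modules`, sorted by decreasing score:
#'   `seed`, `n_nodes`, `score`, `nodes` (list column).
#' @export
mcode_modules <- function(g, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                          fluff_density = 0.1, max_depth = 100) {
  check_network(g)
  if (igraph::vcount(g) == 0) ln_stop("empty graph")
  w <- mcode_vertex_weights(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  names(adj) <- igraph::V(g)$name
  adj <- lapply(adj, function(vs) vs$name)
  visited <- character()
  out <- list()
  for (seed in names(sort(w, decreasing = TRUE))) {
    if (seed %in% visited || w[seed] <= 0) next
    thr <- (1 - vwp) * w[seed]
    module <- seed
    frontier <- seed
    visited <- c(visited, seed)
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      cand <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), visited)
      cand <- cand[w[cand] >= thr]
      if (!length(cand)) break
      visited <- c(visited, cand)
      module <- c(module, cand)
      frontier <- cand
      depth <- depth + 1
    }
    if (fluff) {
      boundary <- setdiff(unique(unlist(adj[module], use.names = FALSE)), module)
      keep <- boundary[vapply(boundary, function(u) {
        closed_neighborhood_density(g, u) > fluff_density
      }, logical(1))]
      module <- c(module, keep)
    }
    if (haircut && length(module) > 1) {
      sub <- igraph::induced_subgraph(g, module)
      core <- igraph::coreness(sub)
      module <- names(core)[core >= 2]
    }
    if (length(module) < 2) next
    sub <- igraph::induced_subgraph(g, module)
    if (igraph::ecount(sub) == 0) next
    nv <- igraph::vcount(sub)
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    out[[length(out) + 1]] <- tibble(seed = seed, n_nodes = nv,
                                     score = dens * nv,
                                     nodes = list(sort(module)))
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(seed = character(), n_nodes = integer(), score = numeric(),
           nodes = list())
  res <- dplyr::arrange(res, dplyr::desc(.data$score), dplyr::desc(.data$n_nodes),
                        .data$seed)
  class(res) <- c("mcode_modules", class(res))
  res
}

mcode_vertex_weights <- function(g) {
  nms <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  w <- vapply(seq_along(nms), function(i) {
    nb <- c(nms[i], adj[[i]]$name)
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) return(0)
    core_sub <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    nv <- igraph::vcount(core_sub)
    dens <- if (nv < 2) 0 else 2 * igraph::ecount(core_sub) / (nv * (nv - 1))
    kmax * dens
  }, numeric(1))
  stats::setNames(w, nms)
}

closed_neighborhood_density <- function(g, v) {
  nb <- c(v, igraph::neighbors(g, v)$name)
  if (length(nb) < 2) return(0)
  sub <- igraph::induced_subgraph(g, nb)
  2 * igraph::ecount(sub) / (igraph::vcount(sub) * (igraph::vcount(sub) - 1))
}

#' Select the disease-defining gene signature from MCODE modules
#'
#' Applies the module admission criteria (score strictly greater than
#' `min_score` and node count strictly greater than `min_nodes`) to the
#' up-regulated and down-regulated module lists, takes the top-ranked passing
#' module per direction, and returns the union as the DDG signature.
#'
#' @param up_modules,down_modules `mcode_modules` tibbles from the up- and
#'   down-regulated DEG subnetworks.
#' @param min_score,min_nodes Admission criteria (defaults 3 and 5).
#' @return A [signature_collection()] with sets `ddg_up`, `ddg_down` (when
#'   present) and `ddg` (their union). If only one direction passes, a
#'   warning is emitted; if neither passes, a hard error advises parameter
#'   review.
#' @export
select_ddgs <- function(up_modules, down_modules, min_score = 3, min_nodes = 5) {
  pick <- function(mods) {
    ok <- mods$score > min_score & mods$n_nodes > min_nodes
    if (!any(ok)) return(NULL)
    mods$nodes[[which(ok)[1]]]
  }
  up <- pick(up_modules); down <- pick(down_modules)
  if (is.null(up) && is.null(down))
    ln_stop("no module passes score > %s and nodes > %s in either direction; review MCODE parameters",
            min_score, min_nodes)
  if (is.null(up)) ln_warn("no up-regulated module passes the DDG criteria")
  if (is.null(down)) ln_warn("no down-regulated module passes the DDG criteria")
  sets <- list()
  if (!is.null(up)) sets$ddg_up <- up
  if (!is.null(down)) sets$ddg_down <- down
  sets$ddg <- union(up, down)
  signature_collection(sets, stats::setNames(
    c(if (!is.null(up)) "up-regulated DDG module",
      if (!is.null(down)) "down-regulated DDG module",
      "disease-defining gene signature"), names(sets)))
}
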