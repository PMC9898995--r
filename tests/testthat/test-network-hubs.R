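test_that("MCODE recovers cliques with score = size and handles sparse graphs", {
  g <- igraph::make_full_graph(6) +
    igraph::make_empty_graph(3, directed = FALSE)
  g <- named_graph(g)
  mods <- mcode_modules(g)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$score, 6)
  expect_setequal(mods$nodes[[1]], paste0("v", 1:6))

  # two disjoint cliques: both found, ranked by score
  g2 <- named_graph(igraph::make_full_graph(8) +
                      igraph::make_full_graph(5))
  mods2 <- mcode_modules(g2)
  expect_equal(mods2$score, c(8, 5))
  # DDG criteria: score > 3 AND nodes > 5 admits only the 8-clique
  pass <- mods2$score > 3 & mods2$n_nodes > 5
  expect_equal(pass, c(TRUE, FALSE))

  # empty-edge graph: no modules
  g3 <- named_graph(igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(nrow(mcode_modules(g3)), 0)
  expect_error(mcode_modules(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("DDG selection takes the top passing module per direction", {
  mk <- function(score, n) tibble::tibble(
    seed = "x", n_nodes = n, score = score,
    nodes = list(sprintf("%s%02d", if (score > 4) "U" else "D", seq_len(n))))
  up <- mk(5.2, 12); down <- mk(3.5, 7)
  sig <- select_ddgs(up, down)
  expect_length(sig$sets$ddg, 19)
  # down module failing the score criterion: only up genes, with a warning
  expect_warning(sig2 <- select_ddgs(up, mk(2.9, 7)), "down-regulated")
  expect_length(sig2$sets$ddg, 12)
  expect_null(sig2$sets$ddg_down)
  # both failing: hard error
  expect_error(suppressWarnings(select_ddgs(mk(2, 12), mk(2.9, 7))), "review")
})

test_that("centralities match hand values on the triangle and path", {
  tri <- named_graph(igraph::make_full_graph(3))
  expect_equal(unname(centrality_scores(tri, "degree")), rep(2, 3))
  expect_equal(unname(centrality_scores(tri, "mnc")), rep(2, 3))
  expect_equal(unname(centrality_scores(tri, "dmnc")), rep(1 / 2^1.7, 3))
  expect_equal(unname(centrality_scores(tri, "mcc")), rep(2, 3))

  p <- igraph::make_graph(~ a - b, b - c)
  mcc <- centrality_scores(p, "mcc")
  expect_equal(mcc[["b"]], 2)  # 1! + 1!
  expect_equal(mcc[["a"]], 1)
  expect_equal(centrality_scores(p, "mnc")[["b"]], 1)  # two isolated neighbors

  # no percolation at retention 1: EPC(v) = component size
  k5 <- named_graph(igraph::make_full_graph(5))
  expect_equal(unname(centrality_scores(k5, "epc", epc_iters = 3, retention = 1)),
               rep(5, 5))
  expect_error(centrality_scores(tri, "unknown"))
})

test_that("centrality scores are invariant under node relabeling", {
  set.seed(42)
  g <- named_graph(igraph::sample_gnp(30, 0.15))
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  for (m in c("degree", "mnc", "dmnc", "mcc")) {
    s1 <- centrality_scores(g, m)
    s2 <- centrality_scores(g2, m)
    expect_equal(s1[names(s2)], s2, tolerance = 1e-12)
  }
  # EPC: same seed, names follow the vertices
  e1 <- centrality_scores(g, "epc", epc_iters = 400, seed = 3)
  e2 <- centrality_scores(g2, "epc", epc_iters = 400, seed = 3)
  expect_equal(unname(sort(e1)), unname(sort(e2)), tolerance = 0.5)
})

test_that("EPC is deterministic given the seed and grows with edge addition", {
  set.seed(7)
  g <- named_graph(igraph::sample_gnp(25, 0.08))
  a <- centrality_scores(g, "epc", epc_iters = 200, seed = 11)
  b <- centrality_scores(g, "epc", epc_iters = 200, seed = 11)
  expect_identical(a, b)
  # adding an edge raises mean component size in expectation
  miss <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                  upper.tri(matrix(TRUE, 25, 25)), arr.ind = TRUE)[1, ]
  g_plus <- igraph::add_edges(g, igraph::V(g)$name[miss])
  a_plus <- centrality_scores(g_plus, "epc", epc_iters = 2000, seed = 11)
  expect_gte(mean(a_plus), mean(centrality_scores(g, "epc", epc_iters = 2000,
                                                  seed = 11)) - 0.05)
})

test_that("top-k aggregation applies the degree filter and documented tie-break", {
  genes <- sprintf("x%02d", 1:12)
  deg <- setNames(c(20, 18, 16, 15, 14, 13, 12, 12, 11, 9, 8, 7), genes)
  base <- setNames(seq(12, 1), genes)
  tables <- list(degree = deg, mnc = base, dmnc = base, mcc = base, epc = base)
  # x10 has degree 9 -> excluded from every top-k even if top-ranked on mcc
  tables$mcc["x10"] <- 100
  tab <- top_k_aggregate(tables, k = 10, min_degree = 10)
  x10 <- tab[tab$gene == "x10", ]
  expect_equal(x10$selected_count, 0)
  expect_false(x10$top_mcc)
  # gene in all five top-10s
  expect_equal(tab$selected_count[tab$gene == "x01"], 5)
  # tie at the rank-10 boundary broken by descending degree
  tie <- base; tie[c("x07", "x08")] <- 5.5  # equal mnc, degrees 12 vs 12
  tie["x09"] <- 5.5                          # degree 11 loses the tie
  tables2 <- list(degree = deg, mnc = tie, dmnc = base, mcc = base, epc = base)
  tab2 <- top_k_aggregate(tables2, k = 8, min_degree = 0)
  picked <- tab2$gene[tab2$top_mnc]
  expect_true(all(c("x07", "x08") %in% picked))
  expect_false("x09" %in% picked)
  expect_warning(top_k_aggregate(tables, k = 99), "clamped")
})

test_that("MCODE recovers planted modules in noisy background networks", {
  hits <- 0
  for (i in 1:5) {
    sim <- simulate_network(n_nodes = 200, background_p = 0.02,
                            planted_clique_sizes = c(8, 6), seed = 400 + i)
    mods <- mcode_modules(sim$network)
    jac <- vapply(sim$truth$planted_modules, function(truth_mod) {
      max(vapply(mods$nodes, jaccard, numeric(1), b = truth_mod))
    }, numeric(1))
    hits <- hits + all(jac >= 0.8)
  }
  expect_gte(hits, 4)
  # and with no planted modules almost nothing passes the DDG criteria
  null_pass <- vapply(1:5, function(i) {
    sim <- simulate_network(n_nodes = 200, background_p = 0.01,
                            planted_clique_sizes = integer(), seed = 500 + i)
    mods <- mcode_modules(sim$network)
    sum(mods$score > 3 & mods$n_nodes > 5)
  }, numeric(1))
  expect_lte(sum(null_pass > 0), 1)
})
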