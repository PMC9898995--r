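# Brute-force oracles, written independently of the package internals (plain
# adjacency-matrix algorithms), plus small fixture builders.

adj_of <- function(g) {
  m <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  diag(m) <- FALSE
  m
}

# connected-component labels by plain stack-based search on an adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# MNC / DMNC by explicit neighborhood-component search (ties between
# equal-sized components broken by edge count, matching the documented rule)
oracle_mnc_dmnc <- function(adj, epsilon = 1.7) {
  n <- nrow(adj)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (!length(nb)) next
    sub <- adj[nb, nb, drop = FALSE]
    comp <- oracle_components(sub)
    sizes <- tabulate(comp)
    best <- max(sizes)
    cand <- which(sizes == best)
    edges <- max(vapply(cand, function(k) {
      idx <- which(comp == k)
      sum(sub[idx, idx, drop = FALSE]) / 2
    }, numeric(1)))
    mnc[v] <- best
    dmnc[v] <- edges / best^epsilon
  }
  list(mnc = mnc, dmnc = dmnc)
}

# MCC by exhaustive subset enumeration (n <= ~12)
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  score <- numeric(n)
  bits <- 2^(0:(n - 1))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, bits) > 0)
    if (length(S) >= 2) {
      pairs <- t(utils::combn(S, 2))
      if (!all(adj[pairs])) next
    }
    outside <- setdiff(seq_len(n), S)
    if (length(outside) &&
        any(vapply(outside, function(u) all(adj[u, S]), logical(1)))) next
    score[S] <- score[S] + factorial(length(S) - 1)
  }
  score
}

# AUC by exhaustive concordant-pair counting
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# quick expression-matrix builder
make_em <- function(values, labels, ...) {
  expression_matrix(values, labels, ...)
}

# two-group Gaussian matrix with optional planted shift
sim_two_group <- function(n_genes, n1, n2, shift_genes = character(),
                          shift = 0, sd = 1, seed = 1, labels = c("LN", "control")) {
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%02d", seq_len(n1 + n2))
    grp <- c(rep(labels[1], n1), rep(labels[2], n2))
    mu <- 7 + rnorm(n_genes, 0, 3)  # gene-level baseline spread
    v <- mu + matrix(rnorm(n_genes * (n1 + n2), mean = 0, sd = sd), n_genes,
                     n1 + n2, dimnames = list(genes, samples))
    if (length(shift_genes))
      v[shift_genes, grp == labels[1]] <- v[shift_genes, grp == labels[1]] + shift
    expression_matrix(v, setNames(grp, samples))
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

named_graph <- function(g) {
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}
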