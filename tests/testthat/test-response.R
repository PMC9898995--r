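test_that("response-DEG overlap counts clusters and directions", {
  degs <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         logfc = c(2, 1.5, -1.2, 1.1),
                         direction = c("up", "up", "down", "up"))
  assignment <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                               cluster = c("DDC-6", "DDC-6", "DDC-6", "DDC-2",
                                           "DDC-1"))
  ov <- response_deg_overlap(degs, assignment, logfc_threshold = 1)
  expect_equal(ov$frac_degs[ov$cluster == "DDC-6"], 0.75)
  expect_equal(ov$frac_up[ov$cluster == "DDC-6"], 2 / 3)
  expect_equal(ov$frac_degs[ov$cluster == "DDC-1"], 0)
  # |logFC| threshold is inclusive at 1, exclusive below
  degs$logfc <- c(0.9, 0.9, 0.9, 1.0)
  ov2 <- response_deg_overlap(degs, assignment, logfc_threshold = 1)
  expect_equal(sum(ov2$n_degs), 1L)
  # all up everywhere
  degs$logfc <- c(2, 2, 2, 2); degs$direction <- "up"
  ov3 <- response_deg_overlap(degs, assignment, logfc_threshold = 1)
  expect_true(all(ov3$frac_up[ov3$n_degs > 0] == 1))
  expect_warning(ov4 <- response_deg_overlap(degs[0, ], assignment), "no DEG")
  expect_true(all(ov4$frac_degs == 0))
})

test_that("stratified splitting preserves class counts and is deterministic", {
  r <- simulate_response_cohort(n_patients = 109, seed = 2)
  counts <- table(r$cohort$labels)
  sp <- split_train_test(r$cohort, ratio = 0.8, seed = 7)
  tr_counts <- table(sp$train$labels)
  for (cl in names(counts))
    expect_lte(abs(tr_counts[[cl]] - 0.8 * counts[[cl]]), 1)
  expect_setequal(c(colnames(sp$train$values), colnames(sp$test$values)),
                  colnames(r$cohort$values))
  sp2 <- split_train_test(r$cohort, ratio = 0.8, seed = 7)
  expect_identical(colnames(sp2$train$values), colnames(sp$train$values))
  expect_error(split_train_test(r$cohort, ratio = 0.995), "absent")
})

test_that("SMOTE interpolates along minority segments and balances classes", {
  feats <- rbind(diag(0, 2, 2), matrix(5, 6, 2)) + 0
  feats[1, ] <- c(0, 0); feats[2, ] <- c(1, 1)
  rownames(feats) <- sprintf("s%d", 1:8)
  labels <- c("min", "min", rep("maj", 6))
  expect_warning(out <- smote(feats, labels, k = 5, seed = 1), "reduced")
  expect_equal(sum(out$labels == "min"), sum(out$labels == "maj"))
  synth <- out$features[grepl("synth", rownames(out$features)), , drop = FALSE]
  # with minority {(0,0),(1,1)} every synthetic point lies on the diagonal
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-12))
  expect_true(all(synth >= 0 & synth <= 1))
  # balanced input returned unchanged
  bal <- smote(feats[c(1:2, 3:4), ], c("min", "min", "maj", "maj"), k = 1)
  expect_identical(bal$features, feats[c(1:2, 3:4), ])
  expect_error(smote(feats[2:8, ], labels[2:8], k = 1), "< 2")
  # 2.76:1 imbalance at n = 94 balances within one
  r <- simulate_response_cohort(n_patients = 94, seed = 3)
  x <- t(r$cohort$values[1:20, ])
  out2 <- smote(x, r$cohort$labels, k = 5, seed = 4)
  tab <- table(out2$labels)
  expect_lte(abs(tab[[1]] - tab[[2]]), 1)
  # synthetic points stay in the convex hull coordinate-wise
  minpts <- x[r$cohort$labels == names(sort(table(r$cohort$labels)))[1], ]
  syn2 <- out2$features[grepl("synth", rownames(out2$features)), ]
  expect_true(all(t(syn2) >= apply(minpts, 2, min) - 1e-9))
  expect_true(all(t(syn2) <= apply(minpts, 2, max) + 1e-9))
})

test_that("LASSO selects planted genes and degenerates to the intercept at heavy penalty", {
  set.seed(11)
  n <- 200; p <- 60
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  beta <- rep(0, p); beta[1:5] <- 2
  pr <- plogis(drop(x %*% beta))
  y <- ifelse(rbinom(n, 1, pr) == 1, "responder", "non-responder")
  fit <- lasso_cv(x, y, folds = 10, seed = 3)
  expect_gte(length(intersect(fit$selected$gene, sprintf("g%02d", 1:5))), 4)
  expect_lte(nrow(fit$selected) - length(intersect(fit$selected$gene,
                                                   sprintf("g%02d", 1:5))), 12)
  # path head: null model, intercept = log-odds of the class balance
  head_coefs <- coef(fit$fit, s = fit$lambda_path[1])
  expect_equal(sum(abs(head_coefs[-1])), 0)
  expect_equal(head_coefs[1], qlogis(mean(y == "responder")), tolerance = 1e-6)
  # selection is monotone along the path near full penalty
  nz <- fit$cv$nonzero
  expect_equal(unname(nz[1]), 0)
  # determinism
  fit2 <- lasso_cv(x, y, folds = 10, seed = 3)
  expect_identical(fit$selected, fit2$selected)
  expect_identical(glance(fit)$lambda, glance(fit2)$lambda)
})

test_that("AUC matches brute-force pair counting, including ties", {
  lab <- c("responder", "responder", "non-responder", "non-responder")
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), lab), 1)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.4), lab), 0.5)
  expect_equal(roc_auc(rep(0.5, 4), lab), 0.5)
  expect_error(roc_auc(1:3, rep("responder", 3)), "both classes")
  withr::with_seed(21, {
    for (i in 1:100) {
      n1 <- sample(1:4, 1); n0 <- sample(1:4, 1)
      scores <- sample(1:5, n1 + n0, replace = TRUE)  # ties likely
      labels <- c(rep("responder", n1), rep("non-responder", n0))
      expect_equal(roc_auc(scores, labels),
                   oracle_auc(scores, labels, "responder"))
    }
  })
})

test_that("DeLong intervals degenerate at perfect separation, mirror under sign flip, and match pROC", {
  lab <- c(rep("responder", 4), rep("non-responder", 4))
  expect_warning(ci <- auc_ci_delong(c(4, 3.5, 3, 2.9, 1, 0.5, 0.2, 0.1), lab),
                 "degenerate")
  expect_equal(c(ci$low, ci$high), c(1, 1))
  set.seed(5)
  sc <- c(rnorm(30, 1), rnorm(30))
  lab2 <- c(rep("responder", 30), rep("non-responder", 30))
  ci1 <- auc_ci_delong(sc, lab2)
  ci2 <- auc_ci_delong(-sc, lab2)
  expect_equal(ci2$low, 1 - ci1$high, tolerance = 1e-12)
  expect_equal(ci2$high, 1 - ci1$low, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  pr <- pROC::ci.auc(pROC::roc(lab2, sc, levels = c("non-responder", "responder"),
                               direction = "<", quiet = TRUE), method = "delong")
  expect_equal(ci1$auc, as.numeric(pr[2]), tolerance = 1e-12)
  expect_equal(ci1$low, as.numeric(pr[1]), tolerance = 1e-9)
  expect_equal(ci1$high, as.numeric(pr[3]), tolerance = 1e-9)
})

test_that("classification metrics satisfy their defining identities", {
  # TP 5, FP 1, FN 2, TN 20
  labels <- c(rep("responder", 7), rep("non-responder", 21))
  predicted <- c(rep("responder", 5), rep("non-responder", 2),
                 "responder", rep("non-responder", 20))
  m <- classification_metrics(predicted, labels)
  expect_equal(m$tp, 5); expect_equal(m$fp, 1)
  expect_equal(m$precision, 0.833, tolerance = 1e-3)
  expect_equal(m$recall, 0.714, tolerance = 1e-3)
  expect_equal(m$f1, 0.769, tolerance = 1e-3)
  perfect <- classification_metrics(labels, labels)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  flipped <- ifelse(labels == "responder", "non-responder", "responder")
  expect_equal(classification_metrics(flipped, labels)$recall, 0)
  expect_warning(classification_metrics(rep("non-responder", 28), labels),
                 "precision")
  # probabilities thresholded at 0.5
  pm <- classification_metrics(ifelse(labels == "responder", 0.9, 0.1), labels)
  expect_equal(pm$accuracy, 1)
})

test_that("hub re-ranking of selected genes flags response DEGs in top positions", {
  star <- igraph::make_star(8, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("leaf%d", 1:7))
  tab <- suppressWarnings(rank_selected_genes(star, igraph::V(star)$name, k = 3))
  expect_equal(tab$gene[1], "hub")
  expect_true(tab$top_degree[tab$gene == "hub"])
  expect_true(tab$top_mnc[tab$gene == "hub"])
  # flagged only when also a response DEG
  tab2 <- rank_selected_genes(star, igraph::V(star)$name, k = 3,
                              response_degs = "hub")
  expect_true(tab2$top_regulatory[tab2$gene == "hub"])
  expect_warning(rank_selected_genes(star, igraph::V(star)$name, k = 3,
                                     response_degs = character()),
                 "high-rank")
  expect_error(rank_selected_genes(star, "absent_gene", k = 3), "network")
})

test_that("per-cluster models keep test samples out of training and rank the planted block first", {
  pan <- simulate_panel_cohort(seed = 31)
  prof <- suppressMessages(build_correlation_profile(
    pan$datasets, pan$truth$signature_genes))
  ddc <- kmeans_cluster(prof, k = 8, seed = 31)
  resp <- simulate_response_cohort(blocks = pan$truth$blocks, seed = 32)
  val <- simulate_response_cohort(blocks = pan$truth$blocks,
                                  reuse_truth = resp$truth, seed = 33)
  mods <- suppressWarnings(run_per_cluster_models(
    resp$cohort, val$cohort, ddc, config = ln_config(seed = 34)))
  expect_s3_class(mods, "response_models")
  expect_true(all(mods$auc_test_low <= mods$auc_test &
                    mods$auc_test <= mods$auc_test_high))
  # the planted block's cluster wins on test AUC and recovers the genes
  truth_genes <- resp$truth$planted_predictive_genes$gene
  planted_cluster <- names(which.max(table(
    tidy(ddc)$cluster[tidy(ddc)$gene %in%
                        pan$truth$blocks[[resp$truth$block_of_predictive_genes]]])))
  expect_equal(mods$cluster[1], planted_cluster)
  expect_gte(length(intersect(mods$selected_genes[[1]], truth_genes)), 4)
  # determinism of the full modelling stage
  mods2 <- suppressWarnings(run_per_cluster_models(
    resp$cohort, val$cohort, ddc, config = ln_config(seed = 34)))
  expect_equal(as.data.frame(dplyr::select(mods, -"selected_genes")),
               as.data.frame(dplyr::select(mods2, -"selected_genes")))
  # no test sample participates in the training split of its cluster
  sp <- split_train_test(resp$cohort, 0.8, seed = mods$split_seed[1])
  expect_length(intersect(colnames(sp$train$values), colnames(sp$test$values)), 0)
})
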