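test_that("Spearman's rho matches the hand rank-difference formula", {
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_equal(spearman_rho(1:5, exp(1:5)), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")
  expect_error(spearman_rho(1:2, 2:1), ">= 3")
})

test_that("correlation profile pools datasets and applies the missing-gene exclusion rule", {
  pan <- simulate_panel_cohort(n_panel_genes = 60, n_blocks = 4,
                               n_samples_per_dataset = c(60, 60, 60),
                               block_rho = c(0.8, 0.4, 0, -0.8),
                               missing_in_dataset = 2, n_missing = 6, seed = 3)
  prof <- suppressMessages(build_correlation_profile(
    pan$datasets, pan$truth$signature_genes, max_missing = 5))
  excl <- attr(prof, "excluded")
  expect_equal(excl$dataset, "panel2")
  expect_match(excl$reason, "6 missing")
  expect_equal(setdiff(names(prof), "gene"), c("panel1", "panel3"))
  expect_true(all(abs(prof$panel1) <= 1, na.rm = TRUE))
  # a dataset missing exactly max_missing genes is retained
  pan2 <- simulate_panel_cohort(n_panel_genes = 60, n_blocks = 4,
                                n_samples_per_dataset = c(60, 60),
                                block_rho = c(0.8, 0.4, 0, -0.8),
                                missing_in_dataset = 2, n_missing = 5, seed = 3)
  prof2 <- suppressMessages(build_correlation_profile(
    pan2$datasets, pan2$truth$signature_genes, max_missing = 5))
  expect_equal(nrow(attr(prof2, "excluded")), 0)
  # block-0 genes have near-zero correlation, strong blocks track their target
  b0 <- pan$truth$blocks$B3; b1 <- pan$truth$blocks$B1
  expect_lt(max(abs(prof$panel1[prof$gene %in% b0])), 0.35)
  expect_gt(min(prof$panel1[prof$gene %in% b1]), 0.6)
  expect_error(build_correlation_profile(pan$datasets, pan$truth$signature_genes,
                                         max_missing = -1), "excluded")
})

test_that("profile columns from replicate datasets agree", {
  pan <- simulate_panel_cohort(n_panel_genes = 200, n_blocks = 8,
                               n_samples_per_dataset = c(200, 200), seed = 10)
  prof <- suppressMessages(build_correlation_profile(
    pan$datasets, pan$truth$signature_genes))
  cols <- as.matrix(prof[, -1])
  expect_gt(cor(cols[, 1], cols[, 2]), 0.9)
})

test_that("K-means clustering is deterministic, co-assigns duplicates and zeroes WSS at k = n", {
  pan <- simulate_panel_cohort(n_panel_genes = 40, n_blocks = 4,
                               n_samples_per_dataset = c(50, 50),
                               block_rho = c(0.8, 0.3, -0.3, -0.8), seed = 6)
  prof <- suppressMessages(build_correlation_profile(
    pan$datasets, pan$truth$signature_genes))
  m1 <- kmeans_cluster(prof, k = 4, seed = 9)
  m2 <- kmeans_cluster(prof, k = 4, seed = 9)
  expect_identical(m1$assignment, m2$assignment)
  # duplicate rows co-assigned
  prof_dup <- prof
  prof_dup[2, -1] <- prof_dup[1, -1]
  md <- kmeans_cluster(prof_dup, k = 4, seed = 9)
  expect_equal(unname(md$assignment[1]), unname(md$assignment[2]))
  # k = number of genes: WSS 0
  mk <- kmeans_cluster(prof, k = nrow(prof), seed = 1)
  expect_equal(mk$tot_wss, 0)
  expect_error(kmeans_cluster(prof, k = 1), ">= 2")
  # column order never changes assignments
  prof_rev <- prof[, c("gene", rev(setdiff(names(prof), "gene")))]
  class(prof_rev) <- class(prof)
  mr <- kmeans_cluster(prof_rev, k = 4, seed = 9)
  expect_equal(mclust::adjustedRandIndex(m1$assignment, mr$assignment), 1)
})

test_that("the WSS curve is non-increasing and elbows follow the second-difference rule", {
  pan <- simulate_panel_cohort(n_panel_genes = 80, n_blocks = 4,
                               n_samples_per_dataset = c(60, 60),
                               block_rho = c(0.8, 0.3, -0.3, -0.8), seed = 2)
  prof <- suppressMessages(build_correlation_profile(
    pan$datasets, pan$truth$signature_genes))
  curve <- wss_curve(prof, k_range = 2:10, seed = 4, n_restarts = 10)
  expect_true(all(diff(curve$wss) <= 1e-8))
  # hand curve: elbows at k = 2 and k = 5
  hand <- setNames(c(400, 200, 190, 180, 90, 80, 78, 76), 1:8)
  expect_equal(elbow_select(hand, which_elbow = 1), 2)
  expect_equal(elbow_select(hand, which_elbow = 2), 5)
  # geometric decay: single leading elbow
  geo <- setNames(512 / 2^(0:5), 1:6)
  expect_equal(elbow_select(geo, which_elbow = 1), 2)
  expect_warning(k2 <- elbow_select(geo, which_elbow = 2), "last")
  expect_equal(k2, 2)
  expect_error(elbow_select(setNames(c(10, 20, 5, 4, 3), 1:5)), "non-increasing")
  expect_error(elbow_select(setNames(c(9, 8, 7), 1:3)), ">= 5")
})

test_that("planted correlation blocks are recovered at the true k", {
  ari <- vapply(1:3, function(i) {
    pan <- simulate_panel_cohort(seed = 600 + i)
    prof <- suppressMessages(build_correlation_profile(
      pan$datasets, pan$truth$signature_genes))
    ddc <- kmeans_cluster(prof, k = 8, seed = 600 + i)
    truth <- rep(names(pan$truth$blocks), lengths(pan$truth$blocks))
    names(truth) <- unlist(pan$truth$blocks)
    mclust::adjustedRandIndex(ddc$assignment[names(truth)], truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})
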